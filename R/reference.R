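## The iENA core. A reference model holds the healthy cohort's per-taxon
## means and SDs and its pairwise Pearson correlation matrix. A single
## sample is scored by the perturbation it induces when appended to the
## reference: sPCC(i, j; s) = PCC over (reference + s) minus PCC over the
## reference. Edge-pairs are scored the same way on edge-profile variables
## (products of reference-standardised abundances), giving a fourth-order
## correlation per pair of edges.

#' Fit the reference (healthy cohort) correlation model
#'
#' @param x closed taxon-by-sample abundance matrix containing at least the
#'   reference samples.
#' @param design a [sample_design()]; samples of the reference group are
#'   used.
#' @return an object of class `"iena_ref"`: list with `samples`, `data`
#'   (taxa x reference samples), `mean`, `sd`, `cor` (reference PCC
#'   matrix), `dropped` (taxa with zero reference variance, excluded), and
#'   `rank` (free-text label of the taxonomic rank).
#' @param rank optional label for the taxonomic rank of the rows
#'   (e.g. "genus").
#' @export
fit_reference <- function(x, design, rank = NULL) {
  x <- abundance_table(x)
  ref_group <- design_reference(design)
  samples <- intersect(colnames(x), design_samples(design, ref_group))
  if (length(samples) < 3L)
    stop("need >= 3 reference samples to estimate correlations (got ",
         length(samples), ")", call. = FALSE)
  xr <- x[, samples, drop = FALSE]
  sds <- apply(xr, 1L, sd)
  dropped <- rownames(xr)[sds == 0]
  keep <- sds > 0
  xr <- xr[keep, , drop = FALSE]
  if (nrow(xr) < 2L)
    stop("fewer than 2 taxa with non-zero reference variance", call. = FALSE)
  structure(list(
    samples = samples,
    data    = xr,
    mean    = rowMeans(xr),
    sd      = sds[keep],
    cor     = cor(t(xr)),
    dropped = dropped,
    rank    = rank
  ), class = "iena_ref")
}

#' @export
print.iena_ref <- function(x, ...) {
  cat("iENA reference model\n")
  cat("  taxa:    ", nrow(x$data),
      if (length(x$dropped)) paste0(" (", length(x$dropped),
                                    " zero-variance taxa dropped)") else "",
      "\n", sep = "")
  cat("  samples: ", length(x$samples), " (",
      paste(head(x$samples, 5L), collapse = ", "),
      if (length(x$samples) > 5L) ", ..." else "", ")\n", sep = "")
  if (!is.null(x$rank)) cat("  rank:    ", x$rank, "\n", sep = "")
  invisible(x)
}

## Reference data for scoring `sample_id`: if the sample is itself a member
## of the reference cohort it is left out (scored against the remaining
## reference samples), so reference individuals can be scored too.
ref_for_sample <- function(ref, sample_id) {
  if (is.null(sample_id) || !sample_id %in% ref$samples) return(ref)
  keep <- setdiff(ref$samples, sample_id)
  if (length(keep) < 3L)
    stop("leave-one-out reference for '", sample_id,
         "' has fewer than 3 samples", call. = FALSE)
  xr <- ref$data[, keep, drop = FALSE]
  structure(list(samples = keep, data = xr, mean = rowMeans(xr),
                 sd = apply(xr, 1L, sd), cor = cor(t(xr)),
                 dropped = ref$dropped, rank = ref$rank),
            class = "iena_ref")
}

align_sample <- function(ref, sample) {
  if (is.null(names(sample))) {
    if (length(sample) != nrow(ref$data))
      stop("unnamed sample vector must match the model's taxa count",
           call. = FALSE)
    names(sample) <- rownames(ref$data)
  }
  missing <- setdiff(rownames(ref$data), names(sample))
  if (length(missing))
    stop("sample lacks taxa: ", paste(head(missing, 5L), collapse = ", "),
         call. = FALSE)
  sample[rownames(ref$data)]
}

#' Full sPCC perturbation matrix for one sample
#'
#' For every taxon pair, the change in Pearson correlation induced by
#' appending the sample to the reference cohort. Values lie in [-2, 2].
#' Pairs whose perturbed correlation is undefined (a taxon constant over
#' reference + sample; only possible numerically) are scored as
#' `0 - PCC_ref` and listed in attribute `flagged`.
#'
#' @param ref an [fit_reference()] model.
#' @param sample named abundance vector covering the model's taxa.
#' @param sample_id optional id; if it names a reference member, that
#'   member is left out of the reference before scoring.
#' @return taxa x taxa symmetric matrix of sPCC values (zero diagonal).
#' @export
spcc_matrix <- function(ref, sample, sample_id = NULL) {
  ref <- ref_for_sample(ref, sample_id)
  sample <- align_sample(ref, sample)
  aug <- cbind(ref$data, sample)
  pert <- suppressWarnings(cor(t(aug)))
  flagged <- NULL
  if (anyNA(pert)) {
    idx <- which(is.na(pert) & upper.tri(pert), arr.ind = TRUE)
    flagged <- cbind(rownames(pert)[idx[, 1]], colnames(pert)[idx[, 2]])
    pert[is.na(pert)] <- 0
  }
  out <- pert - ref$cor
  diag(out) <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Single-pair sPCC score
#'
#' @inheritParams spcc_matrix
#' @param i,j taxon ids (or indices into the model's taxa).
#' @return a single sPCC value; symmetric in `(i, j)`.
#' @export
spcc <- function(ref, sample, i, j, sample_id = NULL) {
  m <- spcc_matrix(ref, sample, sample_id = sample_id)
  m[i, j]
}

#' Per-sample edge variable (edge profile)
#'
#' The product of reference-standardised abundances of the edge's two taxa:
#' `e(s) = z_i(s) * z_j(s)` with `z = (x - mean_ref) / sd_ref`. The edge
#' profile over the reference cohort is the substrate of the fourth-order
#' correlation.
#'
#' @param ref an [fit_reference()] model.
#' @param i,j taxon ids of the edge.
#' @param samples abundance matrix (taxa x samples) to evaluate; defaults
#'   to the reference samples.
#' @return numeric vector of edge-variable values, one per sample.
#' @export
edge_profile <- function(ref, i, j, samples = NULL) {
  if (is.null(samples)) samples <- ref$data
  for (t in c(i, j))
    if (!t %in% rownames(ref$data))
      stop("taxon '", t, "' not retained in the reference model", call. = FALSE)
  zi <- (samples[i, ] - ref$mean[i]) / ref$sd[i]
  zj <- (samples[j, ] - ref$mean[j]) / ref$sd[j]
  zi * zj
}

## Edge-profile matrix for a set of edges: reference samples x edges, plus
## the single-sample profile values. `edges` is a 2-column character matrix.
edge_profile_matrix <- function(ref, edges, sample = NULL) {
  Z <- (ref$data - ref$mean) / ref$sd
  E <- t(Z[edges[, 1], , drop = FALSE] * Z[edges[, 2], , drop = FALSE])
  colnames(E) <- paste(edges[, 1], edges[, 2], sep = "~")
  if (is.null(sample)) return(E)
  zs <- (sample - ref$mean) / ref$sd
  es <- zs[edges[, 1]] * zs[edges[, 2]]
  names(es) <- colnames(E)
  list(ref = E, sample = es)
}

#' Select the top-ranked edges as the background edge-network
#'
#' Ranks all taxon pairs by the strength of their relationship and keeps
#' the top `k` as the "nodes" of the subsequent edge-network. Two ranking
#' scores are available: the absolute reference correlation (default), or
#' the maximum absolute sPCC over a set of scored samples.
#'
#' @param ref an [fit_reference()] model.
#' @param k number of edges to keep; defaults to
#'   `min(200, ceiling(0.1 * n_pairs))`. If `k` exceeds the number of
#'   pairs, all pairs are returned with a message.
#' @param rank_by `"reference"` (|reference PCC|) or `"spcc"`
#'   (max |sPCC| over `spcc_list`).
#' @param spcc_list list of sPCC matrices (from [spcc_matrix()]), required
#'   when `rank_by = "spcc"`.
#' @return data.frame of class `"iena_edges"`: `taxon_i`, `taxon_j`
#'   (lexicographically ordered within pair), `score`, `rank`. Ties are
#'   broken lexicographically by taxon-id pair.
#' @export
select_top_edges <- function(ref, k = NULL, rank_by = c("reference", "spcc"),
                             spcc_list = NULL) {
  rank_by <- match.arg(rank_by)
  taxa <- rownames(ref$cor)
  n <- length(taxa)
  ut <- which(upper.tri(ref$cor), arr.ind = TRUE)
  score_mat <- switch(rank_by,
    reference = abs(ref$cor),
    spcc = {
      if (is.null(spcc_list) || !length(spcc_list))
        stop("rank_by = 'spcc' needs a non-empty spcc_list", call. = FALSE)
      Reduce(pmax, lapply(spcc_list, abs))
    })
  scores <- score_mat[ut]
  n_pairs <- nrow(ut)
  if (is.null(k)) k <- min(200L, ceiling(0.1 * n_pairs))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n_pairs) {
    message("k = ", k, " exceeds the ", n_pairs, " available pairs; keeping all")
    k <- n_pairs
  }
  ti <- taxa[ut[, 1]]; tj <- taxa[ut[, 2]]
  swap <- ti > tj
  tmp <- ti[swap]; ti[swap] <- tj[swap]; tj[swap] <- tmp
  ord <- order(-scores, ti, tj)
  sel <- ord[seq_len(k)]
  out <- data.frame(taxon_i = ti[sel], taxon_j = tj[sel],
                    score = scores[sel], rank = seq_len(k),
                    stringsAsFactors = FALSE)
  class(out) <- c("iena_edges", "data.frame")
  attr(out, "rank_by") <- rank_by
  out
}

#' Fourth-order sPCC scores for all edge-pairs of one sample
#'
#' Evaluates each selected edge as a per-sample variable (see
#' [edge_profile()]), then scores every pair of distinct edges by the sPCC
#' perturbation of the correlation between the two edge variables when the
#' sample is appended to the reference cohort.
#'
#' @param ref an [fit_reference()] model.
#' @param sample named abundance vector.
#' @param edges an [select_top_edges()] result (or 2-column matrix of taxon
#'   ids).
#' @param sample_id optional id for leave-one-out handling of reference
#'   members.
#' @return data.frame: `edge1`, `edge2` (labels `"i~j"`), `score`
#'   (fourth-order sPCC). Edges whose reference profile has zero variance
#'   are skipped and listed in attribute `skipped`.
#' @export
edge_pair_scores <- function(ref, sample, edges, sample_id = NULL) {
  ref <- ref_for_sample(ref, sample_id)
  sample <- align_sample(ref, sample)
  em <- as.matrix(edges[, c(1, 2)])
  prof <- edge_profile_matrix(ref, em, sample)
  sds <- apply(prof$ref, 2L, sd)
  skipped <- colnames(prof$ref)[sds == 0]
  keep <- sds > 0
  E <- prof$ref[, keep, drop = FALSE]
  es <- prof$sample[keep]
  if (ncol(E) < 2L)
    stop("fewer than 2 non-degenerate edges; no edge-pairs to score",
         call. = FALSE)
  C_ref <- cor(E)
  C_pert <- suppressWarnings(cor(rbind(E, es)))
  C_pert[is.na(C_pert)] <- 0
  fo <- C_pert - C_ref
  ut <- which(upper.tri(fo), arr.ind = TRUE)
  out <- data.frame(edge1 = colnames(E)[ut[, 1]],
                    edge2 = colnames(E)[ut[, 2]],
                    score = fo[ut], stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Single edge-pair fourth-order sPCC
#'
#' @inheritParams edge_pair_scores
#' @param e1,e2 edges as length-2 character vectors of taxon ids (distinct
#'   edges).
#' @return one fourth-order sPCC value; symmetric in `(e1, e2)`.
#' @export
fourth_order_spcc <- function(ref, sample, e1, e2, sample_id = NULL) {
  if (identical(sort(e1), sort(e2)))
    stop("e1 and e2 must be distinct edges", call. = FALSE)
  edges <- rbind(e1, e2)
  res <- edge_pair_scores(ref, sample, edges, sample_id = sample_id)
  res$score[1]
}

edge_labels <- function(edges) paste(edges[[1]], edges[[2]], sep = "~")

## Split "i~j" labels back into taxon pairs.
split_edge_labels <- function(labels) {
  do.call(rbind, strsplit(labels, "~", fixed = TRUE))
}
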