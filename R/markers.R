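## Edge-biomarkers and the sCI composite index. The top-ranked edge-pairs
## of a sample are its edge-biomarkers; the taxa they involve form the
## sample's "Marker" set. The composite index
##   sCI = (mean |sPCC| within the marker set)
##       / (mean |sPCC| between marker and non-marker taxa)
##       * (mean |x - mu_ref| over marker taxa)
## quantifies how strongly and how coherently the sample departs from the
## reference community.

#' Select a sample's edge-biomarkers (Marker set)
#'
#' Ranks the sample's edge-pairs by absolute fourth-order sPCC and returns
#' the union of taxa appearing in the top `m` edge-pairs. Ties are broken
#' lexicographically by edge-pair label.
#'
#' @param pair_scores data.frame from [edge_pair_scores()].
#' @param m number of top edge-pairs to keep (default 10).
#' @return character vector of marker taxa (sorted); attributes
#'   `edge_pairs` (the selected pairs) are attached.
#' @export
select_edge_biomarkers <- function(pair_scores, m = 10L) {
  if (is.null(pair_scores) || nrow(pair_scores) == 0L)
    stop("no edge-pairs available for marker selection", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  ord <- order(-abs(pair_scores$score), pair_scores$edge1, pair_scores$edge2)
  top <- pair_scores[ord[seq_len(min(m, nrow(pair_scores)))], , drop = FALSE]
  taxa <- sort(unique(c(split_edge_labels(top$edge1),
                        split_edge_labels(top$edge2))))
  attr(taxa, "edge_pairs") <- top
  taxa
}

#' Compute the sCI composite index for one sample
#'
#' @param ref an [fit_reference()] model.
#' @param sample named abundance vector.
#' @param marker character vector of marker taxa; must be a non-empty
#'   strict subset of the model's taxa.
#' @param spcc optional precomputed sPCC matrix for the sample (from
#'   [spcc_matrix()]); computed if missing.
#' @param sample_id optional id for leave-one-out handling.
#' @return one-row data.frame: `pcc_in`, `pcc_out`, `sd_in`, `sci`,
#'   `flag` (`""`, `"singleton_marker"` or `"zero_pcc_out"`).
#'   A singleton marker has no within pairs; `pcc_in` (and hence `sci`)
#'   is 0. `pcc_out = 0` gives `sci = Inf` with a flag.
#' @export
compute_sci <- function(ref, sample, marker, spcc = NULL, sample_id = NULL) {
  ref_s <- ref_for_sample(ref, sample_id)
  sample <- align_sample(ref_s, sample)
  taxa <- rownames(ref_s$data)
  marker <- unique(as.character(marker))
  if (length(marker) == 0L)
    stop("marker set is empty", call. = FALSE)
  if (!all(marker %in% taxa))
    stop("marker taxa not in the model: ",
         paste(head(setdiff(marker, taxa), 5L), collapse = ", "), call. = FALSE)
  if (length(marker) >= length(taxa))
    stop("marker set equals the whole taxon universe; pcc_out undefined",
         call. = FALSE)
  if (is.null(spcc)) spcc <- spcc_matrix(ref, sample, sample_id = sample_id)
  other <- setdiff(taxa, marker)
  flag <- ""
  if (length(marker) == 1L) {
    pcc_in <- 0
    flag <- "singleton_marker"
  } else {
    mm <- abs(spcc[marker, marker])
    pcc_in <- mean(mm[upper.tri(mm)])
  }
  pcc_out <- mean(abs(spcc[marker, other, drop = FALSE]))
  sd_in <- mean(abs(sample[marker] - ref_s$mean[marker]))
  if (pcc_out == 0) {
    sci <- if (pcc_in == 0) 0 else Inf
    if (is.infinite(sci)) flag <- "zero_pcc_out"
  } else {
    sci <- pcc_in / pcc_out * sd_in
  }
  data.frame(pcc_in = pcc_in, pcc_out = pcc_out, sd_in = sd_in, sci = sci,
             flag = flag, stringsAsFactors = FALSE)
}

#' Union marker set of a disease group
#'
#' Pools the per-sample marker sets of a group. `min_support = 0` gives
#' the plain union; a positive value keeps only taxa recurring in at least
#' that fraction of the group's samples ("robust" union markers — features
#' repeatedly present in the same disease group are the more
#' representative disease-specific candidates).
#'
#' @param markers named list: sample id -> character vector of marker taxa.
#' @param design a [sample_design()].
#' @param group group label.
#' @param min_support minimum fraction of the group's marker-bearing
#'   samples a taxon must appear in (default 0 = plain union).
#' @return character vector of marker taxa; attribute `support` gives the
#'   per-taxon recurrence fraction over the group's samples.
#' @export
union_markers <- function(markers, design, group, min_support = 0) {
  ids <- intersect(names(markers), design_samples(design, group))
  if (length(ids) == 0L)
    stop("no samples with marker sets in group '", group, "'", call. = FALSE)
  counts <- table(unlist(markers[ids]))
  support <- as.numeric(counts) / length(ids)
  names(support) <- names(counts)
  keep <- names(support)[support >= min_support & support > 0]
  if (length(keep) == 0L) keep <- names(support)[support > 0]
  out <- sort(keep)
  attr(out, "support") <- support[order(names(support))]
  out
}

#' Score all samples against group marker sets and assess discrimination
#'
#' Computes the sCI of every sample against each disease group's union
#' marker set, then reports group means and an assignment of each sample:
#' a sample is called for the disease group giving its largest sCI, or for
#' the reference group when all of its sCI values fall below the 95th
#' percentile of the reference cohort's scores for the respective marker
#' set.
#'
#' @param ref an [fit_reference()] model.
#' @param x closed taxon-by-sample abundance matrix (all samples to score).
#' @param design a [sample_design()].
#' @param union_marker_sets named list: disease group -> marker taxa.
#' @param spcc_list optional named list of precomputed sPCC matrices.
#' @return list of class `"iena_sci"`: `scores` (long data.frame: sample,
#'   group, marker_set, pcc_in, pcc_out, sd_in, sci, flag), `group_means`
#'   (marker_set x group matrix of mean sCI), `assignment` (per sample),
#'   `accuracy` (fraction of samples assigned to their true group).
#' @export
classify_by_sci <- function(ref, x, design, union_marker_sets,
                            spcc_list = NULL) {
  x <- abundance_table(x)
  check_design_covers(x, design)
  if (!length(union_marker_sets) || is.null(names(union_marker_sets)))
    stop("union_marker_sets must be a named list (group -> taxa)", call. = FALSE)
  ref_group <- design_reference(design)
  rows <- list()
  for (s in colnames(x)) {
    sp <- if (!is.null(spcc_list) && s %in% names(spcc_list)) spcc_list[[s]]
          else spcc_matrix(ref, x[, s], sample_id = s)
    for (g in names(union_marker_sets)) {
      sci <- compute_sci(ref, x[, s], union_marker_sets[[g]], spcc = sp,
                         sample_id = s)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample = s,
                   group = design$group[design$sample_id == s],
                   marker_set = g, stringsAsFactors = FALSE),
        sci)
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  gm <- tapply(scores$sci, list(scores$marker_set, scores$group), mean)
  ## assignment rule: max-sCI disease group, unless all scores sit within
  ## the reference cohort's range (95th percentile per marker set)
  ref_samples <- design_samples(design, ref_group)
  ref_q95 <- tapply(scores$sci[scores$sample %in% ref_samples],
                    scores$marker_set[scores$sample %in% ref_samples],
                    quantile, probs = 0.95, names = FALSE)
  assignment <- vapply(unique(scores$sample), function(s) {
    sc <- scores[scores$sample == s, ]
    below <- sc$sci <= ref_q95[sc$marker_set]
    if (all(below)) ref_group else sc$marker_set[which.max(sc$sci)]
  }, character(1))
  truth <- design$group[match(names(assignment), design$sample_id)]
  structure(list(scores = scores, group_means = gm,
                 assignment = data.frame(sample = names(assignment),
                                         group = truth,
                                         assigned = unname(assignment),
                                         stringsAsFactors = FALSE),
                 accuracy = mean(assignment == truth)),
            class = "iena_sci")
}

#' @export
print.iena_sci <- function(x, ...) {
  cat("sCI group discrimination\n")
  cat("mean sCI by marker set (rows) and group (columns):\n")
  print(round(x$group_means, 4))
  cat(sprintf("assignment accuracy: %.2f\n", x$accuracy))
  invisible(x)
}
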