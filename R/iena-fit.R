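## The one-call interface: fit the reference model, score every sample,
## build the edge-network, extract per-sample edge-biomarkers, form group
## union markers and sCI-based discrimination. Returns a classed object
## with the usual modelling verbs.

#' Fit an individual-specific edge-network analysis
#'
#' Runs the full iENA workflow on a closed taxon-by-sample abundance table
#' with a healthy reference group: reference correlation model, per-sample
#' sPCC perturbation matrices (reference members are scored leave-one-out),
#' top-edge selection, fourth-order edge-pair scores, per-sample marker
#' sets, per-disease-group union markers and sCI scoring of every sample
#' against every marker set.
#'
#' @param x closed taxon-by-sample abundance matrix (see
#'   [abundance_table()]); taxa all-zero in the reference group are
#'   excluded from the model and reported.
#' @param design a [sample_design()] with a designated reference group.
#' @param top_k edges kept in the edge-network (default
#'   `min(200, ceiling(0.1 * n_pairs))`).
#' @param top_m edge-pairs per sample kept as edge-biomarkers (default
#'   10).
#' @param marker_support union-marker recurrence threshold within a group
#'   (default 0.5: a taxon must appear in at least half of the group's
#'   per-sample marker sets; 0 gives the plain union).
#' @param edge_rank edge-ranking rule passed to [select_top_edges()]
#'   (default `"reference"`).
#' @param rank optional label of the taxonomic rank analysed.
#' @return object of class `"iena"`; see [print.iena()],
#'   [summary.iena()], [predict.iena()], [plot.iena()]. Components:
#'   `ref`, `edges`, `spcc` (per-sample matrices), `pair_scores`
#'   (per-sample data.frames), `markers` (per-sample taxa),
#'   `union_markers` (per disease group), `sci` (a [classify_by_sci()]
#'   result), `design`, `call`.
#' @examples
#' sim <- simulate_cohort(seed = 42)
#' fit <- iena(sim$table, sim$design)
#' fit
#' summary(fit)
#' @export
iena <- function(x, design, top_k = NULL, top_m = 10L, marker_support = 0.5,
                 edge_rank = c("reference", "spcc"), rank = NULL) {
  edge_rank <- match.arg(edge_rank)
  x <- abundance_table(x)
  check_design_covers(x, design)
  ref_group <- design_reference(design)
  ref <- fit_reference(x, design, rank = rank)
  x <- x[rownames(ref$data), , drop = FALSE]

  spcc_list <- lapply(colnames(x), function(s)
    spcc_matrix(ref, x[, s], sample_id = s))
  names(spcc_list) <- colnames(x)

  disease_samples <- design$sample_id[design$group != ref_group]
  edges <- select_top_edges(ref, k = top_k, rank_by = edge_rank,
                            spcc_list = spcc_list[intersect(colnames(x),
                                                            disease_samples)])

  pair_scores <- lapply(colnames(x), function(s)
    edge_pair_scores(ref, x[, s], edges, sample_id = s))
  names(pair_scores) <- colnames(x)

  markers <- lapply(pair_scores, select_edge_biomarkers, m = top_m)

  disease_groups <- setdiff(unique(design$group), ref_group)
  union_sets <- lapply(disease_groups, function(g)
    union_markers(markers, design, g, min_support = marker_support))
  names(union_sets) <- disease_groups

  sci <- classify_by_sci(ref, x, design, union_sets, spcc_list = spcc_list)

  structure(list(ref = ref, edges = edges, spcc = spcc_list,
                 pair_scores = pair_scores, markers = markers,
                 union_markers = union_sets, sci = sci, design = design,
                 top_m = top_m, marker_support = marker_support,
                 edge_rank = edge_rank, call = match.call()),
            class = "iena")
}

#' @export
print.iena <- function(x, ...) {
  ref_group <- design_reference(x$design)
  cat("Individual-specific edge-network analysis\n\n")
  cat("  taxa:          ", nrow(x$ref$data), "\n", sep = "")
  cat("  samples:       ", length(x$spcc), " (reference '", ref_group, "': ",
      length(x$ref$samples), ")\n", sep = "")
  cat("  edge-network:  ", nrow(x$edges), " edges (ranked by ", x$edge_rank,
      ")\n", sep = "")
  for (g in names(x$union_markers))
    cat("  markers [", g, "]:  {", paste(x$union_markers[[g]], collapse = ", "),
        "}\n", sep = "")
  cat(sprintf("  sCI accuracy:  %.2f\n", x$sci$accuracy))
  invisible(x)
}

#' Summary of an iENA fit
#'
#' @param object an [iena()] fit.
#' @param ... unused.
#' @return object of class `"summary.iena"` with per-group mean sCI,
#'   marker sets, and the per-sample assignment table.
#' @export
summary.iena <- function(object, ...) {
  structure(list(group_means = object$sci$group_means,
                 assignment = object$sci$assignment,
                 accuracy = object$sci$accuracy,
                 union_markers = object$union_markers,
                 n_edges = nrow(object$edges),
                 n_taxa = nrow(object$ref$data)),
            class = "summary.iena")
}

#' @export
print.summary.iena <- function(x, ...) {
  cat("iENA summary:", x$n_taxa, "taxa,", x$n_edges, "edge-network edges\n\n")
  cat("mean sCI by marker set (rows) and group (columns):\n")
  print(round(x$group_means, 4))
  cat("\nunion markers:\n")
  for (g in names(x$union_markers))
    cat("  ", g, ": ", paste(x$union_markers[[g]], collapse = ", "), "\n",
        sep = "")
  cat("\nper-sample assignment:\n")
  print(x$assignment, row.names = FALSE)
  cat(sprintf("\naccuracy: %.2f\n", x$accuracy))
  invisible(x)
}

#' Score new samples against a fitted iENA model
#'
#' Computes sPCC matrices and sCI values of new samples against the fit's
#' reference model and union marker sets, and assigns each new sample a
#' group by the fitted assignment rule.
#'
#' @param object an [iena()] fit.
#' @param newdata taxon-by-sample abundance matrix (closed) covering the
#'   model's taxa.
#' @param ... unused.
#' @return data.frame: `sample`, `marker_set`, `pcc_in`, `pcc_out`,
#'   `sd_in`, `sci`, `assigned`.
#' @export
predict.iena <- function(object, newdata, ...) {
  newdata <- abundance_table(newdata)
  ref <- object$ref
  ref_group <- design_reference(object$design)
  ## reference-cohort sCI 95th percentiles per marker set (assignment rule)
  sc <- object$sci$scores
  ref_ids <- design_samples(object$design, ref_group)
  q95 <- tapply(sc$sci[sc$sample %in% ref_ids],
                sc$marker_set[sc$sample %in% ref_ids],
                quantile, probs = 0.95, names = FALSE)
  rows <- list()
  for (s in colnames(newdata)) {
    v <- newdata[rownames(ref$data), s]
    sp <- spcc_matrix(ref, v)
    per <- lapply(names(object$union_markers), function(g)
      cbind(data.frame(sample = s, marker_set = g, stringsAsFactors = FALSE),
            compute_sci(ref, v, object$union_markers[[g]], spcc = sp)))
    per <- do.call(rbind, per)
    below <- per$sci <= q95[per$marker_set]
    per$assigned <- if (all(below)) ref_group else
      per$marker_set[which.max(per$sci)]
    rows[[s]] <- per
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot sCI distributions by group
#'
#' Strip chart of per-sample sCI values for each group, one panel row per
#' marker set, mirroring the composite-index distributions used to
#' discriminate disease states.
#'
#' @param x an [iena()] fit.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.iena <- function(x, ...) {
  sc <- x$sci$scores
  sets <- unique(sc$marker_set)
  op <- graphics::par(mfrow = c(length(sets), 1),
                      mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ms in sets) {
    sub <- sc[sc$marker_set == ms, ]
    stripchart(sci ~ group, data = sub, vertical = TRUE, pch = 19,
               method = "jitter", col = adjustcolor("steelblue", 0.8),
               main = paste("marker set", ms), ylab = "sCI", ...)
  }
  invisible(x)
}
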