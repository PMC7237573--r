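## Seeded replicate experiments that measure how reliably the workflow
## recovers structure planted by the cohort simulator: sCI ordering of
## disease vs reference-like samples, union-marker recovery of the rewired
## module, and hub recovery in per-group networks. These back the
## validation claims in the vignette and the acceptance report.

## Shared single replicate of the planted-rewiring experiment: reference
## cohort with one module, a sign-flipped disease cohort, optionally a
## held-out cohort re-drawn with no effect.
rewired_replicate <- function(seed, n_ref, n_dis, n_taxa = 50L,
                              module_size = 6L, loading = 0.9,
                              effect = "sign_flip", held_out = FALSE,
                              top_m = 10L, marker_support = 0.5) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  members <- taxa[seq_len(module_size)]
  ref <- generate_reference_cohort(
    n_ref, n_taxa, modules = list(list(members = members, loading = loading)),
    seed = seed)
  dis <- generate_disease_cohort(ref, members, effect, n_dis,
                                 seed = seed + 50000L, group = "G")
  rm <- fit_reference(ref$table, ref$design)
  edges <- select_top_edges(rm)
  mks <- lapply(colnames(dis$table), function(s)
    select_edge_biomarkers(edge_pair_scores(rm, dis$table[, s], edges),
                           m = top_m))
  names(mks) <- colnames(dis$table)
  um <- union_markers(mks, dis$design, "G", min_support = marker_support)
  out <- list(ref = ref, dis = dis, model = rm, edges = edges,
              markers = mks, union = um, module = members)
  if (held_out) {
    out$held <- generate_disease_cohort(ref, members, "none", n_dis,
                                        seed = seed + 100000L, group = "X")
  }
  out
}

mean_sci <- function(model, tab, marker) {
  mean(vapply(colnames(tab), function(s)
    compute_sci(model, tab[, s], marker)$sci, numeric(1)))
}

#' Replicate experiment: sCI orders disease above reference
#'
#' For each replicate, generates a reference cohort with a planted
#' correlated module and a disease cohort whose module correlations are
#' sign-flipped, scores both groups' samples with the sCI built from the
#' disease group's union markers, and records whether the disease group's
#' mean sCI exceeds the reference group's mean. As in the study (and in
#' [classify_by_sci()]), the reference group's scores are those of the
#' reference cohort members themselves, each scored leave-one-out;
#' `reference_scoring = "held_out"` instead scores a fresh cohort re-drawn
#' from the unchanged reference model.
#'
#' @param n_rep number of replicates (default 100).
#' @param base_seed seed offset; replicate r uses `base_seed + r`.
#' @param n_per_group samples per cohort (default 5, the study's group
#'   size).
#' @param reference_scoring `"members"` (default) or `"held_out"`.
#' @param ... passed to the shared replicate generator (taxa count,
#'   module size, loading, marker parameters).
#' @return list: `rate` (fraction of replicates with the expected
#'   ordering), `ok` (logical per replicate).
#' @export
replicate_sci_ordering <- function(n_rep = 100L, base_seed = 0L,
                                   n_per_group = 5L,
                                   reference_scoring = c("members",
                                                         "held_out"), ...) {
  reference_scoring <- match.arg(reference_scoring)
  held <- reference_scoring == "held_out"
  ok <- vapply(seq_len(n_rep), function(r) {
    rep <- rewired_replicate(base_seed + r, n_per_group, n_per_group,
                             held_out = held, ...)
    ref_mean <- if (held) {
      mean_sci(rep$model, rep$held$table, rep$union)
    } else {
      mean(vapply(colnames(rep$ref$table), function(s)
        compute_sci(rep$model, rep$ref$table[, s], rep$union,
                    sample_id = s)$sci, numeric(1)))
    }
    mean_sci(rep$model, rep$dis$table, rep$union) > ref_mean
  }, logical(1))
  list(rate = mean(ok), ok = ok)
}

#' Replicate experiment: union markers recover the planted module
#'
#' Measures the Jaccard overlap between the disease group's union marker
#' set and the planted rewired module.
#'
#' @inheritParams replicate_sci_ordering
#' @param n_per_group samples per cohort (default 20).
#' @param jaccard_min overlap counted as a recovery (default 0.5).
#' @return list: `rate` (fraction of replicates with Jaccard >=
#'   `jaccard_min`), `jaccard` (per replicate).
#' @export
replicate_marker_recovery <- function(n_rep = 100L, base_seed = 0L,
                                      n_per_group = 20L, jaccard_min = 0.5,
                                      ...) {
  jac <- vapply(seq_len(n_rep), function(r) {
    rep <- rewired_replicate(base_seed + r, n_per_group, n_per_group, ...)
    length(intersect(rep$union, rep$module)) /
      length(union(rep$union, rep$module))
  }, numeric(1))
  list(rate = mean(jac >= jaccard_min), jaccard = jac)
}

#' Replicate experiment: planted hub recovery in group networks
#'
#' Plants a disease-specific star (one hub taxon strongly coupled to a
#' set of satellites, no structure in the reference), builds per-group
#' co-occurrence networks, and records whether the hub ranks in the
#' disease network's top `k` by degree, and whether
#' [disease_specific_hubs()] flags it for the disease group only.
#'
#' @inheritParams replicate_sci_ordering
#' @param n_per_group samples per group (default 10).
#' @param n_taxa taxa (default 50).
#' @param n_sat satellites of the planted hub (default 15).
#' @param hub_loading,sat_loading star factor loadings (defaults 0.97 and
#'   0.75; hub-satellite latent correlation 0.73).
#' @param threshold network binarisation threshold (default 0.5).
#' @param k hub cut-off (default 3).
#' @return list: `rate_top` (hub in disease top-k), `rate_specific`
#'   (additionally flagged disease-specific), and the per-replicate
#'   logicals.
#' @export
replicate_hub_recovery <- function(n_rep = 100L, base_seed = 0L,
                                   n_per_group = 10L, n_taxa = 50L,
                                   n_sat = 15L, hub_loading = 0.97,
                                   sat_loading = 0.75, threshold = 0.5,
                                   k = 3L) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  res <- vapply(seq_len(n_rep), function(r) {
    seed <- base_seed + r
    hub <- taxa[10]
    sats <- with_seed(seed, sample(setdiff(taxa, hub), n_sat))
    ref <- generate_reference_cohort(n_per_group, n_taxa, seed = seed + 1L)
    dis <- generate_disease_cohort(
      ref, c(hub, sats), "strengthen", n_per_group, seed = seed + 50000L,
      group = "D", loading = c(hub_loading, rep(sat_loading, n_sat)))
    tab <- cbind(ref$table, dis$table)
    design <- sample_design(colnames(tab),
                            rep(c("H", "D"), each = n_per_group),
                            reference = "H")
    tab <- abundance_table(tab, closed = TRUE)
    nets <- lapply(c(H = "H", D = "D"), function(g)
      build_group_network(tab, design, g, threshold = threshold))
    hubs <- lapply(nets, rank_hubs, k = k)
    spec <- disease_specific_hubs(hubs, k = k)
    c(top = hub %in% hubs$D$taxon[hubs$D$rank <= k],
      specific = hub %in% spec$D && !(hub %in% spec$H))
  }, logical(2))
  list(rate_top = mean(res["top", ]), rate_specific = mean(res["specific", ]),
       top = res["top", ], specific = res["specific", ])
}
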