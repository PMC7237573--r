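## Conventional per-feature statistics that accompany the network analysis:
## rank-based two-group and multi-group tests with BH correction,
## hypergeometric category enrichment, alpha diversity and PCA.

#' Two-group Wilcoxon rank-sum differential test
#'
#' Two-sided rank-sum test per feature between two sample groups. The exact
#' null distribution is used at small group sizes (both <= 10, no ties),
#' the tie-corrected normal approximation otherwise.
#'
#' @param x feature-by-sample matrix.
#' @param design a [sample_design()].
#' @param group_a,group_b group labels to compare.
#' @param alpha selection threshold on the raw p-value (default 0.05).
#' @param fdr_alpha optional additional threshold on the BH-adjusted
#'   p-value; `NULL` (default) selects on `alpha` alone.
#' @return data.frame with `feature`, `statistic` (rank-sum W), `p_value`,
#'   `fdr` (BH across features), `selected`.
#' @export
diff_wilcoxon <- function(x, design, group_a, group_b, alpha = 0.05,
                          fdr_alpha = NULL) {
  x <- check_feature_matrix(x)
  for (g in c(group_a, group_b))
    if (!g %in% design$group)
      stop("group '", g, "' absent from design", call. = FALSE)
  sa <- intersect(colnames(x), design_samples(design, group_a))
  sb <- intersect(colnames(x), design_samples(design, group_b))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both groups need >= 2 samples in the table", call. = FALSE)
  exact <- length(sa) <= 10L && length(sb) <= 10L
  res <- t(apply(x, 1L, function(v) {
    wt <- suppressWarnings(
      wilcox.test(v[sa], v[sb], exact = exact, correct = TRUE))
    c(wt$statistic, wt$p.value)
  }))
  out <- data.frame(feature = rownames(x), statistic = res[, 1],
                    p_value = res[, 2], stringsAsFactors = FALSE)
  ## fully tied features carry no signal; the approximate p is NaN there
  out$p_value[is.nan(out$p_value)] <- 1
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$selected <- out$p_value < alpha &
    (if (is.null(fdr_alpha)) TRUE else out$fdr < fdr_alpha)
  rownames(out) <- NULL
  out
}

#' Multi-group Kruskal-Wallis differential test
#'
#' Kruskal-Wallis test per feature across all groups in the design; a
#' feature is selected when `p < alpha` and BH fdr `< fdr_alpha`.
#'
#' @inheritParams diff_wilcoxon
#' @param fdr_alpha BH fdr threshold (default 0.05).
#' @return data.frame with `feature`, `statistic` (H), `p_value`, `fdr`,
#'   `selected`.
#' @export
diff_kruskal <- function(x, design, alpha = 0.05, fdr_alpha = 0.05) {
  x <- check_feature_matrix(x)
  check_design_covers(x, design)
  grp <- design$group[match(colnames(x), design$sample_id)]
  sizes <- table(grp)
  if (length(sizes) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  gf <- factor(grp)
  res <- t(apply(x, 1L, function(v) {
    kt <- suppressWarnings(kruskal.test(v, gf))
    c(kt$statistic, kt$p.value)
  }))
  out <- data.frame(feature = rownames(x), statistic = res[, 1],
                    p_value = res[, 2], stringsAsFactors = FALSE)
  ## constant features give H = 0, p = NaN under kruskal.test; treat as null
  out$p_value[is.nan(out$p_value)] <- 1
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$selected <- out$p_value < alpha & out$fdr < fdr_alpha
  rownames(out) <- NULL
  out
}

#' Hypergeometric category enrichment
#'
#' Upper-tail hypergeometric test (P[X >= hits]) of each functional
#' category against a selected feature set, with the unique feature
#' catalogue as background.
#'
#' @param selected character vector of selected feature ids (subset of
#'   `background`).
#' @param background character vector of all feature ids.
#' @param categories named list: category id -> member feature ids.
#' @param alpha,fdr_alpha thresholds; a category is `enriched` when both
#'   are met (defaults 0.05 / 0.05).
#' @return data.frame with `category`, `hits`, `category_size`,
#'   `selection_size`, `background_size`, `p_value`, `fdr`, `enriched`.
#' @export
enrich_hypergeom <- function(selected, background, categories,
                             alpha = 0.05, fdr_alpha = 0.05) {
  selected <- unique(selected); background <- unique(background)
  if (!all(selected %in% background))
    stop("selected features not a subset of the background: ",
         paste(head(setdiff(selected, background), 5L), collapse = ", "),
         call. = FALSE)
  N <- length(background); n <- length(selected)
  rows <- lapply(names(categories), function(cid) {
    members <- intersect(unique(categories[[cid]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- length(intersect(members, selected))
    p <- phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cid, hits = hits, category_size = K,
               selection_size = n, background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(), hits = integer(),
                      category_size = integer(), selection_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      fdr = numeric(), enriched = logical()))
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_value < alpha & out$fdr < fdr_alpha
  rownames(out) <- NULL
  out
}

#' Category-level abundance comparison
#'
#' Sums member-gene abundances per functional category and sample, then
#' compares the two groups per category with the rank-sum test
#' (BH-corrected across categories).
#'
#' @param x gene-by-sample abundance matrix.
#' @param annotation annotation data.frame (see [read_annotation()]); the
#'   `category` column may hold character vectors (multiple categories per
#'   gene).
#' @inheritParams diff_wilcoxon
#' @param fdr_alpha BH threshold (default 0.05), both thresholds must be
#'   met for selection.
#' @return data.frame as [diff_wilcoxon()], one row per category.
#' @export
category_abundance_test <- function(x, annotation, design, group_a, group_b,
                                    alpha = 0.05, fdr_alpha = 0.05) {
  x <- check_feature_matrix(x)
  cats <- annotation$category
  if (is.null(cats)) stop("annotation has no category column", call. = FALSE)
  if (!is.list(cats)) cats <- strsplit(as.character(cats), ";", fixed = TRUE)
  gene2cat <- stats::setNames(cats, annotation$gene_id)
  all_cats <- sort(unique(unlist(cats)))
  all_cats <- all_cats[nzchar(all_cats)]
  cat_tab <- do.call(rbind, lapply(all_cats, function(cc) {
    members <- annotation$gene_id[vapply(gene2cat[annotation$gene_id],
                                         function(v) cc %in% v, logical(1))]
    members <- intersect(members, rownames(x))
    if (length(members) == 0L) {
      message("category '", cc, "' has no member genes in the table; skipped")
      return(NULL)
    }
    colSums(x[members, , drop = FALSE])
  }))
  kept <- all_cats[vapply(all_cats, function(cc) {
    members <- annotation$gene_id[vapply(gene2cat[annotation$gene_id],
                                         function(v) cc %in% v, logical(1))]
    length(intersect(members, rownames(x))) > 0L
  }, logical(1))]
  rownames(cat_tab) <- kept
  diff_wilcoxon(cat_tab, design, group_a, group_b,
                alpha = alpha, fdr_alpha = fdr_alpha)
}

#' Per-sample alpha diversity
#'
#' @param x closed taxon-by-sample matrix (columns sum to 1).
#' @param index `"shannon"` (-sum p log p, natural log), `"simpson"`
#'   (1 - sum p^2) or `"richness"` (number of taxa detected).
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(x, index = c("shannon", "simpson", "richness")) {
  index <- match.arg(index)
  x <- abundance_table(x)
  if (!is_closed(x))
    stop("alpha_diversity needs closed columns (relative abundances)",
         call. = FALSE)
  switch(index,
         shannon  = vegan::diversity(t(x), index = "shannon"),
         simpson  = vegan::diversity(t(x), index = "simpson"),
         richness = colSums(x > 0))
}

#' PCA embedding of samples
#'
#' Principal component analysis of samples in taxon space (features
#' centred, unscaled).
#'
#' @param x feature-by-sample matrix.
#' @param n_components number of components to keep
#'   (`<= min(samples - 1, features)`).
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions, non-increasing) and `rotation`.
#' @export
pca_embed <- function(x, n_components = 2L) {
  x <- check_feature_matrix(x)
  maxc <- min(ncol(x) - 1L, nrow(x))
  if (n_components < 1L || n_components > maxc)
    stop("n_components must be in [1, ", maxc, "]", call. = FALSE)
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = ev[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
}
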