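## Seeded compositional cohort simulator. Latent log-abundances are
## multivariate normal with a correlation structure assembled from
## single-factor modules (loading vectors), then exponentiated and closed
## to relative abundances. Disease cohorts re-draw from the same model
## with the within-module latent correlations transformed (sign-flip,
## decorrelation, strengthening), so every rewired edge is known exactly.

default_log_means <- function(n_taxa)
  seq(log(0.04), log(0.002), length.out = n_taxa)

## Correlation matrix from per-module loading vectors. Each module is
## list(members, loading) with loading scalar or per-member vector;
## modules act as independent latent factors, so R = L L' + diag(1 - sum
## of squared loadings) is positive semi-definite by construction.
modules_to_correlation <- function(n_taxa, modules, taxa = NULL) {
  taxa <- taxa %||% sprintf("t%02d", seq_len(n_taxa))
  L <- matrix(0, n_taxa, max(1L, length(modules)),
              dimnames = list(taxa, NULL))
  for (k in seq_along(modules)) {
    mod <- modules[[k]]
    members <- mod$members
    if (is.character(members)) members <- match(members, taxa)
    lam <- rep_len(mod$loading, length(members))
    L[members, k] <- lam
  }
  tot <- rowSums(L^2)
  if (any(tot >= 1))
    stop("module loadings imply variance > 1 for taxa: ",
         paste(taxa[tot >= 1], collapse = ", "), call. = FALSE)
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(taxa, taxa)
  R
}

check_pd <- function(R) {
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) stop("correlation spec is not positive definite", call. = FALSE)
  invisible(TRUE)
}

draw_cohort <- function(n_samples, R, log_means, sigma_log, sample_ids, seed) {
  with_seed(seed, {
    sdv <- rep_len(sigma_log, nrow(R))
    Sigma <- (sdv %o% sdv) * R
    Z <- MASS::mvrnorm(n_samples, mu = log_means, Sigma = Sigma)
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
    X <- exp(Z)
    X <- X / rowSums(X)
    out <- t(X)
    dimnames(out) <- list(rownames(R), sample_ids)
    abundance_table(out, closed = TRUE)
  })
}

#' Generate a reference (healthy) cohort
#'
#' Latent multivariate-normal log-abundances with a planted correlation
#' structure, exponentiated and closed to relative abundances.
#'
#' @param n_samples number of samples (>= 3).
#' @param n_taxa number of taxa (>= 4).
#' @param modules correlation structure as a list of
#'   `list(members, loading)` factors (see Details), or `NULL` for
#'   independent taxa. Alternatively pass a full correlation matrix via
#'   `correlation`.
#' @param correlation optional explicit correlation matrix (must be
#'   positive definite); overrides `modules`.
#' @param log_means per-taxon latent log mean; default a geometric
#'   abundance profile from 4\% down to 0.2\%.
#' @param sigma_log latent log-scale standard deviation (default 0.6).
#' @param seed RNG seed; same seed gives bit-identical output.
#' @param group group label for sample ids (default `"H"`).
#' @return list with `table` (taxa x samples, closed), `design`
#'   (a [sample_design()]) and `truth` (list: seed, correlation, modules,
#'   log_means, sigma_log).
#' @details Each module is an independent latent factor; members with
#'   loading `lambda` get pairwise latent correlation `lambda_i *
#'   lambda_j`. This single-factor construction keeps the matrix positive
#'   definite for any loadings below 1.
#' @export
generate_reference_cohort <- function(n_samples, n_taxa = 50L,
                                      modules = NULL, correlation = NULL,
                                      log_means = NULL, sigma_log = 0.6,
                                      seed = 1L, group = "H") {
  if (n_samples < 3L) stop("n_samples must be >= 3", call. = FALSE)
  if (n_taxa < 4L) stop("n_taxa must be >= 4", call. = FALSE)
  if (is.null(correlation)) {
    R <- modules_to_correlation(n_taxa, modules %||% list())
  } else {
    R <- correlation
    if (is.null(rownames(R)))
      dimnames(R) <- list(sprintf("t%02d", seq_len(n_taxa)),
                          sprintf("t%02d", seq_len(n_taxa)))
  }
  check_pd(R)
  log_means <- log_means %||% default_log_means(n_taxa)
  ids <- sprintf("%s%02d", group, seq_len(n_samples))
  tab <- draw_cohort(n_samples, R, log_means, sigma_log, ids, seed)
  truth <- list(seed = seed, correlation = R, modules = modules,
                log_means = log_means, sigma_log = sigma_log)
  list(table = tab,
       design = sample_design(ids, rep(group, n_samples), reference = group),
       truth = truth)
}

apply_effect <- function(modules, module_taxa, effect, taxa, loading = NULL) {
  effect <- match.arg(effect, c("sign_flip", "decorrelate", "strengthen",
                                "none"))
  if (effect == "none") return(modules)
  if (is.numeric(module_taxa)) module_taxa <- taxa[module_taxa]
  ## locate the module whose members match; if absent (e.g. strengthening
  ## a previously unstructured set), append a new factor
  idx <- NULL
  for (k in seq_along(modules)) {
    mem <- modules[[k]]$members
    if (is.numeric(mem)) mem <- taxa[mem]
    if (setequal(mem, module_taxa)) { idx <- k; break }
  }
  if (effect == "strengthen") {
    lam <- loading %||% 0.9
    if (is.null(idx)) {
      modules[[length(modules) + 1L]] <- list(members = module_taxa,
                                              loading = lam)
    } else {
      modules[[idx]]$loading <- lam
    }
    return(modules)
  }
  if (is.null(idx))
    stop("module_taxa do not match a reference module; only 'strengthen' ",
         "can create new structure", call. = FALSE)
  k <- length(module_taxa)
  lam <- rep_len(modules[[idx]]$loading, k)
  if (effect == "decorrelate") {
    modules[[idx]]$loading <- rep(0, k)
  } else { # sign_flip: flip the second half of the module's loadings
    flip <- seq.int(k %/% 2 + 1L, k)
    lam[flip] <- -lam[flip]
    modules[[idx]]$loading <- lam
  }
  modules
}

#' Generate a disease cohort with a rewired module
#'
#' Re-draws samples from the reference latent model after transforming the
#' within-module correlations: `"sign_flip"` flips the loadings of half
#' the module members (so cross-half edges change sign), `"decorrelate"`
#' removes the module structure, `"strengthen"` sets the module loadings
#' to `loading` (creating structure where the reference had none, e.g. a
#' disease-specific hub star), `"none"` re-draws unchanged.
#'
#' @param reference result of [generate_reference_cohort()] (its `truth`
#'   is used).
#' @param module_taxa module members (taxon ids or indices), >= 2.
#' @param effect one of `"sign_flip"`, `"decorrelate"`, `"strengthen"`,
#'   `"none"`.
#' @param n_samples number of disease samples.
#' @param seed RNG seed.
#' @param group group label (default `"D"`).
#' @param loading for `"strengthen"`: new loading(s) for the module
#'   members (scalar or per-member, default 0.9).
#' @return list with `table`, `design` (single group) and `truth`; the
#'   truth records `module`, `effect` and `rewired_edges` (data.frame with
#'   per-edge correlation before/after).
#' @export
generate_disease_cohort <- function(reference, module_taxa, effect,
                                    n_samples, seed = 2L, group = "D",
                                    loading = NULL) {
  rt <- reference$truth
  taxa <- rownames(rt$correlation)
  if (is.numeric(module_taxa)) module_taxa <- taxa[module_taxa]
  if (length(module_taxa) < 2L)
    stop("module must have >= 2 taxa", call. = FALSE)
  if (!all(module_taxa %in% taxa))
    stop("module taxa outside the reference taxon set", call. = FALSE)
  modules2 <- apply_effect(rt$modules %||% list(), module_taxa, effect,
                           taxa, loading = loading)
  R2 <- modules_to_correlation(length(taxa), modules2, taxa = taxa)
  check_pd(R2)
  ids <- sprintf("%s%02d", group, seq_len(n_samples))
  tab <- draw_cohort(n_samples, R2, rt$log_means, rt$sigma_log, ids, seed)
  changed <- which(abs(R2 - rt$correlation) > 1e-12 & upper.tri(R2),
                   arr.ind = TRUE)
  rewired <- data.frame(taxon_i = taxa[changed[, 1]],
                        taxon_j = taxa[changed[, 2]],
                        before = rt$correlation[changed],
                        after = R2[changed], stringsAsFactors = FALSE)
  truth <- list(seed = seed, correlation = R2, modules = modules2,
                module = module_taxa, effect = effect,
                rewired_edges = rewired,
                log_means = rt$log_means, sigma_log = rt$sigma_log)
  list(table = tab,
       design = sample_design(ids, rep(group, n_samples), reference = group),
       truth = truth)
}

#' Simulate a full multi-group study cohort
#'
#' The `"paper"` scenario mirrors the study design this package validates
#' against: three groups of five samples (healthy reference H, and two
#' disease groups G and I), 50 taxa, and one six-taxon module per disease
#' group (distinct modules, placed on the most abundant taxa) whose
#' within-module correlations are sign-flipped relative to the reference.
#'
#' @param scenario `"paper"` or `"custom"`.
#' @param seed RNG seed.
#' @param n_per_group samples per group (default 5).
#' @param n_taxa number of taxa (default 50).
#' @param module_size taxa per planted module (default 6).
#' @param loading module factor loading (default 0.9, within-module latent
#'   correlation 0.81).
#' @param effect rewiring effect for disease groups (default
#'   `"sign_flip"`).
#' @param groups disease group labels (default `c("G", "I")`).
#' @param out_dir optional directory: writes `abundance.tsv`,
#'   `design.tsv` and `truth.json`.
#' @return list with `table` (taxa x all samples), `design`, and `truth`
#'   (per-group module membership, rewired edges, seeds).
#' @export
simulate_cohort <- function(scenario = c("paper", "custom"), seed = 1L,
                            n_per_group = 5L, n_taxa = 50L,
                            module_size = 6L, loading = 0.9,
                            effect = "sign_flip", groups = c("G", "I"),
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  modules <- lapply(seq_along(groups), function(k)
    list(members = taxa[seq_len(module_size) + (k - 1L) * module_size],
         loading = loading))
  ref <- generate_reference_cohort(n_per_group, n_taxa, modules = modules,
                                   seed = seed, group = "H")
  parts <- list(H = ref)
  for (k in seq_along(groups)) {
    parts[[groups[k]]] <- generate_disease_cohort(
      ref, modules[[k]]$members, effect, n_per_group,
      seed = seed + 1000L * k, group = groups[k])
  }
  tab <- do.call(cbind, lapply(parts, function(p) p$table))
  tab <- abundance_table(tab, closed = TRUE)
  ids <- colnames(tab)
  grp <- rep(names(parts), each = n_per_group)
  design <- sample_design(ids, grp, reference = "H")
  truth <- list(seed = seed, scenario = scenario,
                groups = stats::setNames(lapply(seq_along(groups), function(k)
                  list(module = modules[[k]]$members,
                       effect = effect,
                       rewired_edges = parts[[groups[k]]]$truth$rewired_edges)),
                  groups),
                reference_correlation = ref$truth$correlation,
                log_means = ref$truth$log_means,
                sigma_log = ref$truth$sigma_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_abundance(tab, file.path(out_dir, "abundance.tsv"))
    write.table(design, file.path(out_dir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tr <- truth
    tr$reference_correlation <- NULL  # large; regenerate from seed instead
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, design = design, truth = truth)
}

#' Generate a gene-level count table from a taxon table
#'
#' Splits each taxon's abundance over a set of genes (fixed random simplex
#' weights per taxon), assigns gene lengths, and converts to integer read
#' counts at a given sequencing depth, so that the abundance-derivation
#' chain (length normalisation, closure, taxon aggregation) can be
#' exercised against a known answer.
#'
#' @param taxa_table closed taxon-by-sample matrix.
#' @param genes_per_taxon genes per taxon (default 5).
#' @param length_range gene length range in bp (default 300--3000).
#' @param depth reads per sample (default 1e5).
#' @param n_categories number of functional category labels to assign
#'   (default 10).
#' @param seed RNG seed.
#' @return list with `counts` (gene x sample integer matrix),
#'   `gene_lengths` (named), and `annotation` (gene_id, species, genus,
#'   category data.frame; genus groups three consecutive species).
#' @export
generate_gene_table <- function(taxa_table, genes_per_taxon = 5L,
                                length_range = c(300L, 3000L),
                                depth = 1e5, n_categories = 10L, seed = 1L) {
  if (genes_per_taxon < 1L) stop("genes_per_taxon must be >= 1", call. = FALSE)
  taxa <- rownames(taxa_table)
  with_seed(seed, {
    genes <- as.vector(t(outer(taxa, seq_len(genes_per_taxon),
                               function(t, g) sprintf("%s_g%d", t, g))))
    lens <- sample(length_range[1]:length_range[2], length(genes),
                   replace = TRUE)
    names(lens) <- genes
    ## fixed per-taxon simplex split, shared across samples
    w <- numeric(length(genes))
    for (i in seq_along(taxa)) {
      idx <- (i - 1L) * genes_per_taxon + seq_len(genes_per_taxon)
      wi <- stats::rgamma(genes_per_taxon, shape = 1)
      w[idx] <- wi / sum(wi)
    }
    ## length-normalised gene abundance target: a[g, s] = x[taxon, s] * w[g]
    a <- taxa_table[rep(seq_along(taxa), each = genes_per_taxon), ,
                    drop = FALSE] * w
    rownames(a) <- genes
    ## counts = a * length, scaled so each sample totals `depth` reads
    raw <- a * lens
    counts <- round(sweep(raw, 2L, colSums(raw), "/") * depth)
    storage.mode(counts) <- "integer"
    genus <- sprintf("genus%02d", (match(rep(taxa, each = genes_per_taxon),
                                         taxa) - 1L) %/% 3L + 1L)
    cats <- replicate(length(genes),
                      sort(sample(sprintf("K%02d", seq_len(n_categories)),
                                  sample(1:3, 1))), simplify = FALSE)
    annotation <- data.frame(gene_id = genes,
                             species = rep(taxa, each = genes_per_taxon),
                             genus = genus, stringsAsFactors = FALSE)
    annotation$category <- cats
    list(counts = counts, gene_lengths = lens, annotation = annotation)
  })
}
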