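## Abundance tables are plain numeric matrices, taxa (or genes) in rows,
## samples in columns, with unique dimnames. Relative-abundance tables carry
## attr "closed" = TRUE once every column sums to 1.

#' Validate and tag a taxon-by-sample abundance matrix
#'
#' @param x numeric matrix, taxa in rows, samples in columns, with unique
#'   row and column names.
#' @param closed if `TRUE`, require every column to sum to 1 (tolerance
#'   `1e-9`) and tag the matrix as closed.
#' @return the validated matrix (invisibly the same object, with a
#'   `closed` attribute).
#' @export
abundance_table <- function(x, closed = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table needs row (taxon) and column (sample) names", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundance values must be finite and non-negative", call. = FALSE)
  if (closed) {
    cs <- colSums(x)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad))
      stop("columns not closed to 1: ", paste(colnames(x)[bad], collapse = ", "),
           call. = FALSE)
  }
  attr(x, "closed") <- closed
  x
}

is_closed <- function(x) isTRUE(attr(x, "closed")) ||
  all(abs(colSums(x) - 1) <= 1e-9)

## Looser validator for feature matrices fed to the generic statistics
## (values need not be abundances, e.g. transformed data).
check_feature_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric feature-by-sample matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature matrix needs row and column names", call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate feature or sample ids", call. = FALSE)
  x
}

#' Sample-to-group design
#'
#' Builds the design object mapping sample ids to group labels, with one
#' group designated as the healthy reference cohort.
#'
#' @param sample_ids character vector of sample ids.
#' @param groups character vector of group labels, parallel to `sample_ids`.
#' @param reference the reference (healthy) group label; must occur in
#'   `groups`.
#' @return a data.frame with columns `sample_id` and `group`, and attribute
#'   `reference`.
#' @export
sample_design <- function(sample_ids, groups, reference = "H") {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups))
    stop("sample_ids and groups must have equal length", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in design", call. = FALSE)
  if (!nzchar(reference) || !reference %in% groups)
    stop("reference group '", reference, "' absent from design", call. = FALSE)
  d <- data.frame(sample_id = sample_ids, group = groups,
                  stringsAsFactors = FALSE)
  attr(d, "reference") <- reference
  d
}

design_reference <- function(design) attr(design, "reference") %||% "H"

design_samples <- function(design, group) {
  design$sample_id[design$group == group]
}

check_design_covers <- function(x, design) {
  missing <- setdiff(colnames(x), design$sample_id)
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Length-normalised gene abundance
#'
#' Divides mapped read counts by gene length (in bp), the first step in
#' deriving relative abundances from a metagenomic gene catalogue.
#'
#' @param counts gene-by-sample matrix of non-negative mapped-read counts.
#' @param gene_lengths positive gene lengths (bp), one per row of `counts`;
#'   may be a named vector matched by gene id.
#' @return matrix of the same shape, `counts[g, s] / gene_lengths[g]`.
#' @export
gene_abundance <- function(counts, gene_lengths) {
  counts <- abundance_table(counts)
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || anyNA(gene_lengths))
    stop("gene_lengths must cover every gene in the count table", call. = FALSE)
  if (any(!is.finite(gene_lengths)) || any(gene_lengths < 1))
    stop("gene lengths must be positive (>= 1 bp)", call. = FALSE)
  counts / gene_lengths
}

#' Close columns to relative abundances
#'
#' Divides each sample column by its sum so that abundances are fractions
#' summing to one per sample.
#'
#' @param x abundance matrix (any non-negative values).
#' @return closed abundance matrix (columns sum to 1).
#' @export
relative_abundance <- function(x) {
  x <- abundance_table(x)
  cs <- colSums(x)
  zero <- which(cs == 0)
  if (length(zero))
    stop("cannot close all-zero sample(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  out <- sweep(x, 2, cs, "/")
  abundance_table(out, closed = TRUE)
}

#' Aggregate gene abundances to taxa
#'
#' Sums gene-level abundances over genes annotated to the same taxon at the
#' requested rank. Genes without an annotation are collected under the
#' reserved `"unassigned"` label so that per-sample totals are conserved;
#' the unassigned row is reported but should be excluded from network
#' analyses.
#'
#' @param x gene-by-sample abundance matrix.
#' @param annotation data.frame with columns `gene_id`, `species`, `genus`
#'   (and optionally `category`); see [read_annotation()].
#' @param rank `"species"` or `"genus"`.
#' @param reclose re-close columns after dropping the unassigned mass
#'   (default `FALSE`; totals are then conserved exactly).
#' @return taxon-by-sample matrix; attribute `unassigned_genes` lists genes
#'   that fell in the reserved bucket.
#' @export
aggregate_taxa <- function(x, annotation, rank = c("species", "genus"),
                           reclose = FALSE) {
  rank <- match.arg(rank)
  x <- abundance_table(x)
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop("empty annotation map", call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("gene annotated more than once: ",
         paste(unique(annotation$gene_id[duplicated(annotation$gene_id)]),
               collapse = ", "), call. = FALSE)
  lab <- annotation[[rank]][match(rownames(x), annotation$gene_id)]
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  groups <- split(seq_len(nrow(x)), lab)
  out <- do.call(rbind, lapply(groups, function(idx)
    colSums(x[idx, , drop = FALSE])))
  rownames(out) <- names(groups)
  ## unassigned last, named taxa in first-appearance order
  ord <- c(setdiff(unique(lab), "unassigned"), intersect("unassigned", rownames(out)))
  out <- out[ord, , drop = FALSE]
  if (reclose) {
    out <- out[setdiff(rownames(out), "unassigned"), , drop = FALSE]
    out <- relative_abundance(out)
  }
  attr(out, "unassigned_genes") <- rownames(x)[lab == "unassigned"]
  out
}

#' Remove rarely detected features
#'
#' Drops features (genes or taxa) with a non-zero value in fewer than
#' `min_samples` samples; "detected" means strictly positive.
#'
#' @param x feature-by-sample matrix.
#' @param min_samples minimum number of samples a feature must be detected
#'   in to survive (>= 1).
#' @return list with `table` (survivors, original order preserved) and
#'   `removed` (dropped feature ids).
#' @export
prevalence_filter <- function(x, min_samples) {
  x <- abundance_table(x)
  if (!is.numeric(min_samples) || length(min_samples) != 1L || min_samples < 1)
    stop("min_samples must be a single integer >= 1", call. = FALSE)
  detected <- rowSums(x > 0)
  keep <- detected >= min_samples
  if (!any(keep))
    message("prevalence_filter removed every feature")
  list(table = x[keep, , drop = FALSE], removed = rownames(x)[!keep])
}

#' Read / write abundance tables as TSV
#'
#' Tab-separated, UTF-8, header row of sample ids, first column of
#' feature ids. Round-trips to within 1e-12.
#'
#' @param path file path.
#' @return for `read_abundance`, a feature-by-sample numeric matrix.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("abundance TSV needs a feature-id column plus >= 1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]]))
      stop("non-numeric cell(s) in column '", colnames(vals)[j], "' of ", path,
           call. = FALSE)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  abundance_table(m)
}

#' @rdname read_abundance
#' @param x feature-by-sample matrix to write.
#' @param id_column header for the feature-id column (default `"taxon_id"`).
#' @export
write_abundance <- function(x, path, id_column = "taxon_id") {
  x <- abundance_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene annotation map
#'
#' Four-column TSV: `gene_id`, `species`, `genus`, `category` (categories
#' semicolon-separated, may be empty).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `species`, `genus`,
#'   `category` (list column of character vectors).
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("gene_id", "species", "genus")
  if (!all(need %in% colnames(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"category" %in% colnames(df)) df$category <- ""
  df$category <- strsplit(as.character(df$category), ";", fixed = TRUE)
  df
}
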