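# Small deterministic fixtures and independent oracles used across tests.

# Independent Pearson correlation via the cross-product formula (never
# stats::cor), used to brute-force the sPCC contracts.
pearson_manual <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  num / den
}

spcc_manual <- function(ref_data, sample, i, j) {
  a <- c(ref_data[i, ], sample[i])
  b <- c(ref_data[j, ], sample[j])
  pearson_manual(a, b) - pearson_manual(ref_data[i, ], ref_data[j, ])
}

# 4-taxon, 5-reference-sample toy on which everything can be hand-checked.
toy_reference <- function() {
  x <- rbind(
    t1 = c(0.40, 0.35, 0.45, 0.38, 0.42),
    t2 = c(0.30, 0.28, 0.33, 0.25, 0.34),
    t3 = c(0.20, 0.22, 0.12, 0.27, 0.14),
    t4 = c(0.10, 0.15, 0.10, 0.10, 0.10))
  colnames(x) <- paste0("H", 1:5)
  x
}

toy_design <- function() {
  sample_design(paste0("H", 1:5), rep("H", 5), reference = "H")
}

random_reference <- function(seed, n_ref, n_taxa) {
  set.seed(seed)
  x <- matrix(abs(rnorm(n_taxa * n_ref, 1, 0.4)), n_taxa, n_ref,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("H%02d", seq_len(n_ref))))
  x <- sweep(x, 2, colSums(x), "/")
  fit_reference(abundance_table(x, closed = TRUE),
                sample_design(colnames(x), rep("H", n_ref)))
}

random_sample_vec <- function(seed, taxa) {
  set.seed(seed)
  v <- abs(rnorm(length(taxa), 1, 0.4))
  stats::setNames(v / sum(v), taxa)
}
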