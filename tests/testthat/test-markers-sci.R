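test_that("edge-biomarker selection takes the union of top edge-pair taxa", {
  ps <- data.frame(edge1 = c("A~B", "A~B", "C~D"),
                   edge2 = c("C~D", "E~F", "E~F"),
                   score = c(0.9, 0.5, 0.1), stringsAsFactors = FALSE)
  expect_equal(as.character(select_edge_biomarkers(ps, 1)),
               c("A", "B", "C", "D"))
  # m beyond the available pairs saturates at all incident taxa
  expect_equal(as.character(select_edge_biomarkers(ps, 10)),
               c("A", "B", "C", "D", "E", "F"))
  expect_error(select_edge_biomarkers(ps[0, ], 1), "no edge-pairs")
})

test_that("edge-biomarker ranking matches a sort-and-union oracle", {
  set.seed(31)
  for (r in 1:10) {
    labs <- paste0("t", 1:8)
    pairs <- t(combn(paste(labs[1:4], labs[5:8], sep = "~"), 2))
    ps <- data.frame(edge1 = pairs[, 1], edge2 = pairs[, 2],
                     score = rnorm(nrow(pairs)), stringsAsFactors = FALSE)
    got <- select_edge_biomarkers(ps, 3)
    ord <- order(-abs(ps$score), ps$edge1, ps$edge2)
    top <- ps[ord[1:3], ]
    want <- sort(unique(unlist(strsplit(c(top$edge1, top$edge2), "~"))))
    expect_equal(as.character(got), want)
  }
})

test_that("sCI reproduces a hand-worked micro-example exactly", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  v <- stats::setNames(c(0.50, 0.22, 0.18, 0.10), rownames(x))
  marker <- c("t1", "t2")
  got <- compute_sci(ref, v, marker)
  # manual evaluation of the three factors with the independent oracle
  pin <- abs(spcc_manual(x, v, "t1", "t2"))
  pout <- mean(c(abs(spcc_manual(x, v, "t1", "t3")),
                 abs(spcc_manual(x, v, "t1", "t4")),
                 abs(spcc_manual(x, v, "t2", "t3")),
                 abs(spcc_manual(x, v, "t2", "t4"))))
  sdin <- mean(c(abs(v["t1"] - mean(x["t1", ])),
                 abs(v["t2"] - mean(x["t2", ]))))
  expect_equal(got$pcc_in, pin, tolerance = 1e-10)
  expect_equal(got$pcc_out, pout, tolerance = 1e-10)
  expect_equal(got$sd_in, sdin, tolerance = 1e-10)
  expect_equal(got$sci, pin / pout * sdin, tolerance = 1e-10)
})

test_that("sCI degenerate cases behave as specified", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  # sample exactly at the reference means: deviation term zero -> sci 0
  v0 <- ref$mean
  got <- compute_sci(ref, v0, c("t1", "t2"))
  expect_equal(got$sd_in, 0)
  expect_equal(got$sci, 0)
  # singleton marker: no within pairs, sci defined as 0 and flagged
  v <- stats::setNames(c(0.5, 0.2, 0.2, 0.1), rownames(x))
  s1 <- compute_sci(ref, v, "t1")
  expect_equal(s1$pcc_in, 0)
  expect_equal(s1$sci, 0)
  expect_equal(s1$flag, "singleton_marker")
  # marker = universe rejected; empty rejected
  expect_error(compute_sci(ref, v, rownames(x)), "universe")
  expect_error(compute_sci(ref, v, character()), "empty")
  # all marker sPCC zero -> pcc_in 0 -> sci 0 (forced via crafted spcc)
  sp <- matrix(0.3, 4, 4, dimnames = list(rownames(x), rownames(x)))
  sp["t1", "t2"] <- sp["t2", "t1"] <- 0
  diag(sp) <- 0
  z <- compute_sci(ref, v, c("t1", "t2"), spcc = sp)
  expect_equal(z$pcc_in, 0)
  expect_equal(z$sci, 0)
  # pcc_out = 0 with nonzero pcc_in -> Inf sentinel, flagged
  sp2 <- matrix(0, 4, 4, dimnames = dimnames(sp))
  sp2["t1", "t2"] <- sp2["t2", "t1"] <- 0.5
  z2 <- compute_sci(ref, v, c("t1", "t2"), spcc = sp2)
  expect_true(is.infinite(z2$sci))
  expect_equal(z2$flag, "zero_pcc_out")
})

test_that("sCI is invariant to relabelling non-marker taxa and linear in sd_in", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  v <- stats::setNames(c(0.5, 0.2, 0.2, 0.1), rownames(x))
  base <- compute_sci(ref, v, c("t1", "t2"))
  # relabel the two non-marker taxa (swap rows consistently everywhere)
  x2 <- x[c("t1", "t2", "t4", "t3"), ]
  rownames(x2) <- c("t1", "t2", "t3", "t4")
  ref2 <- fit_reference(abundance_table(x2), toy_design())
  v2 <- stats::setNames(v[c("t1", "t2", "t4", "t3")], rownames(x2))
  expect_equal(compute_sci(ref2, v2, c("t1", "t2"))$sci, base$sci,
               tolerance = 1e-12)
  # holding the correlation factors fixed, sci is linear in sd_in
  sp <- spcc_matrix(ref, v)
  s1 <- compute_sci(ref, v, c("t1", "t2"), spcc = sp)
  vshift <- v
  vshift[c("t1", "t2")] <- ref$mean[c("t1", "t2")] +
    2 * (v[c("t1", "t2")] - ref$mean[c("t1", "t2")])
  s2 <- compute_sci(ref, vshift, c("t1", "t2"), spcc = sp)
  expect_equal(s2$sci, 2 * s1$sci, tolerance = 1e-12)
})

test_that("union markers pool group samples with recurrence support", {
  d <- sample_design(c("a", "b", "c"), c("G", "G", "I"), reference = "G")
  mk <- list(a = c("A", "B"), b = c("B", "C"), c = c("X"))
  u <- union_markers(mk, d, "G")
  expect_equal(as.character(u), c("A", "B", "C"))
  expect_equal(attr(u, "support")[["B"]], 1)
  expect_equal(attr(u, "support")[["A"]], 0.5)
  # recurrence filter keeps only majority taxa
  expect_equal(as.character(union_markers(mk, d, "G", min_support = 0.6)), "B")
  # single-sample group: union is that sample's markers
  expect_equal(as.character(union_markers(mk, d, "I")), "X")
  expect_error(union_markers(mk, d, "Z"), "no samples")
  # counting oracle on random sets
  set.seed(12)
  mk2 <- lapply(1:5, function(i) sample(LETTERS[1:6], sample(2:4, 1)))
  names(mk2) <- paste0("s", 1:5)
  d2 <- sample_design(names(mk2), rep("G", 5), reference = "G")
  u2 <- union_markers(mk2, d2, "G")
  expect_equal(as.character(u2), sort(unique(unlist(mk2))))
  tab <- table(unlist(mk2)) / 5
  expect_equal(attr(u2, "support"), c(tab[order(names(tab))]))
})

test_that("two cohorts from the same model show no systematic sCI difference", {
  pvals <- vapply(1:50, function(r) {
    ref <- generate_reference_cohort(5, 12, modules = list(
      list(members = c("t01", "t02", "t03"), loading = 0.9)),
      seed = 7000 + r)
    a <- generate_disease_cohort(ref, c("t01", "t02", "t03"), "none", 5,
                                 seed = 7100 + r, group = "A")
    b <- generate_disease_cohort(ref, c("t01", "t02", "t03"), "none", 5,
                                 seed = 7200 + r, group = "B")
    rm <- fit_reference(ref$table, ref$design)
    marker <- c("t01", "t02", "t03")
    sa <- vapply(colnames(a$table), function(s)
      compute_sci(rm, a$table[, s], marker)$sci, numeric(1))
    sb <- vapply(colnames(b$table), function(s)
      compute_sci(rm, b$table[, s], marker)$sci, numeric(1))
    suppressWarnings(wilcox.test(sa, sb)$p.value)
  }, numeric(1))
  # exchangeable cohorts: significant differences at the nominal rate only
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("group discrimination report orders groups and assigns samples", {
  sim <- simulate_cohort(seed = 42)
  fit <- iena(sim$table, sim$design)
  gm <- fit$sci$group_means
  # each disease group's own-marker mean exceeds the healthy mean
  expect_gt(gm["G", "G"], gm["G", "H"])
  expect_gt(gm["I", "I"], gm["I", "H"])
  expect_true(all(c("sample", "group", "assigned") %in%
                  colnames(fit$sci$assignment)))
  expect_gte(fit$sci$accuracy, 0.5)
})
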