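test_that("reference model reproduces hand-computed Pearson correlations", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  for (i in rownames(x)) for (j in rownames(x)) {
    expect_equal(ref$cor[i, j],
                 if (i == j) 1 else pearson_manual(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }
  expect_equal(ref$mean, rowMeans(x))
  # symmetric, unit diagonal, bounded
  expect_equal(ref$cor, t(ref$cor))
  expect_true(all(abs(ref$cor) <= 1 + 1e-12))
})

test_that("constant reference taxa are excluded and small cohorts rejected", {
  x <- toy_reference()
  x["t4", ] <- 0.1
  ref <- fit_reference(abundance_table(x), toy_design())
  expect_equal(ref$dropped, "t4")
  expect_false("t4" %in% rownames(ref$cor))
  expect_error(fit_reference(abundance_table(x[, 1:2]),
                             sample_design(colnames(x)[1:2], c("H", "H"))),
               ">= 3 reference samples")
  # perfectly collinear taxa have reference PCC 1
  x2 <- toy_reference()
  x2["t2", ] <- 2 * x2["t1", ]
  ref2 <- fit_reference(abundance_table(x2), toy_design())
  expect_equal(ref2$cor["t1", "t2"], 1)
})

test_that("sPCC equals the brute-force two-correlation recomputation", {
  set.seed(101)
  seeds <- sample.int(1e6, 100)
  worst <- 0
  for (s in seeds) {
    n_ref <- sample(3:20, 1)
    n_taxa <- sample(4:50, 1)
    ref <- random_reference(s, n_ref, n_taxa)
    v <- random_sample_vec(s + 1, rownames(ref$data))
    taxa <- rownames(ref$data)
    i <- sample(taxa, 1); j <- sample(setdiff(taxa, i), 1)
    got <- spcc(ref, v, i, j)
    want <- spcc_manual(ref$data, v, i, j)
    worst <- max(worst, abs(got - want))
    # symmetry
    expect_identical(got, spcc(ref, v, j, i))
  }
  expect_lt(worst, 1e-10)
})

test_that("sPCC is a bounded perturbation that vanishes when nothing changes", {
  # collinear reference pair plus a sample on the same line: no perturbation
  x <- toy_reference()
  x["t2", ] <- 2 * x["t1", ]
  ref <- fit_reference(abundance_table(x), toy_design())
  v <- stats::setNames(c(0.5, 1.0, 0.2, 0.12), rownames(x))
  expect_equal(spcc(ref, v, "t1", "t2"), 0, tolerance = 1e-12)
  # bounds over random instances
  set.seed(42)
  for (r in 1:20) {
    ref2 <- random_reference(2000 + r, 5, 12)
    v2 <- random_sample_vec(3000 + r, rownames(ref2$data))
    m <- spcc_matrix(ref2, v2)
    expect_true(all(abs(m) <= 2 + 1e-12))
  }
})

test_that("edge profiles are reference-standardised products", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  # a sample exactly at the reference means scores 0 on every edge
  at_mean <- ref$mean
  expect_equal(unname(edge_profile(ref, "t1", "t2",
                                   matrix(at_mean, ncol = 1,
                                          dimnames = list(names(at_mean), "s")))),
               0)
  # both z-values 1 gives edge variable 1
  v1 <- ref$mean + ref$sd
  expect_equal(unname(edge_profile(ref, "t1", "t3",
                                   matrix(v1, ncol = 1,
                                          dimnames = list(names(v1), "s")))),
               1)
  # manual standardisation on the toy
  prof <- edge_profile(ref, "t1", "t2")
  man <- ((x["t1", ] - mean(x["t1", ])) / sd(x["t1", ])) *
         ((x["t2", ] - mean(x["t2", ])) / sd(x["t2", ]))
  expect_equal(prof, man)
})

test_that("top-edge selection ranks, breaks ties lexicographically, caps k", {
  x <- toy_reference()
  ref <- fit_reference(abundance_table(x), toy_design())
  all_edges <- select_top_edges(ref, k = 6)
  # matches a brute-force sort on |reference correlation|
  ut <- which(upper.tri(ref$cor), arr.ind = TRUE)
  sc <- abs(ref$cor)[ut]
  expect_equal(sort(all_edges$score, decreasing = TRUE), sort(sc, decreasing = TRUE))
  expect_equal(all_edges$rank, 1:6)
  top2 <- select_top_edges(ref, k = 2)
  expect_equal(top2$score, sort(sc, decreasing = TRUE)[1:2])
  # k beyond the number of pairs returns all with a message
  expect_message(big <- select_top_edges(ref, k = 100), "keeping all")
  expect_equal(nrow(big), 6)
  # exact ties fall back to lexicographic pair order
  xt <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(3, 6, 9, 12),
              d = c(4, 3, 7, 1))
  colnames(xt) <- paste0("H", 1:4)
  reft <- fit_reference(abundance_table(xt),
                        sample_design(colnames(xt), rep("H", 4)))
  e <- select_top_edges(reft, k = 3)
  # a~b, a~c, b~c all have |r| = 1
  expect_equal(paste(e$taxon_i, e$taxon_j)[1:3], c("a b", "a c", "b c"))
})

test_that("max-|sPCC| edge ranking agrees with a full-sort oracle", {
  ref <- random_reference(7, 6, 10)
  vs <- lapply(1:3, function(k) random_sample_vec(500 + k, rownames(ref$data)))
  sp <- lapply(vs, function(v) spcc_matrix(ref, v))
  e <- select_top_edges(ref, k = 50, rank_by = "spcc", spcc_list = sp)
  A <- Reduce(pmax, lapply(sp, abs))
  manual <- sort(A[upper.tri(A)], decreasing = TRUE)[1:45]
  expect_equal(e$score, manual)
})

test_that("fourth-order sPCC equals the materialised-profile oracle", {
  set.seed(77)
  worst <- 0
  for (r in 1:100) {
    n_ref <- sample(4:12, 1)
    ref <- random_reference(9000 + r, n_ref, 8)
    v <- random_sample_vec(9500 + r, rownames(ref$data))
    taxa <- rownames(ref$data)
    e1 <- sample(taxa, 2); e2 <- sample(setdiff(taxa, e1), 2)
    got <- fourth_order_spcc(ref, v, e1, e2)
    # oracle: materialise both profiles with manual z-scores, correlate twice
    zprof <- function(pair, data) {
      zi <- (data[pair[1], ] - mean(ref$data[pair[1], ])) / sd(ref$data[pair[1], ])
      zj <- (data[pair[2], ] - mean(ref$data[pair[2], ])) / sd(ref$data[pair[2], ])
      zi * zj
    }
    p1 <- zprof(e1, ref$data); p2 <- zprof(e2, ref$data)
    s1 <- zprof(e1, matrix(v, ncol = 1, dimnames = list(names(v), "s")))
    s2 <- zprof(e2, matrix(v, ncol = 1, dimnames = list(names(v), "s")))
    want <- pearson_manual(c(p1, s1), c(p2, s2)) - pearson_manual(p1, p2)
    worst <- max(worst, abs(got - want))
    # symmetry in the two edges
    expect_equal(got, fourth_order_spcc(ref, v, e2, e1), tolerance = 1e-12)
  }
  expect_lt(worst, 1e-10)
})

test_that("duplicated edge profiles give a zero fourth-order score", {
  # e2 collinear with e1 over reference and sample: both correlations 1
  x <- toy_reference()
  x["t3", ] <- 3 * x["t1", ]
  x["t4", ] <- 2 * x["t2", ]
  ref <- fit_reference(abundance_table(x), toy_design())
  v <- stats::setNames(c(0.4, 0.3, 1.2, 0.6), rownames(x))
  # profiles of (t1,t2) and (t3,t4) are proportional by construction
  expect_equal(fourth_order_spcc(ref, v, c("t1", "t2"), c("t3", "t4")), 0,
               tolerance = 1e-10)
})

test_that("restricting to pre-selected edges never changes a pair's score", {
  ref <- random_reference(55, 6, 10)
  v <- random_sample_vec(56, rownames(ref$data))
  all_edges <- select_top_edges(ref, k = 45)
  few_edges <- all_edges[c(1, 5, 9, 20), ]
  full <- edge_pair_scores(ref, v, all_edges)
  sub <- edge_pair_scores(ref, v, few_edges)
  key <- function(d) paste(d$edge1, d$edge2)
  shared <- intersect(key(full), key(sub))
  expect_gt(length(shared), 0)
  expect_equal(full$score[match(shared, key(full))],
               sub$score[match(shared, key(sub))])
})

test_that("no false perturbation signal without rewiring", {
  # disease-like and held-out reference-like cohorts drawn from the same
  # model should show the same mean |sPCC|; paired difference ~ 0
  diffs <- vapply(1:50, function(r) {
    ref <- generate_reference_cohort(5, 12, seed = 4000 + r)
    a <- generate_disease_cohort(ref, c("t01", "t02"), "none", 5,
                                 seed = 5000 + r, group = "A")
    b <- generate_disease_cohort(ref, c("t01", "t02"), "none", 5,
                                 seed = 6000 + r, group = "B")
    rm <- fit_reference(ref$table, ref$design)
    m <- function(tab) mean(vapply(colnames(tab), function(s)
      mean(abs(spcc_matrix(rm, tab[, s]))), numeric(1)))
    m(a$table) - m(b$table)
  }, numeric(1))
  expect_gt(wilcox.test(diffs)$p.value, 0.05)
})
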