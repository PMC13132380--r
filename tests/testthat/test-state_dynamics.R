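test_that("classify_cbs applies the 1.5-fold rule with inclusive boundaries", {
  expect_equal(classify_cbs(3.0, 1.5, pseudocount = 0), "CLUSTER_I_K4_HIGH")
  expect_equal(classify_cbs(1.0, 1.6, pseudocount = 0), "CLUSTER_II_K27_HIGH")
  expect_equal(classify_cbs(5, 5, pseudocount = 0), "CLUSTER_III_EQUAL")
  # ratio exactly 1.5 goes to the high cluster on either side
  expect_equal(classify_cbs(1.5, 1.0, pseudocount = 0), "CLUSTER_I_K4_HIGH")
  expect_equal(classify_cbs(1.0, 1.5, pseudocount = 0), "CLUSTER_II_K27_HIGH")
  expect_error(classify_cbs(-1, 2), "non-negative")
})

test_that("classify_cbs partitions and is symmetric under mark swap", {
  set.seed(31)
  k4 <- stats::rlnorm(500, 1, 1)
  k27 <- stats::rlnorm(500, 1, 1)
  lab <- classify_cbs(k4, k27)
  expect_true(all(lab %in% cbs_levels()[1:3]))
  swapped <- classify_cbs(k27, k4)
  map <- c(CLUSTER_I_K4_HIGH = "CLUSTER_II_K27_HIGH",
           CLUSTER_II_K27_HIGH = "CLUSTER_I_K4_HIGH",
           CLUSTER_III_EQUAL = "CLUSTER_III_EQUAL")
  expect_identical(unname(map[lab]), swapped)
})

test_that("transition table covers shared and one-sided genes", {
  a <- stats::setNames(c("CLUSTER_II_K27_HIGH", "CLUSTER_III_EQUAL",
                         "CLUSTER_I_K4_HIGH"), c("g1", "g2", "g3"))
  b <- stats::setNames(rep("CLUSTER_I_K4_HIGH", 3), c("g1", "g2", "g3"))
  tt <- transition_table(a, b)
  expect_equal(tt$counts["CLUSTER_II_K27_HIGH", "CLUSTER_I_K4_HIGH"], 1L,
               ignore_attr = TRUE)
  expect_equal(tt$counts["CLUSTER_III_EQUAL", "CLUSTER_I_K4_HIGH"], 1L,
               ignore_attr = TRUE)
  expect_equal(tt$counts["CLUSTER_I_K4_HIGH", "CLUSTER_I_K4_HIGH"], 1L,
               ignore_attr = TRUE)
  expect_equal(sum(tt$counts), 3L)

  # gene bivalent in A only -> (label_A, NONBIVALENT)
  tt2 <- transition_table(c(a, g4 = "CLUSTER_I_K4_HIGH"), b)
  rec <- tt2$records[tt2$records$gene_id == "g4", ]
  expect_equal(rec$to, "NONBIVALENT")
  # identical assignments -> diagonal mass only
  tt3 <- transition_table(a, a)
  expect_equal(sum(diag(tt3$counts)), 3L)
  expect_equal(sum(tt3$counts), 3L)
  expect_error(transition_table(a, stats::setNames("CLUSTER_I_K4_HIGH", "zz")),
               "share no genes")
})

test_that("transition row sums conserve condition-A label counts", {
  cfg <- sim_config(n_genes = 800, seed = 13)
  sim <- simulate_chip(simulate_genome(800, 13), cfg)
  la <- stats::setNames(state_to_label[sim$truth$state_a], sim$truth$gene_id)
  lb <- stats::setNames(state_to_label[sim$truth$state_b], sim$truth$gene_id)
  tt <- transition_table(la, lb)
  expect_equal(as.vector(rowSums(tt$counts)),
               as.vector(table(factor(la, levels = cbs_levels()))))
})

test_that("switch_expression_fraction counts induced switch genes", {
  labels_a <- stats::setNames(
    c(rep("CLUSTER_II_K27_HIGH", 6), rep("CLUSTER_III_EQUAL", 4)),
    paste0("g", 1:10))
  labels_b <- stats::setNames(rep("CLUSTER_I_K4_HIGH", 10), paste0("g", 1:10))
  tt <- transition_table(labels_a, labels_b)
  lfc <- stats::setNames(c(rep(1, 9), -1), paste0("g", 1:10))
  out <- switch_expression_fraction(tt, lfc)
  expect_equal(out$fraction, 0.9)
  expect_equal(out$n_switch, 10L)
  # no switches under a definition that never occurs -> error
  expect_error(
    switch_expression_fraction(tt, lfc, switch_definition = list(
      c("CLUSTER_I_K4_HIGH", "CLUSTER_II_K27_HIGH"))),
    "no switch genes")
  expect_error(switch_expression_fraction(tt, lfc[1:5]),
               "without an expression value")
})

test_that("correlation matches the closed-form product-moment oracle", {
  x <- c(0.3, -1.2, 2.5, 0.9, -0.4)
  y <- c(1.1, -0.7, 1.9, 0.2, 0.05)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- bivalency_expression_correlation(x, y)
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  expect_equal(out$n, 5L)
  # p from the t transform with n - 2 df
  tval <- r_direct * sqrt((5 - 2) / (1 - r_direct^2))
  expect_equal(out$p_value, 2 * stats::pt(-abs(tval), df = 3),
               tolerance = 1e-12)
  # exact linear data
  xx <- 1:10
  expect_equal(bivalency_expression_correlation(xx, 2 * xx + 1)$r, 1)
  expect_equal(bivalency_expression_correlation(xx, -xx)$r, -1)
  expect_error(bivalency_expression_correlation(xx, rep(1, 10)),
               "zero variance")
  expect_error(bivalency_expression_correlation(1:2, 1:2), ">= 3")
})

test_that("named correlation inputs are matched by gene id", {
  dm <- stats::setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  # by position these would correlate positively; by gene id, perfectly
  # negatively — name matching must win
  de <- stats::setNames(c(2, 4, 6, 8), c("d", "c", "b", "a"))
  out <- bivalency_expression_correlation(dm, de)
  expect_equal(out$r, -1)
})

test_that("k-means cross-check agrees with threshold labels on simulations", {
  cfg <- sim_config(n_genes = 1500, seed = 17)
  sim <- simulate_chip(simulate_genome(1500, 17), cfg)
  biv <- sim$truth$is_bivalent_a
  k4 <- sim$signal$A[biv, "H3K4me3"]
  k27 <- sim$signal$A[biv, "H3K27me3"]
  lab <- classify_cbs(k4, k27)
  expect_gte(cbs_kmeans_concordance(k4, k27, lab, seed = 17), 0.9)
})
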