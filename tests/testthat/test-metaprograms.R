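test_that("jaccard is a bounded, symmetric set similarity", {
  expect_equal(jaccard(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A"), c("B")), 0)
  expect_equal(jaccard(character(0L), character(0L)), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
  }
})

test_that("NMF factorization is non-negative, deterministic, identifiable", {
  pm <- simulate_program_matrices(n_samples = 2, n_cells_per_sample = 60,
                                  n_genes = 500, baseline_mean = 0,
                                  planted_programs = NULL, seed = 9)
  # default planted programs need >= 450 genes; 500 works
  V <- preprocess_expression(pm$matrices$S1)
  fit <- nmf_factorize(V, 5, seed = 9)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  fit2 <- nmf_factorize(V, 5, seed = 9)
  expect_identical(fit, fit2)
  # zero baseline: each factor's top genes recover one planted block exactly
  tops <- apply(fit$W, 2L, function(w) rownames(V)[order(-w)][1:90])
  rec <- apply(tops, 2L, function(g)
    max(vapply(pm$truth$programs, jaccard, numeric(1L), g)))
  expect_true(all(rec >= 0.9))
  # each planted program matched by some factor
  matched <- apply(tops, 2L, function(g)
    which.max(vapply(pm$truth$programs, jaccard, numeric(1L), g)))
  expect_setequal(matched, 1:5)
  expect_error(nmf_factorize(-V, 3), "non-negative")
  expect_error(nmf_factorize(V, 0), "between 1")
})

test_that("rank sweep yields one instance per factor with top-n gene sets", {
  pm <- simulate_program_matrices(n_samples = 2, n_cells_per_sample = 40,
                                  n_genes = 500, seed = 2)
  inst <- run_nmf_sweep(pm$matrices$S1, ks = 4:9, n_top = 90, seed = 2,
                        sample_id = "S1")
  expect_length(inst, sum(4:9))
  expect_true(all(vapply(inst, function(p) length(p$genes) == 90L,
                         logical(1L))))
  expect_true(all(vapply(inst, function(p) all(p$scores >= 0), logical(1L))))
  # requesting a rank above the matrix dimension skips it with a warning
  small <- pm$matrices$S1[, 1:5]
  expect_warning(inst_small <- run_nmf_sweep(small, ks = c(4, 10), n_top = 20,
                                             seed = 1, sample_id = "S1"),
                 "skipping k = 10")
  expect_length(inst_small, 4L)
})

test_that("greedy clustering obeys recurrence and sample-support rules", {
  g <- function(i) sprintf("gene%03d", i)
  setA <- g(1:30); setB <- g(31:60)
  # program A recurs at two ranks in two samples; program B in one sample only
  inst <- list(
    manual_instance("s1", 4, 1, setA),
    manual_instance("s1", 5, 1, setA),
    manual_instance("s2", 4, 1, setA),
    manual_instance("s2", 5, 2, setA),
    manual_instance("s1", 4, 2, setB),
    manual_instance("s1", 5, 2, setB))
  mps <- cluster_programs(inst, n_top = 30)
  expect_length(mps, 1L)
  expect_setequal(mps[[1L]]$consensus, setA)
  expect_equal(mps[[1L]]$support[["n_samples"]], 2L)

  # all instances identical -> exactly one meta-program holding everything
  same <- list(manual_instance("s1", 4, 1, setA),
               manual_instance("s1", 5, 1, setA),
               manual_instance("s2", 4, 1, setA),
               manual_instance("s2", 5, 1, setA))
  mps2 <- cluster_programs(same, n_top = 30)
  expect_length(mps2, 1L)
  expect_equal(nrow(mps2[[1L]]$members), 4L)

  # an instance with no within-sample partner at another rank is discarded
  lone <- c(same[1:4], list(manual_instance("s3", 4, 1, setB)))
  mps3 <- cluster_programs(lone, n_top = 30)
  expect_length(mps3, 1L)
  expect_setequal(mps3[[1L]]$consensus, setA)

  expect_error(cluster_programs(list()), "no program instances")
})

test_that("every instance joins at most one meta-program", {
  pm <- simulate_program_matrices(n_samples = 3, n_cells_per_sample = 60,
                                  seed = 6)
  inst <- unlist(lapply(names(pm$matrices), function(s)
    run_nmf_sweep(pm$matrices[[s]], ks = 4:6, seed = 6, sample_id = s)),
    recursive = FALSE)
  mps <- cluster_programs(inst)
  keys <- unlist(lapply(mps, function(mp)
    paste(mp$members$sample_id, mp$members$k, mp$members$factor_index)))
  expect_equal(anyDuplicated(keys), 0L)
  # consensus is always drawn from member gene sets
  for (mp in mps) {
    member_genes <- unique(unlist(lapply(seq_len(nrow(mp$members)), function(i) {
      m <- mp$members[i, ]
      inst[[which(vapply(inst, function(p)
        p$sample_id == m$sample_id && p$k == m$k &&
          p$factor_index == m$factor_index, logical(1L)))]]$genes
    })))
    expect_true(all(mp$consensus %in% member_genes))
  }
})
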