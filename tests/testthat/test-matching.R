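test_that("line alignment matches the worked examples", {
  al <- align_lines(c(1000, 1050), c(1000.3, 1050.2), 1.5)
  expect_equal(al$k, 2)
  expect_equal(al$sum_abs_de, 0.5, tolerance = 1e-9)
  al2 <- align_lines(c(1000, 1050), c(1000.3), 1.5)
  expect_equal(al2$k, 1)
  expect_equal(nrow(al2$pairs), 1)
  expect_error(align_lines(c(2, 1), c(1, 2)), "sorted")
})

test_that("alignment DP equals the exhaustive monotone-assignment oracle", {
  set.seed(17)
  for (r in 1:300) {
    ma <- sample(1:4, 1); mb <- sample(1:4, 1)
    a <- sort(runif(ma, 0, 12))
    b <- sort(runif(mb, 0, 12))
    gate <- runif(1, 0.5, 4)
    dp <- align_lines(a, b, gate)
    ex <- exhaustive_align(a, b, gate)
    expect_equal(dp$k, ex$k)
    expect_equal(dp$sum_abs_de, ex$sum_abs_de, tolerance = 1e-9)
  }
})

test_that("pair scores follow the linear kernel with gap penalties", {
  p <- score_params()
  x <- c(900, 950, 1000)
  expect_equal(score_pair(x, x, p), 3)
  expect_equal(score_pair(c(1000, 1050, 1100), c(1000.3, 1050.3), p), 1.35,
               tolerance = 1e-9)
  # fully disjoint barcodes are non-candidates
  expect_identical(score_pair(c(900, 910), c(980, 990), p), -Inf)
  # symmetry on random candidate pairs
  set.seed(23)
  for (r in 1:50) {
    a <- sort(runif(3, 900, 910))
    b <- sort(a + rnorm(3, 0, 1))
    expect_equal(score_pair(a, b, p), score_pair(b, a, p))
  }
})

test_that("score-set construction matches brute-force scoring on small pools", {
  pool1 <- random_test_pool(200, seed = 61, delta_big = 40)
  pool2 <- random_test_pool(200, seed = 62, delta_big = 40)
  p <- score_params()
  ss <- build_score_sets(pool1, pool2, p)
  # brute force over all 200 x 200 pairs
  brute <- c()
  for (i in seq_len(200)) {
    a <- pool_barcode(pool1, i)
    for (j in seq_len(200)) {
      s <- score_pair(a, pool_barcode(pool2, j), p)
      if (is.finite(s)) brute <- c(brute, s)
    }
  }
  expect_equal(sort(ss$cross_scores), sort(brute), tolerance = 1e-9)
  # self sets exclude identity comparisons: at most n(n-1)/2 unordered pairs
  ss_self <- build_score_sets(pool1, pool1, p)
  expect_lte(length(ss_self$s11), 200 * 199 / 2)
  expect_equal(length(ss_self$s11), length(ss_self$s22))
})

test_that("a pool matched against itself puts every cell's best score on the identity", {
  pool <- random_test_pool(150, seed = 71, delta_big = 40)
  ss <- build_score_sets(pool, pool, score_params(min_matched_lines = 1))
  best <- tapply(ss$cross$score, ss$cross$i, max)
  ident <- ss$cross[ss$cross$i == ss$cross$j, ]
  expect_equal(as.numeric(best[as.character(ident$i)]), ident$score)
  expect_equal(ident$score, pool_multiplicities(pool)[ident$i],
               tolerance = 1e-9)
})

test_that("disjoint spectral ranges yield an empty cross set", {
  lo <- barcode_pool(c("a", "b"), list(c(900, 905), c(902, 907)))
  hi <- barcode_pool(c("c", "d"), list(c(1000, 1005), c(1002, 1007)))
  ss <- build_score_sets(lo, hi, score_params())
  expect_length(ss$cross_scores, 0)
})

test_that("threshold selection respects quantile contracts", {
  set.seed(5)
  s <- rnorm(1e4)
  thr <- select_threshold(s, q = 1e-2)
  expect_gte(thr, median(s))
  expect_equal(mean(s > thr), 1e-2, tolerance = 2e-3)
  # q below 1/n floors at the maximum observed self score
  expect_equal(select_threshold(s, q = 1e-9), max(s))
  expect_error(select_threshold(numeric(0)), "explicit threshold")
})

test_that("identical pools match perfectly with a diagonal confusion table", {
  pool <- sample_pool(uniform_joint(300), tagging_mixture("fixed", m = 3),
                      300, seed = 81)
  ms <- match_pools(pool, pool)
  expect_equal(ms$match_rate, 1)
  expect_true(all(ms$matches$c1_id == ms$matches$c2_id))
  expect_true(all(ms$matches$mean_abs_dE == 0))
  cf <- as.matrix(ms$confusion)
  expect_equal(sum(cf) - sum(diag(cf)), 0)
})

test_that("matching is invariant to run order and cell relabeling", {
  j <- uniform_joint(100)
  ex <- make_two_run_experiment(j, tagging_mixture("fixed", m = 3),
                                noise_model("gaussian", sigma_phi = 0.1),
                                N = 400, cell_dropout = 0.1, seed = 55)
  ms12 <- match_pools(ex$c1, ex$c2)
  ms21 <- match_pools(ex$c2, ex$c1)
  expect_equal(nrow(ms12$matches), nrow(ms21$matches))
  expect_setequal(paste(ms12$matches$c1_id, ms12$matches$c2_id),
                  paste(ms21$matches$c2_id, ms21$matches$c1_id))
  # relabeled cells give the same matched pairs up to the id map
  c2r <- ex$c2
  c2r$cell_id <- sprintf("renamed_%s", c2r$cell_id)
  msr <- match_pools(ex$c1, c2r)
  expect_equal(paste(msr$matches$c1_id,
                     sub("renamed_", "", msr$matches$c2_id)),
               paste(ms12$matches$c1_id, ms12$matches$c2_id))
})

test_that("noise fitting recovers generalized-Gaussian parameters", {
  # beta = 2: alpha should approach sigma * sqrt(2); many repeats per LP so
  # per-LP centering barely shrinks the fluctuations
  nz2 <- noise_model("gaussian", sigma_phi = 0.1)
  df2 <- make_repeat_measurements(100, 100, nz2, seed = 13)
  f2 <- fit_noise(df2)
  expect_lt(abs(f2$beta - 2), 0.2)
  expect_lt(abs(f2$alpha - 0.1 * sqrt(2)) / (0.1 * sqrt(2)), 0.1)
  # recovery across the beta range of interest
  for (cse in list(c(0.047, 1.28, 156, 71), c(0.25, 1.37, 156, 71),
                   c(0.1, 1.0, 200, 60))) {
    nz <- noise_model("generalized-gaussian", alpha = cse[1], beta = cse[2])
    df <- make_repeat_measurements(cse[3], cse[4], nz, seed = 14)
    f <- fit_noise(df)
    expect_lt(abs(f$alpha - cse[1]) / cse[1], 0.1)
    expect_lt(abs(f$beta - cse[2]) / cse[2], 0.1)
  }
})

test_that("noise fitting is scale-equivariant and rejects degenerate input", {
  nz <- noise_model("generalized-gaussian", alpha = 0.2, beta = 1.5)
  df <- make_repeat_measurements(50, 40, nz, seed = 15)
  f <- fit_noise(df)
  df_scaled <- df
  mu <- ave(df$energy_meV, df$lp_id)
  df_scaled$energy_meV <- mu + 3 * (df$energy_meV - mu)
  fs <- fit_noise(df_scaled)
  expect_equal(fs$alpha, 3 * f$alpha, tolerance = 1e-3)
  expect_equal(fs$beta, f$beta, tolerance = 1e-3)
  df0 <- make_repeat_measurements(30, 5, noise_model("gaussian",
                                                     sigma_phi = 0),
                                  seed = 16)
  expect_error(fit_noise(df0), "degenerate")
})
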