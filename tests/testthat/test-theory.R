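test_that("discrete barcode counting matches binomial arithmetic", {
  expect_equal(count_unique_barcodes(discrete_palette(100, 3)), 161700)
  expect_equal(count_unique_barcodes(discrete_palette(5, 5)), 1)
  expect_equal(count_unique_barcodes(discrete_palette(100, 3), approx = TRUE),
               100^3 / 6)
  expect_error(discrete_palette(3, 5), "l")
})

test_that("discrete duplicate rate follows the birthday-style formula", {
  expect_equal(duplicate_rate_discrete(12345, 1), 0)
  expect_equal(duplicate_rate_discrete(1, 2), 1)
  # frozen from direct evaluation of 1 - (1 - 1e-6)^9999
  expect_equal(duplicate_rate_discrete(1e6, 1e4), 0.00994918,
               tolerance = 1e-6)
  expect_equal(duplicate_rate_discrete(1e6, 1e4, exact = FALSE), 0.01)
})

test_that("minimum barcode count for a duplicate budget is consistent", {
  r <- min_unique_barcodes(1e4, 0.01)
  expect_equal(r$B, 1e6)
  # frozen from solving 1 - (1 - 1/B)^9999 = 0.01 numerically
  expect_equal(r$B_exact, 994892.6, tolerance = 1e-4)
  expect_lte(duplicate_rate_discrete(r$B, 1e4), 0.01)
  expect_lte(duplicate_rate_discrete(ceiling(r$B_exact), 1e4), 0.01)
  expect_error(min_unique_barcodes(1e4, 1.2), "eps0")
})

test_that("effective barcode count applies only to uniform distributions", {
  u100 <- spectral_distribution("uniform", delta_big = 100)
  expect_equal(effective_barcodes(u100, 0.5, 3), 1e6 / 6)
  expect_equal(effective_barcodes(u100, 0.5, 1), 100)
  expect_equal(effective_barcodes(
    spectral_distribution("uniform", delta_big = 300), 0.5, 3), 4.5e6)
  g <- spectral_distribution("gaussian", sigma = 10)
  expect_error(effective_barcodes(g, 0.5, 3), "uniform")
})

test_that("continuous duplicate rate: closed form and degenerate cases", {
  j <- uniform_joint(100)
  r <- duplicate_rate_continuous(j, 3, 0.5, 1e4)
  # oracle: 1 - (1 - 1/B_eff)^9999 with B_eff = (100)^3/6
  expect_equal(r$rate, 1 - (1 - 6 / 1e6)^9999, tolerance = 1e-12)
  expect_equal(r$mc_stderr, 0)
  expect_equal(duplicate_rate_continuous(j, 3, 0.5, 1)$rate, 0)
  expect_error(duplicate_rate_continuous(j, 3, -0.1, 10), "delta")
  expect_error(duplicate_rate_continuous(j, 3, 0.5, 0), "N")
})

test_that("Monte-Carlo duplicate rate agrees with the closed form on a flat density", {
  # an 'empirical' flat density is numerically uniform but exercises the
  # Monte-Carlo integration path
  flat <- spectral_distribution("empirical", grid = c(900, 1000),
                                density = c(1, 1))
  j <- joint_barcode_distribution(flat)
  r <- duplicate_rate_continuous(j, 3, 0.5, 1e4, n_mc = 2e5, seed = 7)
  expect_equal(r$path, "monte-carlo")
  closed <- 1 - (1 - 6 / 1e6)^9999
  expect_lt(abs(r$rate - closed), 3 * r$mc_stderr + 1e-9)
  expect_error(duplicate_rate_continuous(j, 3, 0.5, 1e4), "seed")
})

test_that("noise error matches erf / incomplete-gamma quadrature", {
  nz <- noise_model("gaussian", sigma_phi = 0.1)
  # oracle: 1 - erf(5/sqrt(2))^3 via pnorm
  expect_equal(noise_error(nz, 0.5, 3), 1 - (2 * pnorm(5) - 1)^3,
               tolerance = 1e-12)
  expect_lt(noise_error(nz, 100, 3), 1e-15)
  # generalized Gaussian with beta = 2 is a Gaussian with sigma = alpha/sqrt(2)
  gg <- noise_model("generalized-gaussian", alpha = 0.2, beta = 2)
  gz <- noise_model("gaussian", sigma_phi = 0.2 / sqrt(2))
  deltas <- c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 2)
  expect_equal(noise_error(gg, deltas, 3), noise_error(gz, deltas, 3),
               tolerance = 1e-10)
  # numeric quadrature oracle for a non-trivial beta
  gg2 <- noise_model("generalized-gaussian", alpha = 0.047, beta = 1.28)
  phi <- function(x) with(list(a = 0.047, b = 1.28),
                          b / (2 * a * gamma(1 / b)) * exp(-(abs(x) / a)^b))
  inner <- integrate(phi, -0.1, 0.1, rel.tol = 1e-12)$value
  expect_equal(noise_error(gg2, 0.1, 4), 1 - inner^4, tolerance = 1e-8)
})

test_that("total error is the inclusion-exclusion combination", {
  expect_equal(total_error(0, 0.3), 0.3)
  expect_equal(total_error(1, 0.3), 1)
  expect_equal(total_error(0.5, 0.5), 0.75)
  expect_equal(total_error(0.2, 0.7), total_error(0.7, 0.2))
  expect_error(total_error(1.2, 0), "0, 1")
})

test_that("delta optimization finds the total-error minimum", {
  j <- uniform_joint(100)
  nz <- noise_model("gaussian", sigma_phi = 0.1)
  for (N in c(1e3, 1e5)) {
    od <- optimize_delta(j, nz, 3, N)
    f <- function(d) total_error(
      duplicate_rate_continuous(j, 3, d, N)$rate,
      noise_error(nz, d, 3))
    expect_lte(od$eps_min, f(od$delta_opt * 2) + 1e-12)
    expect_lte(od$eps_min, f(od$delta_opt / 2) + 1e-12)
    # brute-force fine-grid scan oracle
    grid <- exp(seq(log(1e-3), log(50), length.out = 4000))
    expect_lte(od$eps_min, min(vapply(grid, f, numeric(1))) + 1e-10)
  }
  # delta_opt shrinks (weakly) as the pool grows
  d_small <- optimize_delta(j, nz, 3, 1e3)$delta_opt
  d_large <- optimize_delta(j, nz, 3, 1e6)$delta_opt
  expect_lte(d_large, d_small)
  # degenerate noise falls back to the lower bound with a warning
  expect_warning(
    od0 <- optimize_delta(j, noise_model("gaussian", sigma_phi = 0), 3, 1e3),
    "degenerate")
  expect_equal(od0$status, "degenerate-noise")
})

test_that("maximum pool size honors its bisection contract", {
  j <- uniform_joint(100)
  nz <- noise_model("gaussian", sigma_phi = 0.1)
  eps_min <- function(N) optimize_delta(j, nz, 3, N)$eps_min
  n_max <- max_pool_size(j, nz, 3, 0.01)
  expect_gt(n_max, 2)
  expect_lte(eps_min(n_max), 0.01)
  expect_gt(eps_min(n_max + 1), 0.01)
  # hopeless tolerance yields 0
  expect_equal(max_pool_size(j, noise_model("gaussian", sigma_phi = 20),
                             3, 1e-6), 0)
})

test_that("Poisson mixture weights and degenerate fixed mode behave", {
  tw <- lpbarcode:::tagging_weights(tagging_mixture("poisson", lambda = 3))
  expect_equal(tw$w0, exp(-3), tolerance = 1e-12)
  expect_equal(sum(tw$w), 1, tolerance = 1e-6)   # renormalized over m >= 1
  j <- uniform_joint(100)
  nz <- noise_model("gaussian", sigma_phi = 0.1)
  # fixed-mode 'mixture' equals the plain fixed-m computation
  r_fix <- mixture_error_rates(tagging_mixture("fixed", m = 3), j, nz,
                               0.5, 1e4)
  expect_equal(r_fix$eps_dup,
               duplicate_rate_continuous(j, 3, 0.5, 1e4)$rate)
  expect_equal(r_fix$eps_noise, noise_error(nz, 0.5, 3))
  # low multiplicities dominate the duplicate contributions at lambda = 3
  r <- mixture_error_rates(tagging_mixture("poisson", lambda = 3), j, nz,
                           0.5, 1e5)
  contrib <- r$per_m$contribution
  low <- sum(contrib[r$per_m$m <= 2])
  expect_gt(low, 0.9 * sum(contrib))
})

test_that("duplicate loss responds to pool size and tagging ratio as expected", {
  j <- uniform_joint(100)
  nz <- noise_model("gaussian", sigma_phi = 0.1)
  tag6 <- tagging_mixture("poisson", lambda = 6)
  l_small <- duplicate_loss(tag6, j, nz, 1e4, 0.01)
  l_big <- duplicate_loss(tag6, j, nz, 1e6, 0.01)
  expect_equal(l_small$status, "ok")
  expect_lte(l_small$loss, l_big$loss)
  # higher tagging ratio reduces duplication loss at fixed N
  l_lam3 <- duplicate_loss(tagging_mixture("poisson", lambda = 3), j, nz,
                           1e5, 0.01)
  l_lam6 <- duplicate_loss(tag6, j, nz, 1e5, 0.01)
  expect_lt(l_lam6$loss, l_lam3$loss)
  # the chosen gate puts the weighted noise error on the budget
  tw <- lpbarcode:::tagging_weights(tag6)
  wn <- sum(tw$w * (1 - lpbarcode:::noise_interval_prob(nz, l_lam6$delta)^tw$m))
  expect_equal(wn, 0.01, tolerance = 1e-6)
})

test_that("predicted duplicate loss matches a directly simulated pool", {
  j <- joint_barcode_distribution(
    spectral_distribution("uniform", delta_big = 300))
  nz <- noise_model("generalized-gaussian", alpha = 0.047, beta = 1.28)
  tag <- tagging_mixture("poisson", lambda = 6)
  dl <- duplicate_loss(tag, j, nz, 1e5, 0.01)
  pool <- sample_pool(j, tag, ceiling(1e5 / (1 - exp(-6))), seed = 31)
  emp <- count_duplicates(pool, dl$delta)$frac_dup
  se <- sqrt(max(emp * (1 - emp), 1e-8) / length(pool))
  expect_lt(abs(emp - dl$loss), 3 * se + 0.002)
})
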