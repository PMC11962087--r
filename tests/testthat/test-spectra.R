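make_line_spectrum <- function(centers, grid = seq(900, 1000, by = 0.2),
                               width = 0.8, amp = 1, noise_sd = 0,
                               seed = NULL) {
  y <- rowSums(vapply(centers, function(c0)
    amp * exp(-(grid - c0)^2 / (2 * width^2)), numeric(length(grid))))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(grid), 0, noise_sd)
  }
  list(energy = grid, intensity = y)
}

test_that("peak detection finds isolated and paired lines", {
  s <- make_line_spectrum(950, noise_sd = 0.02, seed = 1)   # SNR 50
  pk <- detect_peaks(s$energy, s$intensity)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$energy_meV - 950), 0.2 + 1e-9)
  s2 <- make_line_spectrum(c(945, 955), noise_sd = 0.02, seed = 2)
  expect_equal(nrow(detect_peaks(s2$energy, s2$intensity)), 2)
  # flat spectrum: no peaks, not an error
  flat <- detect_peaks(seq(900, 910, 0.5), rep(1, 21))
  expect_equal(nrow(flat), 0)
  expect_error(detect_peaks(1:5, 1:5), "8 grid points")
})

test_that("pure-noise spectra yield no detections at the default threshold", {
  # false-positive probe: 1000 seeded noise-only spectra
  set.seed(99)
  n_fp <- 0
  grid <- seq(900, 950, by = 0.4)
  for (r in 1:1000) {
    y <- rnorm(length(grid), 0, 1)
    n_fp <- n_fp + (nrow(detect_peaks(grid, y)) > 0)
  }
  expect_equal(n_fp, 0)
})

test_that("detection is translation-equivariant and scale-invariant", {
  s <- make_line_spectrum(c(930, 960), noise_sd = 0.03, seed = 3)
  pk <- detect_peaks(s$energy, s$intensity)
  pk_shift <- detect_peaks(s$energy + 57.3, s$intensity)
  expect_equal(pk_shift$energy_meV, pk$energy_meV + 57.3)
  pk_scaled <- detect_peaks(s$energy, s$intensity * 1234)
  expect_equal(pk_scaled$index, pk$index)
})

test_that("Gaussian refinement reaches sub-grid accuracy", {
  grid <- seq(900, 1000, by = 0.2)
  # noiseless, on-grid symmetric line: exact center recovery
  s <- make_line_spectrum(950, grid = grid)
  pk <- detect_peaks(s$energy, s$intensity)
  fit <- refine_peak(s$energy, s$intensity, pk$index[1])
  expect_equal(fit$method, "gaussian")
  expect_lt(abs(fit$center - 950), 1e-9)
  # off-grid center at SNR 100: error below a fifth of the grid step
  errs <- vapply(1:20, function(r) {
    c0 <- 950 + runif(1, -0.1, 0.1)
    s <- make_line_spectrum(c0, grid = grid, noise_sd = 0.01, seed = 100 + r)
    pk <- detect_peaks(s$energy, s$intensity)
    fit <- refine_peak(s$energy, s$intensity, pk$index[1])
    abs(fit$center - c0)
  }, numeric(1))
  expect_lt(max(errs), 0.2 / 5)
  # window clipped at the grid edge falls back to the parabolic vertex
  fit_edge <- refine_peak(grid, make_line_spectrum(900.4, grid)$intensity, 3)
  expect_equal(fit_edge$method, "parabolic")
})

test_that("event extraction recovers barcodes and flags untagged events", {
  s <- make_line_spectrum(c(920, 950, 980), noise_sd = 0.02, seed = 6)
  bc <- barcode_from_event(s$energy, s$intensity)
  expect_equal(bc$m, 3L)
  expect_false(bc$untagged)
  expect_equal(bc$energies, c(920, 950, 980), tolerance = 1e-2)
  empty <- barcode_from_event(seq(900, 950, 0.5),
                              rep(0, length(seq(900, 950, 0.5))))
  expect_true(empty$untagged)
  expect_equal(empty$m, 0L)
  # lines closer than min_separation merge (documented limitation)
  s2 <- make_line_spectrum(c(950, 950.5), noise_sd = 0.01, seed = 7)
  expect_lt(barcode_from_event(s2$energy, s2$intensity)$m, 3)
})

test_that("pixel-peak clustering groups spatially adjacent equal-energy peaks", {
  # 2 LPs, 9 pixels each, 30 meV apart
  patch <- expand.grid(x = 0:2, y = 0:2)
  pk <- rbind(
    data.frame(patch, energy_meV = 900 + rnorm(9, 0, 0.01)),
    data.frame(patch + 10, energy_meV = 930 + rnorm(9, 0, 0.01)))
  cl <- cluster_pixel_peaks(pk, spatial_radius = 1, energy_tol = 1)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$energy_meV), c(900, 930), tolerance = 0.02)
  expect_equal(sort(cl$n_pixels), c(9L, 9L))
  # isolated pixel peak forms its own cluster
  one <- cluster_pixel_peaks(data.frame(x = 5, y = 5, energy_meV = 910), 1, 1)
  expect_equal(nrow(one), 1)
  # co-located LPs within the energy tolerance merge: limitation by design
  both <- data.frame(x = c(0, 0), y = c(0, 0),
                     energy_meV = c(900, 900.1))
  expect_equal(nrow(cluster_pixel_peaks(both, 1, 1)), 1)
  # permutation invariance of cluster energies
  perm <- sample(nrow(pk))
  cl2 <- cluster_pixel_peaks(pk[perm, ], 1, 1)
  expect_equal(sort(cl2$energy_meV), sort(cl$energy_meV))
})

test_that("energy-wavelength conversion is exact and involutive", {
  expect_equal(wavelength_to_energy(1239.84198), 1000)
  expect_equal(wavelength_to_energy(1150), 1078.12, tolerance = 1e-4)
  x <- c(800, 950, 1100)
  expect_equal(wavelength_to_energy(energy_to_wavelength(x)), x,
               tolerance = 1e-12)
  expect_error(wavelength_to_energy(-1), "positive")
  expect_equal(wavelength_bins(1150, 1650, 1), 500L)
})

test_that("end-to-end extraction recovers well-separated barcodes", {
  j <- joint_barcode_distribution(
    spectral_distribution("uniform", delta_big = 280, center = 950))
  pool <- sample_pool(j, tagging_mixture("fixed", m = 3), 300, seed = 41)
  # condition on the stated regime: line separations of at least 5 meV
  sep_ok <- vapply(seq_len(300), function(i)
    min(diff(pool_barcode(pool, i))) >= 5, logical(1))
  ds <- make_spectra_dataset(pool, grid = seq(800, 1100, by = 0.2),
                             linewidth = 0.8, snr = 30, seed = 42)
  ids <- pool$cell_id[sep_ok]
  n_ok <- 0; max_err <- 0
  for (id in ids) {
    s <- ds$spectra[ds$spectra$origin_id == id, ]
    bc <- barcode_from_event(s$energy_meV, s$intensity)
    truth <- sort(ds$truth$energy_meV[ds$truth$origin_id == id])
    if (bc$m == length(truth)) {
      n_ok <- n_ok + 1
      max_err <- max(max_err, max(abs(bc$energies - truth)))
    }
  }
  expect_gte(n_ok / length(ids), 0.99)
  # line energies recovered within 3x the injected intensity-noise scale
  expect_lt(max_err, 3 / 30)
})
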