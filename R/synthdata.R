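#' Six-envelope LP library specification
#'
#' Default emulation of an LP library fabricated from six semiconductor
#' compositions: six Gaussian spectral envelopes centered 825 to 1075 meV
#' (50 meV spacing) with equal weights, spanning roughly 800--1100 meV.
#' Each envelope's width (sd 15 meV by default) makes neighboring
#' envelopes overlap into a quasi-continuous ~300 meV band.
#'
#' @param centers envelope centers in meV.
#' @param sds envelope standard deviations in meV (recycled).
#' @param weights envelope weights (recycled, normalized).
#' @param f_dm dual-mode LP fraction (default 0).
#' @param fsr dual-mode spacing bounds in meV (default \code{c(50, 70)}).
#' @return an object of class \code{"library_spec"}.
#' @export
library_spec <- function(centers = seq(825, 1075, by = 50), sds = 15,
                         weights = 1, f_dm = 0, fsr = c(50, 70)) {
  if (is.unsorted(centers, strictly = TRUE))
    stop("'centers' must be strictly ascending")
  k <- length(centers)
  sds <- rep_len(sds, k)
  weights <- rep_len(weights, k)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  weights <- weights / sum(weights)
  structure(list(centers = centers, sds = sds, weights = weights,
                 f_dm = f_dm, fsr = fsr), class = "library_spec")
}

#' Build the joint barcode distribution of an LP library
#'
#' Turns a \code{\link{library_spec}} into a
#' \code{\link{joint_barcode_distribution}}: a Gaussian-mixture line
#' density \eqn{g(E)} (a single component collapses to a plain Gaussian)
#' plus the dual-mode parameters.
#'
#' @param spec a \code{\link{library_spec}}.
#' @return a \code{\link{joint_barcode_distribution}}.
#' @export
make_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "library_spec"))
  base <- if (length(spec$centers) == 1) {
    spectral_distribution("gaussian", sigma = spec$sds[1],
                          center = spec$centers[1])
  } else {
    spectral_distribution("gaussian-mixture",
                          components = data.frame(center = spec$centers,
                                                  sd = spec$sds,
                                                  weight = spec$weights))
  }
  joint_barcode_distribution(base, f_dm = spec$f_dm, fsr = spec$fsr)
}

#' Simulate a two-run measurement experiment with ground truth
#'
#' One true barcode pool is measured twice with independent noise
#' realizations (runs \eqn{C_1} and \eqn{C_2}). Before the second
#' measurement a fraction \code{cell_dropout} of cells is lost (e.g. during
#' the washing/centrifugation between flow-cytometry cycles), and in each
#' measurement every line is independently lost with probability
#' \code{line_dropout} (applied after noise). Cells whose lines are all
#' dropped disappear from that run. The true correspondence between run
#' ids is returned.
#'
#' @param joint a \code{\link{joint_barcode_distribution}}.
#' @param tagging a \code{\link{tagging_mixture}}.
#' @param noise a \code{\link{noise_model}}.
#' @param N number of cells tagged.
#' @param cell_dropout fraction of cells lost before run 2, in [0, 1).
#' @param line_dropout per-line loss probability per measurement, in
#'   [0, 1).
#' @param seed integer root seed.
#' @return list with \code{c1}, \code{c2} (\code{\link{barcode_pool}}s with
#'   run-local ids) and \code{truth} (data.frame: \code{true_id},
#'   \code{c1_id}, \code{c2_id}; NA where the cell is absent from a run).
#' @export
make_two_run_experiment <- function(joint, tagging, noise, N,
                                    cell_dropout = 0.1, line_dropout = 0,
                                    seed) {
  stopifnot_scalar(cell_dropout, "cell_dropout", 0, 1)
  stopifnot_scalar(line_dropout, "line_dropout", 0, 1)
  if (cell_dropout >= 1 || line_dropout >= 1)
    stop("dropout rates must be < 1")
  truth_pool <- sample_pool(joint, tagging, N, split_seed(seed, 1))
  r1 <- measure_run(truth_pool, noise, line_dropout, split_seed(seed, 2),
                    "c1")
  kept <- with_seed(split_seed(seed, 3),
                    stats::runif(length(truth_pool)) >= cell_dropout)
  sub <- subset_pool(truth_pool, which(kept))
  r2 <- measure_run(sub, noise, line_dropout, split_seed(seed, 4), "c2")
  truth <- data.frame(true_id = truth_pool$cell_id,
                      c1_id = r1$map[truth_pool$cell_id],
                      c2_id = NA_character_,
                      stringsAsFactors = FALSE)
  truth$c2_id[match(sub$cell_id, truth_pool$cell_id)] <-
    r2$map[sub$cell_id]
  list(c1 = r1$pool, c2 = r2$pool, truth = truth)
}

# one noisy measurement of a pool with per-line dropout; returns the
# measured pool (run-local ids) and a map true_id -> run id (NA if lost)
measure_run <- function(pool, noise, line_dropout, seed, prefix) {
  noised <- apply_noise(pool, noise, split_seed(seed, 1))
  m <- pool_multiplicities(noised)
  keep_line <- with_seed(split_seed(seed, 2),
                         stats::runif(length(noised$energies)) >= line_dropout)
  cell <- rep.int(seq_along(noised$cell_id), m)
  en <- noised$energies[keep_line]
  cell <- cell[keep_line]
  new_m <- tabulate(cell, nbins = length(noised$cell_id))
  keep_cell <- new_m > 0
  idx <- which(keep_cell)
  run_ids <- sprintf("%s_%06d", prefix, seq_along(idx))
  map <- stats::setNames(rep(NA_character_, length(pool$cell_id)),
                         pool$cell_id)
  map[pool$cell_id[idx]] <- run_ids
  pool_out <- new_barcode_pool(run_ids, en[cell %in% idx],
                               c(0L, cumsum(new_m[idx])),
                               provenance = list(seed = seed,
                                                 line_dropout = line_dropout))
  list(pool = pool_out, map = map)
}

# pool restricted to cell positions idx (order preserved)
subset_pool <- function(pool, idx) {
  m <- pool_multiplicities(pool)
  take <- unlist(lapply(idx, function(i)
    seq.int(pool$offsets[i] + 1, length.out = m[i])), use.names = FALSE)
  new_barcode_pool(pool$cell_id[idx], pool$energies[take],
                   c(0L, cumsum(m[idx])),
                   if (is.null(pool$plet_id)) NULL else pool$plet_id[take],
                   pool$provenance)
}

#' Synthesize emission spectra for a barcode pool
#'
#' Instrument emulation for the extraction pipeline. In \code{"flow"} mode
#' each cell yields one spectrum: Gaussian lines of width \code{linewidth}
#' at the barcode energies (unit amplitude) plus additive Gaussian noise of
#' sd \code{1/snr}. In \code{"imaging"} mode each LP line spans a 3x3
#' pixel patch at a random location, one spectrum per pixel, and the truth
#' table records the pixel-to-LP assignment.
#'
#' @param pool a \code{\link{barcode_pool}}.
#' @param grid ascending energy grid in meV; must cover the pool's range.
#' @param linewidth Gaussian line sd in meV (default 0.8).
#' @param snr amplitude signal-to-noise ratio (default 30); \code{Inf}
#'   for noiseless spectra.
#' @param seed integer seed.
#' @param mode \code{"flow"} or \code{"imaging"}.
#' @return list with \code{spectra} (long data.frame: origin_id, x, y,
#'   energy_meV, intensity) and \code{truth} (true line energies per
#'   origin; lines outside the grid are flagged).
#' @export
make_spectra_dataset <- function(pool, grid = seq(800, 1100, by = 0.2),
                                 linewidth = 0.8, snr = 30, seed = 1,
                                 mode = c("flow", "imaging")) {
  mode <- match.arg(mode)
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly ascending")
  m <- pool_multiplicities(pool)
  with_seed(seed, {
    if (mode == "flow") {
      spectra <- lapply(seq_along(pool$cell_id), function(i) {
        en <- pool_barcode(pool, i)
        y <- rowSums(vapply(en, function(e)
          exp(-(grid - e)^2 / (2 * linewidth^2)), numeric(length(grid))))
        if (is.finite(snr)) y <- y + stats::rnorm(length(grid), 0, 1 / snr)
        data.frame(origin_id = pool$cell_id[i], x = NA_integer_,
                   y = NA_integer_, energy_meV = grid, intensity = y,
                   stringsAsFactors = FALSE)
      })
      truth <- data.frame(origin_id = rep(pool$cell_id, m),
                          energy_meV = pool$energies,
                          in_grid = pool$energies >= min(grid) &
                                    pool$energies <= max(grid),
                          stringsAsFactors = FALSE)
      list(spectra = do.call(rbind, spectra), truth = truth)
    } else {
      # one 3x3 patch of pixel spectra per line; patches placed on a
      # coarse lattice so different LPs never overlap spatially
      n_lines <- length(pool$energies)
      px <- ((seq_len(n_lines) - 1) %% 100) * 5
      py <- ((seq_len(n_lines) - 1) %/% 100) * 5
      rows <- list()
      truth <- data.frame(origin_id = rep(pool$cell_id, m),
                          lp = seq_len(n_lines),
                          energy_meV = pool$energies,
                          x = px, y = py,
                          in_grid = pool$energies >= min(grid) &
                                    pool$energies <= max(grid),
                          stringsAsFactors = FALSE)
      for (t in seq_len(n_lines)) {
        e <- pool$energies[t]
        for (dx in 0:2) for (dy in 0:2) {
          y <- exp(-(grid - e)^2 / (2 * linewidth^2))
          if (is.finite(snr)) y <- y + stats::rnorm(length(grid), 0, 1 / snr)
          rows[[length(rows) + 1]] <-
            data.frame(origin_id = rep(truth$origin_id[t], length(grid)),
                       x = px[t] + dx, y = py[t] + dy,
                       energy_meV = grid, intensity = y,
                       stringsAsFactors = FALSE)
        }
      }
      list(spectra = do.call(rbind, rows), truth = truth)
    }
  })
}

#' Repeated line measurements of a set of LPs
#'
#' Emulates tracking individual LPs over repeated spectral acquisitions:
#' each LP's true energy is drawn from the library line density and each
#' repeat adds an independent draw from the noise model. Used to exercise
#' \code{\link{fit_noise}} (e.g. 156 LPs x 71 repeats).
#'
#' @param n_lp number of LPs (\eqn{\ge 1}).
#' @param n_repeats repeats per LP (\eqn{\ge 2}).
#' @param noise a \code{\link{noise_model}}.
#' @param seed integer seed.
#' @param joint line-energy source (default: six-envelope library).
#' @return data.frame with columns \code{lp_id}, \code{repeat_index},
#'   \code{energy_meV}, plus attribute \code{"true_energy"}.
#' @export
make_repeat_measurements <- function(n_lp, n_repeats, noise, seed,
                                     joint = make_library()) {
  stopifnot_scalar(n_lp, "n_lp", 1)
  stopifnot_scalar(n_repeats, "n_repeats", 2)
  with_seed(seed, {
    truth <- sample_lines(joint$base, n_lp)
    en <- rep(truth, each = n_repeats) +
      noise_sample(noise, n_lp * n_repeats)
    out <- data.frame(lp_id = rep(sprintf("lp_%04d", seq_len(n_lp)),
                                  each = n_repeats),
                      repeat_index = rep(seq_len(n_repeats), n_lp),
                      energy_meV = en, stringsAsFactors = FALSE)
    attr(out, "true_energy") <- truth
    out
  })
}
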