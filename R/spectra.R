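#' Photon energy / wavelength conversion
#'
#' \eqn{E(\mathrm{meV}) = 10^3 \times 1239.84198 / \lambda(\mathrm{nm})}
#' and its inverse (the same formula). Spectral linewidths and measurement
#' noise are approximately constant in frequency, so all internal work is
#' in photon energy (meV).
#'
#' @param lambda_nm wavelength(s) in nm (> 0).
#' @param energy_meV photon energy(ies) in meV (> 0).
#' @return converted values.
#' @examples
#' wavelength_to_energy(1239.84198)  # 1000 meV
#' @export
wavelength_to_energy <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  1e3 * 1239.84198 / lambda_nm
}

#' @rdname wavelength_to_energy
#' @export
energy_to_wavelength <- function(energy_meV) {
  if (any(energy_meV <= 0)) stop("energy must be positive")
  1e3 * 1239.84198 / energy_meV
}

#' Number of discrete colors from wavelength binning
#'
#' How many distinguishable colors a spectral range supports at a given
#' bin width, e.g. 1-nm binning over 1150--1650 nm gives 500 colors.
#'
#' @param lo_nm,hi_nm wavelength range bounds in nm.
#' @param bin_nm bin width in nm (default 1).
#' @return integer number of bins.
#' @export
wavelength_bins <- function(lo_nm, hi_nm, bin_nm = 1) {
  if (hi_nm <= lo_nm || bin_nm <= 0) stop("invalid range or bin width")
  as.integer(floor((hi_nm - lo_nm) / bin_nm))
}

#' Detect emission-line peaks in a spectrum
#'
#' Local maxima whose prominence exceeds \code{min_prominence_mads} times
#' the robust noise level (median absolute deviation of the intensity),
#' thinned so that retained peaks are pairwise separated by at least
#' \code{min_separation} (highest peaks win). Deterministic.
#'
#' @param energy ascending energy grid in meV (\eqn{\ge 8} points).
#' @param intensity non-negative intensities, same length.
#' @param min_prominence_mads prominence threshold in MAD units (default 8).
#' @param min_separation minimum peak separation in meV (default 1.0).
#' @return data.frame with columns \code{index}, \code{energy_meV},
#'   \code{intensity}, \code{prominence}; zero rows for flat or pure-noise
#'   spectra.
#' @export
detect_peaks <- function(energy, intensity, min_prominence_mads = 8,
                         min_separation = 1.0) {
  n <- length(energy)
  if (n < 8) stop("need at least 8 grid points")
  if (length(intensity) != n) stop("grid/intensity length mismatch")
  if (is.unsorted(energy, strictly = TRUE))
    stop("'energy' must be strictly ascending")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  y <- intensity
  # local maxima (left-strict to break plateau ties at the left edge)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(empty_peaks())
  noise <- stats::mad(y)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  thr <- max(min_prominence_mads * noise, .Machine$double.eps)
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty_peaks())
  # enforce min separation, highest first
  ord <- order(-y[cand])
  sel <- logical(length(cand))
  for (r in ord) {
    e <- energy[cand[r]]
    if (!any(sel & abs(energy[cand] - e) < min_separation)) sel[r] <- TRUE
  }
  out <- data.frame(index = cand[sel], energy_meV = energy[cand[sel]],
                    intensity = y[cand[sel]], prominence = prom[sel])
  out[order(out$index), , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(index = integer(0), energy_meV = numeric(0),
             intensity = numeric(0), prominence = numeric(0))
}

# topographic prominence of a local maximum: height above the higher of the
# two key saddles (minima toward the nearest higher ground on each side).
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  if (i > 1) {
    j <- i - 1
    left_min <- y[j]
    while (j >= 1 && y[j] <= y[i]) {
      if (y[j] < left_min) left_min <- y[j]
      j <- j - 1
    }
    if (j < 1) left_min <- min(y[1:i])
  }
  right_min <- y[i]
  if (i < n) {
    j <- i + 1
    right_min <- y[j]
    while (j <= n && y[j] <= y[i]) {
      if (y[j] < right_min) right_min <- y[j]
      j <- j + 1
    }
    if (j > n) right_min <- min(y[i:n])
  }
  y[i] - max(left_min, right_min)
}

#' Refine a peak position by Gaussian line fitting
#'
#' Least-squares fit of a Gaussian plus constant baseline in a window of
#' \code{window} grid points on each side of the detected peak, giving a
#' sub-grid-resolution line center. If the window is clipped by the grid
#' edge or the fit is singular, the fallback is the parabolic vertex
#' through the three points around the maximum, flagged in \code{method}.
#'
#' @param energy,intensity the spectrum (ascending grid, meV).
#' @param peak_index grid index of the detected peak.
#' @param window half-width of the fit window in grid points (default 5).
#' @return list with \code{center} (meV), \code{width} (Gaussian sd, meV),
#'   \code{amplitude}, \code{fit_rmse}, \code{method}
#'   (\code{"gaussian"} or \code{"parabolic"}).
#' @export
refine_peak <- function(energy, intensity, peak_index, window = 5) {
  n <- length(energy)
  if (peak_index < 1 || peak_index > n) stop("peak index outside grid")
  lo <- peak_index - window; hi <- peak_index + window
  clipped <- lo < 1 || hi > n
  lo <- max(lo, 1); hi <- min(hi, n)
  x <- energy[lo:hi]; y <- intensity[lo:hi]
  if (!clipped) {
    b0 <- min(y); a0 <- intensity[peak_index] - b0
    c0 <- energy[peak_index]
    # half-max width start estimate
    above <- x[y - b0 >= a0 / 2]
    w0 <- if (length(above) >= 2) diff(range(above)) / 2.355
          else diff(range(x)) / 6
    w0 <- max(w0, mean(diff(x)) / 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - cc)^2 / (2 * w^2)) + b,
                        start = list(A = a0, cc = c0, w = w0, b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (cf[["cc"]] >= energy[1] && cf[["cc"]] <= energy[n] &&
          is.finite(cf[["w"]]) && cf[["w"]] != 0) {
        return(list(center = unname(cf[["cc"]]),
                    width = abs(unname(cf[["w"]])),
                    amplitude = unname(cf[["A"]]),
                    fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                    method = "gaussian"))
      }
    }
  }
  # parabolic vertex through the 3 points around the maximum
  i <- min(max(peak_index, 2), n - 1)
  y3 <- intensity[(i - 1):(i + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  step <- (energy[i + 1] - energy[i - 1]) / 2
  off <- if (denom != 0) 0.5 * (y3[1] - y3[3]) / denom else 0
  list(center = energy[i] + off * step,
       width = step, amplitude = y3[2],
       fit_rmse = NA_real_, method = "parabolic")
}

#' Extract a barcode from one event spectrum
#'
#' Flow-cytometry path: detect peaks, refine each by Gaussian fitting, and
#' sort the fitted centers ascending into the cell's barcode. Spectra with
#' no detected line yield a multiplicity-0 record flagged untagged.
#'
#' @param energy,intensity the event spectrum.
#' @param min_prominence_mads,min_separation,window extraction parameters,
#'   see \code{\link{detect_peaks}} and \code{\link{refine_peak}}.
#' @return list with \code{energies} (sorted fitted centers, meV),
#'   \code{m}, \code{untagged}, and the per-line \code{fits}.
#' @export
barcode_from_event <- function(energy, intensity, min_prominence_mads = 8,
                               min_separation = 1.0, window = 5) {
  pk <- detect_peaks(energy, intensity, min_prominence_mads, min_separation)
  if (nrow(pk) == 0)
    return(list(energies = numeric(0), m = 0L, untagged = TRUE,
                fits = list()))
  fits <- lapply(pk$index, function(i)
    refine_peak(energy, intensity, i, window))
  centers <- sort(vapply(fits, `[[`, numeric(1), "center"))
  list(energies = centers, m = length(centers), untagged = FALSE,
       fits = fits)
}

#' Cluster per-pixel peaks into per-LP emission energies
#'
#' Imaging path: the microscope yields one spectrum per pixel, so a single
#' LP produces several nearby pixel peaks at nearly the same energy.
#' Single-linkage clustering connects two pixel peaks iff their Chebyshev
#' pixel distance is at most \code{spatial_radius} and their energy
#' difference is at most \code{energy_tol}; each cluster is one LP and its
#' emission energy is the unweighted mean of the member peak energies.
#'
#' @param peaks data.frame with columns \code{x}, \code{y} (0-based pixel
#'   coordinates) and \code{energy_meV}.
#' @param spatial_radius maximum Chebyshev pixel distance (default 1).
#' @param energy_tol maximum energy difference in meV (default 1).
#' @return data.frame with one row per LP: \code{cluster},
#'   \code{energy_meV} (mean), \code{n_pixels}, \code{x}, \code{y}
#'   (mean coordinates).
#' @export
cluster_pixel_peaks <- function(peaks, spatial_radius = 1, energy_tol = 1) {
  if (!all(c("x", "y", "energy_meV") %in% names(peaks)))
    stop("'peaks' needs columns x, y, energy_meV")
  n <- nrow(peaks)
  if (n == 0)
    return(data.frame(cluster = integer(0), energy_meV = numeric(0),
                      n_pixels = integer(0), x = numeric(0), y = numeric(0)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(peaks$x[i] - peaks$x[j]),
              abs(peaks$y[i] - peaks$y[j])) <= spatial_radius &&
          abs(peaks$energy_meV[i] - peaks$energy_meV[j]) <= energy_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cl <- match(root, unique(root))
  agg <- function(v) as.vector(tapply(v, cl, mean))
  data.frame(cluster = seq_along(unique(root)),
             energy_meV = agg(peaks$energy_meV),
             n_pixels = as.vector(table(cl)),
             x = agg(peaks$x), y = agg(peaks$y))
}
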