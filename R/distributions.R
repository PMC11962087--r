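#' Spectral distribution of laser-particle emission lines
#'
#' Describes the single-line emission density \eqn{g(E)} from which the
#' energies of individual laser particles (LPs) are drawn, in photon-energy
#' units (meV). Four kinds are supported: \code{"uniform"} (LPs fabricated
#' from graded semiconductor blends, constant density over a band of width
#' \eqn{\Delta}), \code{"gaussian"} (a single composition; the width
#' parameter is tied to the standard deviation by \eqn{\Delta = \sqrt{12}
#' \sigma} so that uniform and Gaussian cases of equal \eqn{\Delta} have
#' equal standard deviation), \code{"gaussian-mixture"} (several
#' compositions, e.g. the six-envelope library), and \code{"empirical"}
#' (a measured line-energy density given on a grid).
#'
#' Gaussian components are truncated at \eqn{\pm 6} standard deviations and
#' renormalized on the truncated support; the neglected tail mass is below
#' \code{2e-9} and irrelevant at the error rates of interest.
#'
#' @param kind one of \code{"uniform"}, \code{"gaussian"},
#'   \code{"gaussian-mixture"}, \code{"empirical"}.
#' @param delta_big band width \eqn{\Delta} in meV (uniform, or Gaussian via
#'   \eqn{\Delta=\sqrt{12}\sigma}).
#' @param sigma Gaussian standard deviation in meV (alternative to
#'   \code{delta_big}).
#' @param center band / line center in meV (default 950, mid of the
#'   800--1100 meV LP emission range).
#' @param components for \code{"gaussian-mixture"}: data.frame with columns
#'   \code{center}, \code{sd}, \code{weight} (meV, meV, summing to 1).
#' @param grid,density for \code{"empirical"}: ascending energy grid (meV)
#'   and non-negative density values; normalized by the trapezoid rule.
#' @return an object of class \code{"spectral_distribution"}.
#' @examples
#' g <- spectral_distribution("uniform", delta_big = 100)
#' line_density(g, c(925, 950, 1200))
#' @export
spectral_distribution <- function(kind = c("uniform", "gaussian",
                                           "gaussian-mixture", "empirical"),
                                  delta_big = NULL, sigma = NULL,
                                  center = 950, components = NULL,
                                  grid = NULL, density = NULL) {
  kind <- match.arg(kind)
  out <- list(kind = kind)
  if (kind == "uniform") {
    if (is.null(delta_big)) stop("uniform distribution requires 'delta_big'")
    stopifnot_scalar(delta_big, "delta_big", 0, strict_lower = TRUE)
    out$delta_big <- delta_big
    out$sigma <- delta_big / sqrt(12)
    out$support <- center + c(-0.5, 0.5) * delta_big
  } else if (kind == "gaussian") {
    if (is.null(sigma)) {
      if (is.null(delta_big))
        stop("gaussian distribution requires 'sigma' or 'delta_big'")
      sigma <- delta_big / sqrt(12)
    }
    stopifnot_scalar(sigma, "sigma", 0, strict_lower = TRUE)
    out$sigma <- sigma
    out$delta_big <- sqrt(12) * sigma
    out$center <- center
    out$support <- center + c(-6, 6) * sigma
    out$trunc_z <- stats::pnorm(6) - stats::pnorm(-6)
  } else if (kind == "gaussian-mixture") {
    if (is.null(components) ||
        !all(c("center", "sd", "weight") %in% names(components)))
      stop("gaussian-mixture requires 'components' with center, sd, weight")
    components <- as.data.frame(components)
    if (any(components$sd <= 0)) stop("component sds must be positive")
    if (any(components$weight < 0) || abs(sum(components$weight) - 1) > 1e-8)
      stop("component weights must be non-negative and sum to 1")
    components <- components[order(components$center), , drop = FALSE]
    out$components <- components
    out$trunc_z <- stats::pnorm(6) - stats::pnorm(-6)
    out$support <- c(min(components$center - 6 * components$sd),
                     max(components$center + 6 * components$sd))
    mu <- sum(components$weight * components$center)
    v <- sum(components$weight * (components$sd^2 + components$center^2)) - mu^2
    out$sigma <- sqrt(v)
    out$delta_big <- sqrt(12) * out$sigma
  } else { # empirical
    if (is.null(grid) || is.null(density) || length(grid) != length(density))
      stop("empirical distribution requires matching 'grid' and 'density'")
    if (is.unsorted(grid, strictly = TRUE)) stop("'grid' must be strictly ascending")
    if (any(density < 0)) stop("'density' must be non-negative")
    w <- diff(grid)
    z <- sum(0.5 * w * (density[-1] + density[-length(density)]))
    if (z <= 0) stop("'density' integrates to zero")
    density <- density / z
    out$grid <- grid
    out$density <- density
    out$support <- range(grid)
    cdf <- c(0, cumsum(0.5 * w * (density[-1] + density[-length(density)])))
    cdf <- cdf / cdf[length(cdf)]
    out$cdf <- cdf
    mu <- sum(0.5 * w * (grid[-1] * density[-1] +
                         grid[-length(grid)] * density[-length(grid)]))
    m2 <- sum(0.5 * w * (grid[-1]^2 * density[-1] +
                         grid[-length(grid)]^2 * density[-length(grid)]))
    out$sigma <- sqrt(max(m2 - mu^2, 0))
    out$delta_big <- sqrt(12) * out$sigma
  }
  structure(out, class = "spectral_distribution")
}

#' @export
print.spectral_distribution <- function(x, ...) {
  cat("Spectral distribution g(E):", x$kind, "\n")
  cat(sprintf("  width Delta = %.4g meV (sd %.4g meV), support [%.4g, %.4g] meV\n",
              x$delta_big, x$sigma, x$support[1], x$support[2]))
  if (!is.null(x$components))
    cat("  components:", nrow(x$components), "Gaussian envelopes\n")
  invisible(x)
}

#' Evaluate the line-energy density g(E)
#'
#' @param dist a \code{\link{spectral_distribution}}.
#' @param E energies in meV.
#' @return density values (1/meV), zero outside the support.
#' @export
line_density <- function(dist, E) {
  stopifnot(inherits(dist, "spectral_distribution"))
  inside <- E >= dist$support[1] & E <= dist$support[2]
  d <- numeric(length(E))
  if (dist$kind == "uniform") {
    d[inside] <- 1 / dist$delta_big
  } else if (dist$kind == "gaussian") {
    d[inside] <- stats::dnorm(E[inside], dist$center, dist$sigma) / dist$trunc_z
  } else if (dist$kind == "gaussian-mixture") {
    cm <- dist$components
    for (i in seq_len(nrow(cm))) {
      ok <- inside & abs(E - cm$center[i]) <= 6 * cm$sd[i]
      d[ok] <- d[ok] + cm$weight[i] *
        stats::dnorm(E[ok], cm$center[i], cm$sd[i]) / dist$trunc_z
    }
  } else {
    d[inside] <- stats::approx(dist$grid, dist$density, E[inside],
                               rule = 2)$y
  }
  d
}

#' Draw line energies from g(E)
#'
#' @param dist a \code{\link{spectral_distribution}}.
#' @param n number of draws.
#' @return numeric vector of energies in meV.
#' @export
sample_lines <- function(dist, n) {
  stopifnot(inherits(dist, "spectral_distribution"))
  if (n == 0) return(numeric(0))
  if (dist$kind == "uniform") {
    stats::runif(n, dist$support[1], dist$support[2])
  } else if (dist$kind == "gaussian") {
    # inverse-CDF draw on the +-6 sigma truncation
    u <- stats::runif(n, stats::pnorm(-6), stats::pnorm(6))
    dist$center + dist$sigma * stats::qnorm(u)
  } else if (dist$kind == "gaussian-mixture") {
    cm <- dist$components
    comp <- sample.int(nrow(cm), n, replace = TRUE, prob = cm$weight)
    u <- stats::runif(n, stats::pnorm(-6), stats::pnorm(6))
    cm$center[comp] + cm$sd[comp] * stats::qnorm(u)
  } else {
    u <- stats::runif(n)
    stats::approx(dist$cdf, dist$grid, u, rule = 2, ties = "ordered")$y
  }
}

#' Per-line measurement noise model
#'
#' The fluctuation \eqn{E'} of a measured line energy about its mean is
#' modeled either as a Gaussian with standard deviation \eqn{\sigma_\varphi},
#' or as a zero-centered generalized Gaussian
#' \deqn{\varphi(E') = \frac{\beta}{2\alpha\Gamma(1/\beta)}
#'   e^{-(|E'|/\alpha)^\beta},}
#' which captures the Lorentzian-like tails of measured LP line jitter
#' (\eqn{\beta = 2} recovers a Gaussian with \eqn{\sigma_\varphi =
#' \alpha/\sqrt{2}}).
#'
#' A scale of exactly zero is accepted and denotes noiseless measurement
#' (all fluctuation mass at 0); planning routines treat it as a degenerate
#' case.
#'
#' @param family \code{"gaussian"} or \code{"generalized-gaussian"}.
#' @param sigma_phi Gaussian standard deviation in meV.
#' @param alpha generalized-Gaussian scale in meV.
#' @param beta generalized-Gaussian exponent (> 0).
#' @return an object of class \code{"noise_model"}.
#' @seealso \code{\link{noise_preset}}, \code{\link{noise_error}},
#'   \code{\link{fit_noise}}
#' @export
noise_model <- function(family = c("gaussian", "generalized-gaussian"),
                        sigma_phi = NULL, alpha = NULL, beta = NULL) {
  family <- match.arg(family)
  if (family == "gaussian") {
    stopifnot_scalar(sigma_phi, "sigma_phi", 0)
    out <- list(family = family, sigma_phi = sigma_phi)
  } else {
    stopifnot_scalar(alpha, "alpha", 0)
    stopifnot_scalar(beta, "beta", 0, strict_lower = TRUE)
    out <- list(family = family, alpha = alpha, beta = beta)
  }
  structure(out, class = "noise_model")
}

#' Named noise presets from measured LP line jitter
#'
#' Two fitted generalized-Gaussian regimes are provided as presets:
#' \code{"microscope"} (\eqn{\alpha = 0.047} meV, \eqn{\beta = 1.28};
#' confocal readout, 156 LPs tracked over repeated spectra) and
#' \code{"flow"} (\eqn{\alpha = 0.25} meV, \eqn{\beta = 1.37}; flow
#' cytometer readout).
#'
#' @param name \code{"microscope"} or \code{"flow"}.
#' @return a \code{\link{noise_model}}.
#' @export
noise_preset <- function(name = c("microscope", "flow")) {
  name <- match.arg(name)
  if (name == "microscope")
    noise_model("generalized-gaussian", alpha = 0.047, beta = 1.28)
  else
    noise_model("generalized-gaussian", alpha = 0.25, beta = 1.37)
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$family == "gaussian")
    cat(sprintf("Noise model: gaussian, sigma_phi = %g meV\n", x$sigma_phi))
  else
    cat(sprintf("Noise model: generalized gaussian, alpha = %g meV, beta = %g\n",
                x$alpha, x$beta))
  invisible(x)
}

# P(|E'| <= delta): the single-line probability of staying inside the gate.
noise_interval_prob <- function(noise, delta) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(delta < 0)) stop("'delta' must be non-negative")
  if (noise$family == "gaussian") {
    if (noise$sigma_phi == 0) return(rep(1, length(delta)))
    2 * stats::pnorm(delta / noise$sigma_phi) - 1
  } else {
    if (noise$alpha == 0) return(rep(1, length(delta)))
    # regularized lower incomplete gamma P(1/beta, (delta/alpha)^beta)
    stats::pgamma((delta / noise$alpha)^noise$beta, shape = 1 / noise$beta)
  }
}

# Standard deviation of the fluctuation distribution.
noise_sd <- function(noise) {
  if (noise$family == "gaussian") return(noise$sigma_phi)
  noise$alpha * sqrt(exp(lgamma(3 / noise$beta) - lgamma(1 / noise$beta)))
}

# Draws from phi(E'). Generalized Gaussian via |X| = alpha * W^(1/beta),
# W ~ Gamma(1/beta, 1), with a random sign.
noise_sample <- function(noise, n) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$family == "gaussian") {
    if (noise$sigma_phi == 0) return(numeric(n))
    stats::rnorm(n, 0, noise$sigma_phi)
  } else {
    if (noise$alpha == 0) return(numeric(n))
    w <- stats::rgamma(n, shape = 1 / noise$beta)
    sign(stats::runif(n) - 0.5) * noise$alpha * w^(1 / noise$beta)
  }
}

# Log-density of the generalized Gaussian (used by fit_noise).
dgengauss_log <- function(x, alpha, beta) {
  log(beta) - log(2 * alpha) - lgamma(1 / beta) - (abs(x) / alpha)^beta
}

#' Joint barcode distribution G_m, with optional dual-mode subpopulation
#'
#' The sorted energies of an \eqn{m}-line barcode drawn from a common LP pool
#' follow \eqn{G_m(E_1,\ldots,E_m) = m!\,\prod_i g(E_i)} when every LP emits
#' a single mode. A fraction \code{f_dm} of barcodes instead contains exactly
#' one dual-mode LP, whose two lines are separated by its free spectral range
#' (FSR); this yields the mixture \eqn{G_m = (1-f_{dm}) G_{sm} + f_{dm}
#' G_{dm}}. Barcodes with two or more dual-mode LPs are neglected
#' (\eqn{f_{dm} \ll 1}).
#'
#' @param base a \code{\link{spectral_distribution}} for single lines.
#' @param f_dm fraction of barcodes carrying one dual-mode LP, in [0, 1].
#'   Only applies to multiplicities \eqn{m \ge 2}.
#' @param fsr length-2 numeric: bounds (meV) of the uniform FSR (dual-mode
#'   line spacing) distribution; default \code{c(50, 70)}.
#' @return an object of class \code{"joint_barcode_distribution"}.
#' @export
joint_barcode_distribution <- function(base, f_dm = 0, fsr = c(50, 70)) {
  stopifnot(inherits(base, "spectral_distribution"))
  stopifnot_scalar(f_dm, "f_dm", 0, 1)
  if (length(fsr) != 2 || any(fsr <= 0) || fsr[2] < fsr[1])
    stop("'fsr' must be positive ascending bounds")
  structure(list(base = base, f_dm = f_dm, fsr = fsr),
            class = "joint_barcode_distribution")
}

#' @export
print.joint_barcode_distribution <- function(x, ...) {
  cat("Joint barcode distribution G_m\n")
  print(x$base)
  if (x$f_dm > 0)
    cat(sprintf("  dual-mode fraction f_dm = %g, FSR ~ U[%g, %g] meV\n",
                x$f_dm, x$fsr[1], x$fsr[2]))
  invisible(x)
}

# Draw n sorted m-line barcodes from G_m; returns an n x m matrix.
joint_sample <- function(joint, m, n) {
  stopifnot(inherits(joint, "joint_barcode_distribution"), m >= 1, n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, m))
  E <- matrix(sample_lines(joint$base, n * m), n, m)
  if (joint$f_dm > 0 && m >= 2) {
    dual <- stats::runif(n) < joint$f_dm
    nd <- sum(dual)
    if (nd > 0) {
      f <- stats::runif(nd, joint$fsr[1], joint$fsr[2])
      # columns m-1, m hold the correlated pair before sorting
      E[dual, m] <- E[dual, m - 1] + f
    }
  }
  t(apply(E, 1, sort))
}

# Density of G_m at sorted rows of E (n x m matrix).
joint_density <- function(joint, E) {
  stopifnot(inherits(joint, "joint_barcode_distribution"))
  if (is.vector(E)) E <- matrix(E, 1)
  m <- ncol(E)
  gE <- matrix(line_density(joint$base, E), nrow(E), m)
  g_sm <- factorial(m) * apply(gE, 1, prod)
  if (joint$f_dm == 0 || m < 2) return(g_sm)
  # one dual-mode pair occupying sorted slots (i, j), i < j:
  # (m-2)! * g(E_i) * f_FSR(E_j - E_i) * prod_{k != i,j} g(E_k)
  f_lo <- joint$fsr[1]; f_hi <- joint$fsr[2]
  f_dens <- 1 / (f_hi - f_lo)
  g_dm <- numeric(nrow(E))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      sp <- E[, j] - E[, i]
      ok <- sp >= f_lo & sp <= f_hi
      if (!any(ok)) next
      others <- setdiff(seq_len(m), c(i, j))
      prod_o <- if (length(others))
        apply(gE[ok, others, drop = FALSE], 1, prod) else 1
      g_dm[ok] <- g_dm[ok] +
        factorial(m - 2) * gE[ok, i] * f_dens * prod_o
    }
  }
  (1 - joint$f_dm) * g_sm + joint$f_dm * g_dm
}

#' Tagging multiplicity model
#'
#' Number of LPs acquired per cell: either fixed at \code{m}, or Poisson
#' with mean tagging ratio \code{lambda} (stochastic tagging). Untagged
#' cells (\eqn{m = 0}) carry no barcode; by default they are excluded from
#' the barcoded pool and reported separately as tagging loss.
#'
#' @param mode \code{"fixed"} or \code{"poisson"}.
#' @param m fixed multiplicity (lines per cell).
#' @param lambda mean LPs per cell in Poisson mode.
#' @param include_untagged keep \eqn{m=0} cells in denominators (default
#'   \code{FALSE}).
#' @return an object of class \code{"tagging_mixture"}.
#' @export
tagging_mixture <- function(mode = c("fixed", "poisson"), m = NULL,
                            lambda = NULL, include_untagged = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot_scalar(m, "m", 1)
    out <- list(mode = mode, m = as.integer(m),
                include_untagged = include_untagged)
  } else {
    stopifnot_scalar(lambda, "lambda", 0, strict_lower = TRUE)
    out <- list(mode = mode, lambda = lambda,
                include_untagged = include_untagged)
  }
  structure(out, class = "tagging_mixture")
}

#' @export
print.tagging_mixture <- function(x, ...) {
  if (x$mode == "fixed")
    cat(sprintf("Tagging: fixed multiplicity m = %d\n", x$m))
  else
    cat(sprintf("Tagging: Poisson, lambda = %g LPs/cell (untagged %s)\n",
                x$lambda,
                if (x$include_untagged) "included" else "excluded"))
  invisible(x)
}

# Multiplicity weights over m >= 1 (renormalized when untagged excluded),
# truncated where the cumulative Poisson mass reaches 1 - 1e-6.
tagging_weights <- function(tagging) {
  stopifnot(inherits(tagging, "tagging_mixture"))
  if (tagging$mode == "fixed") {
    return(list(m = tagging$m, w = 1, w0 = 0))
  }
  lam <- tagging$lambda
  m_max <- stats::qpois(1 - 1e-6, lam)
  m_max <- max(m_max, 1)
  m <- seq_len(m_max)
  w <- stats::dpois(m, lam)
  w0 <- stats::dpois(0, lam)
  if (!tagging$include_untagged) w <- w / sum(w)  # renormalize over m >= 1
  list(m = m, w = w, w0 = w0)
}

#' Discrete spectral palette
#'
#' Discrete-level barcoding: \code{l} distinguishable colors (spectral bins)
#' and multiplicity \code{m} LPs per cell. When a bin spacing \code{gap}
#' (\eqn{2\delta}, meV) is given, \code{l} can be derived from a band width
#' via \eqn{l = \Delta / 2\delta}.
#'
#' @param l number of distinguishable colors; \code{l >= m}.
#' @param m barcode multiplicity.
#' @param gap optional bin spacing \eqn{2\delta} in meV.
#' @return an object of class \code{"discrete_palette"}.
#' @export
discrete_palette <- function(l, m, gap = NULL) {
  stopifnot_scalar(l, "l", 1)
  stopifnot_scalar(m, "m", 1)
  if (l < m) stop("'l' must be >= 'm' for combination counting")
  structure(list(l = as.integer(l), m = as.integer(m), gap = gap),
            class = "discrete_palette")
}

#' @export
print.discrete_palette <- function(x, ...) {
  cat(sprintf("Discrete palette: l = %d colors, m = %d LPs/cell", x$l, x$m))
  if (!is.null(x$gap)) cat(sprintf(", bin spacing %g meV", x$gap))
  cat("\n")
  invisible(x)
}
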