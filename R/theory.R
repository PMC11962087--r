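#' Number of unique discrete barcodes
#'
#' With \code{l} distinguishable colors and \code{m} LPs per cell (each color
#' used at most once, order irrelevant) the number of unique barcodes is the
#' binomial coefficient \eqn{B = C(l, m)}. For \eqn{l \gg m} this is well
#' approximated by \eqn{l^m / m!}.
#'
#' @param palette a \code{\link{discrete_palette}}.
#' @param approx if \code{TRUE} return the \eqn{l^m/m!} approximation.
#' @return barcode count (exact integer-valued double, or the approximation).
#' @examples
#' count_unique_barcodes(discrete_palette(100, 3))   # 161700
#' @export
count_unique_barcodes <- function(palette, approx = FALSE) {
  stopifnot(inherits(palette, "discrete_palette"))
  if (approx) return(palette$l^palette$m / factorial(palette$m))
  choose(palette$l, palette$m)
}

#' Barcode duplicate rate for discrete levels
#'
#' Probability that a given cell's barcode is also carried by at least one
#' other cell when \code{N} cells draw uniformly from \code{B} equiprobable
#' barcodes:
#' \deqn{\varepsilon_{dup} = 1 - (1 - 1/B)^{N-1} \approx N/B,}
#' the approximation holding for \eqn{B \gg N}.
#'
#' @param B number of unique barcodes (\eqn{\ge 1}).
#' @param N pool size, number of tagged cells (\eqn{\ge 1}).
#' @param exact use the exact form (default); otherwise the \eqn{N/B}
#'   approximation.
#' @return duplicate rate in [0, 1].
#' @export
duplicate_rate_discrete <- function(B, N, exact = TRUE) {
  stopifnot_scalar(B, "B", 1)
  stopifnot_scalar(N, "N", 1)
  if (!exact) return(clamp01(N / B))
  1 - (1 - 1 / B)^(N - 1)
}

#' Minimum number of unique barcodes for a target duplicate rate
#'
#' Smallest \code{B} keeping the duplicate rate of an \code{N}-cell pool at
#' or below \code{eps0}. Under the planning approximation
#' \eqn{\varepsilon \approx N/B} this is \eqn{\lceil N/\varepsilon_0
#' \rceil}; the exact-form solution of \eqn{1-(1-1/B)^{N-1} = \varepsilon_0}
#' is also returned.
#'
#' @param N pool size (\eqn{\ge 2}).
#' @param eps0 tolerated duplicate rate, \eqn{0 < \varepsilon_0 < 1}.
#' @return list with \code{B} (approximation, the planning answer) and
#'   \code{B_exact} (exact-form solution, real-valued).
#' @examples
#' min_unique_barcodes(1e4, 0.01)$B   # 1e6
#' @export
min_unique_barcodes <- function(N, eps0) {
  stopifnot_scalar(N, "N", 2)
  stopifnot_scalar(eps0, "eps0", 0, strict_lower = TRUE)
  if (eps0 >= 1) stop("'eps0' must be < 1")
  B_approx <- ceiling(N / eps0)
  # exact: 1 - (1 - 1/B)^(N-1) = eps0  =>  B = 1 / (1 - (1-eps0)^(1/(N-1)))
  B_exact <- 1 / (1 - (1 - eps0)^(1 / (N - 1)))
  list(B = B_approx, B_exact = B_exact)
}

#' Effective number of unique barcodes in a continuous spectrum
#'
#' For a uniform line distribution of width \eqn{\Delta} and a Chebyshev
#' matching half-gap \eqn{\delta}, the continuous analogue of the discrete
#' barcode count is
#' \deqn{B_{eff} = \frac{1}{m!}\left(\frac{\Delta}{2\delta}\right)^m,}
#' the ratio of the barcode-space volume to the volume claimed by a single
#' barcode.
#'
#' @param dist a uniform \code{\link{spectral_distribution}} (defined only
#'   for the uniform case).
#' @param delta matching half-gap \eqn{\delta} in meV; \eqn{2\delta <
#'   \Delta}.
#' @param m multiplicity.
#' @return effective barcode count.
#' @export
effective_barcodes <- function(dist, delta, m) {
  stopifnot(inherits(dist, "spectral_distribution"))
  if (dist$kind != "uniform")
    stop("B_eff is defined only for the uniform distribution")
  stopifnot_scalar(delta, "delta", 0, strict_lower = TRUE)
  stopifnot_scalar(m, "m", 1)
  if (2 * delta >= dist$delta_big) stop("need 2*delta < Delta")
  (dist$delta_big / (2 * delta))^m / factorial(m)
}

# eps_dup(delta, N) closure for a joint distribution at fixed m.
# Uniform + f_dm = 0 uses the closed form (stderr 0); otherwise a
# Monte-Carlo estimate over a sample drawn once (common random numbers,
# so the function is smooth in delta and reusable across N).
make_eps_dup_fun <- function(joint, m, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(joint, "joint_barcode_distribution"))
  if (joint$base$kind == "uniform" && joint$f_dm == 0) {
    Delta <- joint$base$delta_big
    f <- function(delta, N) {
      B_eff <- (Delta / (2 * delta))^m / factorial(m)
      # (2 delta)^m G_m = 1/B_eff can exceed 1 for large delta: clamp
      p <- clamp01(1 / B_eff)
      list(rate = 1 - (1 - p)^(N - 1), stderr = 0)
    }
    attr(f, "path") <- "closed-form"
    return(f)
  }
  if (is.null(seed))
    stop("Monte-Carlo evaluation of eps_dup requires an explicit 'seed'")
  if (n_mc < 1e3) stop("'n_mc' must be >= 1000")
  G <- with_seed(seed, {
    E <- joint_sample(joint, m, n_mc)
    joint_density(joint, E)
  })
  f <- function(delta, N) {
    p <- clamp01(1 - clamp01((2 * delta)^m * G))^(N - 1)
    list(rate = 1 - mean(p), stderr = stats::sd(p) / sqrt(length(p)))
  }
  attr(f, "path") <- "monte-carlo"
  f
}

#' Barcode duplicate rate for continuous spectra
#'
#' Evaluates
#' \deqn{\varepsilon_{dup} = 1 - \int G_m(E)\,
#'   \bigl(1 - (2\delta)^m G_m(E)\bigr)^{N-1} dE}
#' over the \eqn{m}-dimensional sorted-energy space. For a uniform line
#' distribution without dual-mode LPs the integral collapses to the closed
#' form \eqn{1 - (1 - 1/B_{eff})^{N-1}}; otherwise it is estimated by Monte
#' Carlo, drawing \eqn{E \sim G_m} and averaging the clamped survival term.
#' The integrand factor \eqn{(2\delta)^m G_m(E)} is a probability and is
#' clamped to [0, 1] before exponentiation.
#'
#' @param joint a \code{\link{joint_barcode_distribution}}.
#' @param m multiplicity.
#' @param delta matching half-gap in meV (> 0).
#' @param N pool size (\eqn{\ge 1}).
#' @param n_mc Monte-Carlo sample size (default 1e5).
#' @param seed integer seed, required on the Monte-Carlo path.
#' @return list with \code{rate} and \code{mc_stderr} (0 for closed form).
#' @export
duplicate_rate_continuous <- function(joint, m, delta, N, n_mc = 1e5,
                                      seed = NULL) {
  stopifnot_scalar(m, "m", 1)
  stopifnot_scalar(delta, "delta", 0, strict_lower = TRUE)
  stopifnot_scalar(N, "N", 1)
  f <- make_eps_dup_fun(joint, m, n_mc, seed)
  r <- f(delta, N)
  list(rate = r$rate, mc_stderr = r$stderr, path = attr(f, "path"))
}

#' Noise-induced misidentification rate
#'
#' Probability that two measurements of the same \eqn{m}-line barcode differ
#' by more than the gate on at least one line:
#' \deqn{\varepsilon_{noise} = 1 - \left(\int_{-\delta}^{\delta}
#'   \varphi(E')\,dE'\right)^m.}
#' The inner integral is \eqn{\mathrm{erf}(\delta/\sigma_\varphi\sqrt{2})}
#' for Gaussian noise and the regularized lower incomplete gamma
#' \eqn{P(1/\beta, (\delta/\alpha)^\beta)} for generalized-Gaussian noise.
#'
#' @param noise a \code{\link{noise_model}}.
#' @param delta matching half-gap in meV (\eqn{\ge 0}).
#' @param m multiplicity (\eqn{\ge 1}).
#' @return error rate in [0, 1]; vectorized over \code{delta}.
#' @export
noise_error <- function(noise, delta, m) {
  stopifnot_scalar(m, "m", 1)
  if (any(delta < 0)) stop("'delta' must be >= 0")
  1 - noise_interval_prob(noise, delta)^m
}

#' Compound total error rate
#'
#' Combines duplication and noise errors assuming independence:
#' \eqn{\varepsilon_{tot} = \varepsilon_{dup} + \varepsilon_{noise} -
#' \varepsilon_{dup}\varepsilon_{noise}}.
#'
#' @param eps_dup,eps_noise rates in [0, 1] (vectorized).
#' @return total error rate in [0, 1].
#' @export
total_error <- function(eps_dup, eps_noise) {
  if (any(eps_dup < 0 | eps_dup > 1) || any(eps_noise < 0 | eps_noise > 1))
    stop("error rates must lie in [0, 1]")
  eps_dup + eps_noise - eps_dup * eps_noise
}

#' Optimal matching half-gap
#'
#' Finds \eqn{\delta_{opt}} minimizing the total error
#' \eqn{\varepsilon_{tot}(\delta) =
#' \varepsilon_{dup}(\delta) \oplus \varepsilon_{noise}(\delta)} by a
#' log-spaced grid scan over \eqn{[10^{-3}, \Delta/2]} meV followed by
#' golden-section refinement in the best bracket. \eqn{\varepsilon_{tot}} is
#' assumed unimodal in \eqn{\delta}; the grid guards against mild
#' violations.
#'
#' @param joint a \code{\link{joint_barcode_distribution}}.
#' @param noise a \code{\link{noise_model}}.
#' @param m multiplicity.
#' @param N pool size (\eqn{\ge 2}).
#' @param n_mc,seed Monte-Carlo controls for non-uniform distributions.
#' @param n_grid number of grid points (default 200).
#' @return list with \code{delta_opt} (meV), \code{eps_min},
#'   \code{eps_dup}, \code{eps_noise} at the optimum, and \code{status}
#'   (\code{"ok"} or \code{"degenerate-noise"}).
#' @export
optimize_delta <- function(joint, noise, m, N, n_mc = 1e5, seed = NULL,
                           n_grid = 200) {
  stopifnot_scalar(N, "N", 2)
  eps_dup_fun <- make_eps_dup_fun(joint, m, n_mc, seed)
  if (noise_sd(noise) == 0) {
    warning("degenerate (zero-scale) noise: delta_opt at lower search bound")
    d <- 1e-3
    r <- eps_dup_fun(d, N)
    return(list(delta_opt = d, eps_min = r$rate, eps_dup = r$rate,
                eps_noise = 0, status = "degenerate-noise"))
  }
  f <- function(delta)
    total_error(clamp01(eps_dup_fun(delta, N)$rate),
                noise_error(noise, delta, m))
  hi <- joint$base$delta_big / 2
  grid <- exp(seq(log(1e-3), log(hi), length.out = n_grid))
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo_b <- grid[max(i - 1, 1)]
  hi_b <- grid[min(i + 1, n_grid)]
  opt <- stats::optimize(f, interval = c(lo_b, hi_b))
  if (opt$objective <= vals[i]) {
    d <- opt$minimum; v <- opt$objective
  } else {
    d <- grid[i]; v <- vals[i]
  }
  list(delta_opt = d, eps_min = v,
       eps_dup = eps_dup_fun(d, N)$rate,
       eps_noise = noise_error(noise, d, m), status = "ok")
}

#' Maximum pool size under an error tolerance
#'
#' Largest integer \code{N} whose minimized total error
#' \eqn{\varepsilon_{min}(N)} stays at or below \code{eps0}, found by
#' integer bisection over \eqn{N \in [2, 10^{12}]} using the monotonicity
#' of \eqn{\varepsilon_{min}} in \code{N}. Returns 0 if even \eqn{N = 2}
#' exceeds the tolerance.
#'
#' @inheritParams optimize_delta
#' @param eps0 error tolerance, \eqn{0 < \varepsilon_0 < 1}.
#' @return maximum pool size (double; capped at 1e12).
#' @export
max_pool_size <- function(joint, noise, m, eps0, n_mc = 1e5, seed = NULL) {
  stopifnot_scalar(eps0, "eps0", 0, strict_lower = TRUE)
  if (eps0 >= 1) stop("'eps0' must be < 1")
  eps_dup_fun <- make_eps_dup_fun(joint, m, n_mc, seed)
  eps_min <- function(N) {
    f <- function(delta)
      total_error(clamp01(eps_dup_fun(delta, N)$rate),
                  noise_error(noise, delta, m))
    hi <- joint$base$delta_big / 2
    grid <- exp(seq(log(1e-3), log(hi), length.out = 200))
    vals <- vapply(grid, f, numeric(1))
    i <- which.min(vals)
    opt <- stats::optimize(f, interval = c(grid[max(i - 1, 1)],
                                           grid[min(i + 1, 200)]))
    min(opt$objective, vals[i])
  }
  if (eps_min(2) > eps0) return(0)
  lo <- 2; hi <- 4
  while (hi < 1e12 && eps_min(hi) <= eps0) {
    lo <- hi; hi <- hi * 16
  }
  if (hi >= 1e12 && eps_min(1e12) <= eps0) return(1e12)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (eps_min(mid) <= eps0) lo <- mid else hi <- mid
  }
  lo
}

#' Error rates under Poisson tagging multiplicity
#'
#' Under stochastic tagging, multiplicity varies across cells; since
#' measurements of different multiplicities are presumed to come from
#' distinct barcodes, duplication only occurs within each multiplicity
#' class. For each \eqn{m \ge 1} (up to the cumulative Poisson mass
#' \eqn{1 - 10^{-6}}) the sub-pool of size \eqn{N w_m} contributes
#' \eqn{\varepsilon_{dup}(m, N w_m)} and \eqn{\varepsilon_{noise}(m)}; the
#' pool-level rates are the weight-averaged sums.
#'
#' @param tagging a \code{\link{tagging_mixture}}.
#' @param joint a \code{\link{joint_barcode_distribution}}.
#' @param noise a \code{\link{noise_model}}.
#' @param delta matching half-gap in meV.
#' @param N pool size (barcoded cells, i.e. after untagged removal).
#' @param n_mc,seed Monte-Carlo controls for non-uniform distributions.
#' @return list with \code{per_m} (data.frame: m, weight, N_m, eps_dup,
#'   eps_noise, contribution), weighted \code{eps_dup}, \code{eps_noise},
#'   \code{eps_tot}, and \code{tagging_loss} (Poisson \eqn{w_0}).
#' @export
mixture_error_rates <- function(tagging, joint, noise, delta, N,
                                n_mc = 1e5, seed = NULL) {
  stopifnot_scalar(delta, "delta", 0, strict_lower = TRUE)
  tw <- tagging_weights(tagging)
  eps_dup_m <- numeric(length(tw$m))
  eps_noise_m <- numeric(length(tw$m))
  for (i in seq_along(tw$m)) {
    m <- tw$m[i]
    N_m <- N * tw$w[i]
    f <- make_eps_dup_fun(joint, m, n_mc, split_seed(seed, m))
    eps_dup_m[i] <- if (N_m > 1) clamp01(f(delta, N_m)$rate) else 0
    eps_noise_m[i] <- noise_error(noise, delta, m)
  }
  eps_dup <- sum(tw$w * eps_dup_m)
  eps_noise <- sum(tw$w * eps_noise_m)
  list(per_m = data.frame(m = tw$m, weight = tw$w, N_m = N * tw$w,
                          eps_dup = eps_dup_m, eps_noise = eps_noise_m,
                          contribution = tw$w * eps_dup_m),
       eps_dup = eps_dup, eps_noise = eps_noise,
       eps_tot = total_error(clamp01(eps_dup), clamp01(eps_noise)),
       tagging_loss = tw$w0)
}

#' Duplicate-induced sample loss at a fixed noise budget
#'
#' When duplicates can be detected and discarded (treated as sample loss
#' rather than misidentification), the gate is chosen so that the weighted
#' noise error equals the tolerance: solve \eqn{\varepsilon_{noise}(\delta)
#' = \varepsilon_0} for \eqn{\delta} (bisection; \eqn{\varepsilon_{noise}}
#' is decreasing in \eqn{\delta}), then report the weighted
#' \eqn{\varepsilon_{dup}} at that gate as the duplicate-induced loss
#' fraction.
#'
#' @inheritParams mixture_error_rates
#' @param eps0 tolerated noise error, \eqn{0 < \varepsilon_0 < 1}.
#' @return list with \code{loss} (duplicate fraction), \code{delta} (meV),
#'   \code{status} (\code{"ok"} or \code{"noise-budget-unreachable"}), and
#'   the underlying \code{rates} table.
#' @export
duplicate_loss <- function(tagging, joint, noise, N, eps0,
                           n_mc = 1e5, seed = NULL) {
  stopifnot_scalar(eps0, "eps0", 0, strict_lower = TRUE)
  if (eps0 >= 1) stop("'eps0' must be < 1")
  tw <- tagging_weights(tagging)
  wnoise <- function(delta)
    sum(tw$w * (1 - noise_interval_prob(noise, delta)^tw$m))
  lo <- 1e-9; hi <- 1e4
  if (wnoise(hi) > eps0)
    return(list(loss = NA_real_, delta = NA_real_,
                status = "noise-budget-unreachable", rates = NULL))
  if (wnoise(lo) <= eps0) {
    delta <- lo  # even a vanishing gate meets the budget (near-zero noise)
  } else {
    delta <- stats::uniroot(function(d) wnoise(d) - eps0, c(lo, hi),
                            tol = 1e-12)$root
  }
  r <- mixture_error_rates(tagging, joint, noise, delta, N, n_mc, seed)
  list(loss = r$eps_dup, delta = delta, status = "ok", rates = r)
}
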