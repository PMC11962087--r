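#' Plan a barcoding experiment
#'
#' The central planning entry point: given the line distribution, the
#' measurement noise model, a tagging model and the intended pool size,
#' computes the optimal matching half-gap \eqn{\delta_{opt}}, the error
#' rates at that gate, the effective barcode count and the maximum pool
#' size compatible with the tolerance. For Poisson tagging the
#' duplicates-as-loss analysis is used: the gate is set by the noise
#' budget and the duplicate fraction is reported as sample loss.
#'
#' @param joint a \code{\link{joint_barcode_distribution}} (or a
#'   \code{\link{spectral_distribution}}, promoted with \code{f_dm = 0}).
#' @param noise a \code{\link{noise_model}}.
#' @param tagging a \code{\link{tagging_mixture}} (default: fixed
#'   \code{m = 3}).
#' @param N pool size (number of barcoded cells).
#' @param eps0 error tolerance (default 0.01).
#' @param n_mc,seed Monte-Carlo controls for non-uniform distributions.
#' @param max_pool also compute the maximum pool size at \code{eps0}
#'   (fixed-\code{m} tagging only; default \code{TRUE}).
#' @return an object of class \code{"lp_plan"} with fields \code{N},
#'   \code{delta}, \code{delta_opt}, \code{eps_dup}, \code{eps_noise},
#'   \code{eps_tot}, \code{eps_min}, \code{B}, \code{B_eff}, \code{eps0},
#'   \code{N_max}, \code{loss}, \code{mc_stderr}.
#' @examples
#' g <- spectral_distribution("uniform", delta_big = 300)
#' pl <- lp_plan(joint_barcode_distribution(g), noise_model("gaussian",
#'   sigma_phi = 0.1), tagging_mixture("fixed", m = 3), N = 1e4)
#' pl
#' @export
lp_plan <- function(joint, noise, tagging = tagging_mixture("fixed", m = 3),
                    N, eps0 = 0.01, n_mc = 1e5, seed = NULL,
                    max_pool = TRUE) {
  if (inherits(joint, "spectral_distribution"))
    joint <- joint_barcode_distribution(joint)
  stopifnot(inherits(joint, "joint_barcode_distribution"),
            inherits(noise, "noise_model"),
            inherits(tagging, "tagging_mixture"))
  stopifnot_scalar(N, "N", 2)
  out <- list(N = N, eps0 = eps0, tagging = tagging, joint = joint,
              noise = noise)
  if (tagging$mode == "fixed") {
    m <- tagging$m
    od <- optimize_delta(joint, noise, m, N, n_mc, seed)
    dr <- duplicate_rate_continuous(joint, m, od$delta_opt, N, n_mc, seed)
    out$m <- m
    out$delta <- out$delta_opt <- od$delta_opt
    out$eps_dup <- od$eps_dup
    out$eps_noise <- od$eps_noise
    out$eps_tot <- out$eps_min <- od$eps_min
    out$mc_stderr <- dr$mc_stderr
    out$B_eff <- if (joint$base$kind == "uniform" && joint$f_dm == 0)
      effective_barcodes(joint$base, od$delta_opt, m) else NA_real_
    out$N_max <- if (max_pool)
      max_pool_size(joint, noise, m, eps0, n_mc, seed) else NA_real_
    out$loss <- NA_real_
  } else {
    dl <- duplicate_loss(tagging, joint, noise, N, eps0, n_mc, seed)
    if (dl$status != "ok") stop("noise budget unreachable at eps0 = ", eps0)
    out$lambda <- tagging$lambda
    out$delta <- out$delta_opt <- dl$delta
    out$eps_dup <- dl$rates$eps_dup
    out$eps_noise <- dl$rates$eps_noise
    out$eps_tot <- out$eps_min <- dl$rates$eps_tot
    out$mc_stderr <- 0
    out$B_eff <- NA_real_
    out$N_max <- NA_real_
    out$loss <- dl$loss
    out$per_m <- dl$rates$per_m
    out$tagging_loss <- dl$rates$tagging_loss
  }
  structure(out, class = "lp_plan")
}

#' @export
print.lp_plan <- function(x, ...) {
  cat("LP barcoding plan\n")
  if (x$tagging$mode == "fixed")
    cat(sprintf("  N = %s cells, m = %d LPs/cell, eps0 = %g\n",
                format(x$N, big.mark = ","), x$m, x$eps0))
  else
    cat(sprintf("  N = %s cells, Poisson lambda = %g LPs/cell, eps0 = %g\n",
                format(x$N, big.mark = ","), x$lambda, x$eps0))
  cat(sprintf("  gate delta = %.4g meV\n", x$delta))
  cat(sprintf("  eps_dup = %.3g, eps_noise = %.3g, eps_tot = %.3g\n",
              x$eps_dup, x$eps_noise, x$eps_tot))
  if (is.finite(x$B_eff))
    cat(sprintf("  B_eff = %.4g unique barcodes\n", x$B_eff))
  if (is.finite(x$N_max))
    cat(sprintf("  max pool size at eps0: %s cells\n",
                format(x$N_max, big.mark = ",")))
  if (is.finite(x$loss))
    cat(sprintf("  duplicate-induced sample loss: %.2f%% (untagged loss %.2f%%)\n",
                100 * x$loss, 100 * x$tagging_loss))
  invisible(x)
}

#' Total-error sweep over the matching gate
#'
#' Evaluates \eqn{\varepsilon_{dup}}, \eqn{\varepsilon_{noise}} and
#' \eqn{\varepsilon_{tot}} on a log-spaced \eqn{\delta} grid for a plan's
#' conditions; useful for inspection and for the \code{plot} method.
#'
#' @param x an \code{"lp_plan"}.
#' @param n_grid grid size (default 100).
#' @return data.frame with columns \code{delta_meV}, \code{eps_dup},
#'   \code{eps_noise}, \code{eps_tot}.
#' @export
delta_sweep <- function(x, n_grid = 100) {
  stopifnot(inherits(x, "lp_plan"))
  m_eff <- if (x$tagging$mode == "fixed") x$m else x$lambda
  grid <- exp(seq(log(1e-3), log(x$joint$base$delta_big / 2),
                  length.out = n_grid))
  if (x$tagging$mode == "fixed") {
    f <- make_eps_dup_fun(x$joint, x$m, 1e4,
                          if (x$joint$base$kind == "uniform" &&
                              x$joint$f_dm == 0) NULL else 1L)
    ed <- vapply(grid, function(d) clamp01(f(d, x$N)$rate), numeric(1))
    en <- noise_error(x$noise, grid, x$m)
  } else {
    ed <- en <- numeric(n_grid)
    for (i in seq_along(grid)) {
      r <- mixture_error_rates(x$tagging, x$joint, x$noise, grid[i], x$N,
                               n_mc = 1e4, seed = 1L)
      ed[i] <- r$eps_dup; en[i] <- r$eps_noise
    }
  }
  data.frame(delta_meV = grid, eps_dup = ed, eps_noise = en,
             eps_tot = total_error(clamp01(ed), clamp01(en)))
}

#' @export
plot.lp_plan <- function(x, n_grid = 60, ...) {
  sw <- delta_sweep(x, n_grid)
  ylim <- range(pmax(c(sw$eps_dup, sw$eps_noise, sw$eps_tot), 1e-12))
  graphics::plot(sw$delta_meV, pmax(sw$eps_tot, 1e-12), type = "l",
                 log = "xy", lwd = 2, ylim = ylim,
                 xlab = expression(delta ~ "(meV)"),
                 ylab = "error rate", ...)
  graphics::lines(sw$delta_meV, pmax(sw$eps_dup, 1e-12), lty = 2)
  graphics::lines(sw$delta_meV, pmax(sw$eps_noise, 1e-12), lty = 3)
  graphics::abline(v = x$delta, col = "grey50")
  graphics::legend("bottomright",
                   c("eps_tot", "eps_dup", "eps_noise"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(sw)
}
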