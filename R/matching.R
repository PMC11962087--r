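#' Scoring parameters for cross-run barcode matching
#'
#' @param gate maximum per-line energy difference for two lines to be
#'   considered aligned, in meV (default 1.5).
#' @param gap_penalty score deduction per unmatched line (default 0.25).
#' @param min_matched_lines minimum aligned line pairs for a pair of
#'   barcodes to be a match candidate (default 2).
#' @return an object of class \code{"score_params"}.
#' @export
score_params <- function(gate = 1.5, gap_penalty = 0.25,
                         min_matched_lines = 2) {
  stopifnot_scalar(gate, "gate", 0, strict_lower = TRUE)
  stopifnot_scalar(gap_penalty, "gap_penalty", 0)
  stopifnot_scalar(min_matched_lines, "min_matched_lines", 1)
  structure(list(gate = gate, gap_penalty = gap_penalty,
                 min_matched_lines = as.integer(min_matched_lines)),
            class = "score_params")
}

#' Align the lines of two barcodes
#'
#' Order-preserving one-to-one assignment between two sorted line lists,
#' maximizing the number of matched pairs and, among maximal assignments,
#' minimizing the summed \eqn{|\Delta E|}; only pairs with \eqn{|\Delta E|
#' \le} \code{gate} may match. Computed by dynamic programming (sequence
#' alignment with gaps).
#'
#' @param a,b sorted numeric vectors of line energies (meV).
#' @param gate maximum per-line energy difference (meV).
#' @return list with \code{k} (matched pairs), \code{sum_abs_de},
#'   \code{pairs} (2-column matrix of 1-based indices into \code{a} and
#'   \code{b}).
#' @export
align_lines <- function(a, b, gate = 1.5) {
  if (is.unsorted(a) || is.unsorted(b))
    stop("barcode energies must be sorted ascending")
  r <- .align_pair_cpp(as.numeric(a), as.numeric(b), gate)
  list(k = r$k, sum_abs_de = r$sum_abs_de,
       pairs = cbind(i = r$i, j = r$j))
}

#' Score a candidate barcode pair
#'
#' Likelihood-style match score: over the aligned line pairs,
#' \deqn{s = \sum_{pairs} \left(1 - \frac{|\Delta E|}{gate}\right)
#'   - gap\_penalty \times (m_a + m_b - 2k),}
#' so a perfect \eqn{m}-line match scores \eqn{m} and every unmatched line
#' costs \code{gap_penalty}. Pairs with fewer than
#' \code{min_matched_lines} aligned lines are non-candidates and score
#' \code{-Inf}. Symmetric in its arguments.
#'
#' @param a,b sorted numeric vectors of line energies (meV).
#' @param params a \code{\link{score_params}}.
#' @return numeric score (\code{-Inf} for non-candidates).
#' @export
score_pair <- function(a, b, params = score_params()) {
  al <- align_lines(a, b, params$gate)
  if (al$k < params$min_matched_lines) return(-Inf)
  al$k - al$sum_abs_de / params$gate -
    params$gap_penalty * (length(a) + length(b) - 2 * al$k)
}

# flat (offsets, energies) view of a pool for the C++ scorer
pool_flat <- function(pool) {
  list(off = pool$offsets, en = pool$energies)
}

#' Cross- and self-match score distributions for two pools
#'
#' Generates candidate pairs through a sorted 1-D line index (a pair is a
#' candidate iff the two cells share at least one line within the gate and
#' at least \code{min_matched_lines} lines align), then scores candidates:
#' \eqn{S_{cross}} over \eqn{C_1 \times C_2} and \eqn{S_{self} = S_{11}
#' \cup S_{22}} over within-run pairs excluding self-comparisons.
#'
#' @param c1,c2 \code{\link{barcode_pool}} objects (non-empty).
#' @param params a \code{\link{score_params}}.
#' @param detail_min only candidate pairs with score at or above this value
#'   are returned with cell-level detail (ids, matched-line counts);
#'   \code{-Inf} (default) returns detail for all candidates. Score
#'   vectors are always complete.
#' @return list with \code{cross} (data.frame: i, j, c1_id, c2_id, score,
#'   k_matched, mean_abs_dE), \code{cross_scores}, \code{self_scores},
#'   and sub-vectors \code{s11}, \code{s22}.
#' @export
build_score_sets <- function(c1, c2, params = score_params(),
                             detail_min = -Inf) {
  stopifnot(inherits(c1, "barcode_pool"), inherits(c2, "barcode_pool"))
  if (length(c1) == 0 || length(c2) == 0) stop("pools must be non-empty")
  f1 <- pool_flat(c1); f2 <- pool_flat(c2)
  cr <- .score_pools_cpp(f1$off, f1$en, f2$off, f2$en, params$gate,
                         params$gap_penalty, params$min_matched_lines,
                         FALSE, detail_min)
  s11 <- .score_pools_cpp(f1$off, f1$en, f1$off, f1$en, params$gate,
                          params$gap_penalty, params$min_matched_lines,
                          TRUE, Inf)
  s22 <- .score_pools_cpp(f2$off, f2$en, f2$off, f2$en, params$gate,
                          params$gap_penalty, params$min_matched_lines,
                          TRUE, Inf)
  # detail-row scores recomputed from their components (k, mean |dE|)
  sc <- cr$k - cr$k * cr$mean_abs_de / params$gate -
    params$gap_penalty * (pool_multiplicities(c1)[cr$i] +
                          pool_multiplicities(c2)[cr$j] - 2 * cr$k)
  cross <- data.frame(i = cr$i, j = cr$j,
                      c1_id = c1$cell_id[cr$i], c2_id = c2$cell_id[cr$j],
                      score = sc,
                      k_matched = cr$k, mean_abs_dE = cr$mean_abs_de,
                      stringsAsFactors = FALSE)
  list(cross = cross, cross_scores = cr$scores,
       self_scores = c(s11$scores, s22$scores),
       s11 = s11$scores, s22 = s22$scores, params = params)
}

#' Select the match-acceptance threshold from self-match scores
#'
#' Correct matches form a high-score subpopulation present in
#' \eqn{S_{cross}} but absent in \eqn{S_{self}}; the threshold is taken as
#' the \eqn{1-q} upper quantile of the self-match scores (default
#' \eqn{q = 10^{-5}}), floored at the maximum observed self score when
#' \eqn{q < 1/|S_{self}|}. Finite scores only.
#'
#' @param self_scores numeric vector of self-match scores (non-empty), or a
#'   list from \code{\link{build_score_sets}}.
#' @param q upper tail mass (default 1e-5).
#' @return threshold score.
#' @export
select_threshold <- function(self_scores, q = 1e-5) {
  if (is.list(self_scores)) self_scores <- self_scores$self_scores
  s <- self_scores[is.finite(self_scores)]
  if (length(s) == 0)
    stop("empty self-score set: supply an explicit threshold")
  stopifnot_scalar(q, "q", 0, 1, strict_lower = TRUE)
  if (q < 1 / length(s)) return(max(s))
  stats::quantile(s, 1 - q, names = FALSE, type = 7)
}

#' Match cells between two measurement runs
#'
#' Full cross-run matching: candidate scoring, threshold selection from the
#' self-match score distribution (unless an explicit \code{threshold} is
#' given), and greedy one-to-one resolution of above-threshold cross pairs
#' in descending score order (ties broken by smaller mean \eqn{|\Delta E|},
#' then lexicographic cell ids). A multiplicity confusion table of the
#' accepted matches is included.
#'
#' @param c1,c2 \code{\link{barcode_pool}} objects.
#' @param params a \code{\link{score_params}}.
#' @param threshold explicit score cutoff; default \code{NULL} selects it
#'   via \code{\link{select_threshold}}.
#' @param q upper tail mass for threshold selection (default 1e-5).
#' @return an object of class \code{"lp_matchset"}: accepted \code{matches}
#'   (data.frame c1_id, c2_id, score, k_matched, mean_abs_dE),
#'   \code{threshold}, \code{match_rate} (matches / smaller run size),
#'   \code{confusion} (multiplicity table), and score-distribution
#'   summaries.
#' @export
match_pools <- function(c1, c2, params = score_params(), threshold = NULL,
                        q = 1e-5) {
  stopifnot(inherits(c1, "barcode_pool"), inherits(c2, "barcode_pool"))
  f1 <- pool_flat(c1); f2 <- pool_flat(c2)
  s11 <- .score_pools_cpp(f1$off, f1$en, f1$off, f1$en, params$gate,
                          params$gap_penalty, params$min_matched_lines,
                          TRUE, Inf)$scores
  s22 <- .score_pools_cpp(f2$off, f2$en, f2$off, f2$en, params$gate,
                          params$gap_penalty, params$min_matched_lines,
                          TRUE, Inf)$scores
  self_scores <- c(s11, s22)
  if (is.null(threshold)) threshold <- select_threshold(self_scores, q)
  cr <- .score_pools_cpp(f1$off, f1$en, f2$off, f2$en, params$gate,
                         params$gap_penalty, params$min_matched_lines,
                         FALSE, threshold)
  # detail rows are candidates with score >= detail threshold; accepted
  # matches require score strictly above it
  det <- data.frame(i = cr$i, j = cr$j, k_matched = cr$k,
                    mean_abs_dE = cr$mean_abs_de)
  det$score <- det$k_matched - det$k_matched * det$mean_abs_dE / params$gate -
    params$gap_penalty * (pool_multiplicities(c1)[det$i] +
                          pool_multiplicities(c2)[det$j] - 2 * det$k_matched)
  det <- det[det$score > threshold, , drop = FALSE]
  ord <- order(-det$score, det$mean_abs_dE, c1$cell_id[det$i],
               c2$cell_id[det$j])
  det <- det[ord, , drop = FALSE]
  used1 <- logical(length(c1)); used2 <- logical(length(c2))
  take <- logical(nrow(det))
  for (r in seq_len(nrow(det))) {
    i <- det$i[r]; j <- det$j[r]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE; take[r] <- TRUE
    }
  }
  acc <- det[take, , drop = FALSE]
  matches <- data.frame(c1_id = c1$cell_id[acc$i], c2_id = c2$cell_id[acc$j],
                        score = acc$score, k_matched = acc$k_matched,
                        mean_abs_dE = acc$mean_abs_dE,
                        stringsAsFactors = FALSE)
  m1 <- pool_multiplicities(c1)[acc$i]
  m2 <- pool_multiplicities(c2)[acc$j]
  confusion <- if (nrow(acc))
    table(m_run1 = factor(m1, levels = sort(unique(c(m1, m2)))),
          m_run2 = factor(m2, levels = sort(unique(c(m1, m2)))))
  else table(m_run1 = integer(0), m_run2 = integer(0))
  structure(list(matches = matches, threshold = threshold, q = q,
                 n1 = length(c1), n2 = length(c2),
                 match_rate = nrow(matches) / min(length(c1), length(c2)),
                 confusion = confusion,
                 self_summary = summary_scores(self_scores),
                 cross_summary = summary_scores(cr$scores),
                 n_self = length(self_scores),
                 n_cross = length(cr$scores),
                 params = params),
            class = "lp_matchset")
}

summary_scores <- function(s) {
  s <- s[is.finite(s)]
  if (!length(s)) return(c(n = 0))
  c(n = length(s), min = min(s), median = stats::median(s),
    q99 = stats::quantile(s, 0.99, names = FALSE), max = max(s))
}

#' @export
print.lp_matchset <- function(x, ...) {
  cat("Cross-run barcode match set\n")
  cat(sprintf("  runs: %d vs %d cells; candidates: %d cross, %d self\n",
              x$n1, x$n2, x$n_cross, x$n_self))
  cat(sprintf("  threshold: %.3f (q = %g); accepted matches: %d (%.1f%% of smaller run)\n",
              x$threshold, x$q, nrow(x$matches), 100 * x$match_rate))
  invisible(x)
}

#' @export
summary.lp_matchset <- function(object, ...) {
  cat("Accepted one-to-one matches:", nrow(object$matches), "\n")
  cat(sprintf("  match rate: %.2f%%, threshold %.3f\n",
              100 * object$match_rate, object$threshold))
  if (nrow(object$matches)) {
    cat(sprintf("  mean |dE| of matched lines: %.4f meV\n",
                mean(object$matches$mean_abs_dE)))
    cat("  multiplicity confusion (run1 rows x run2 cols):\n")
    print(object$confusion)
  }
  invisible(object)
}

#' Fit the generalized-Gaussian noise model to repeated measurements
#'
#' Estimates the line-jitter model \eqn{\varphi(E') =
#' \frac{\beta}{2\alpha\Gamma(1/\beta)} e^{-(|E'|/\alpha)^\beta}} by maximum
#' likelihood from repeated measurements of the same LPs. Fluctuations are
#' the per-LP energies minus the per-LP mean, pooled across LPs; the scale
#' has the closed-form profile \eqn{\hat\alpha(\beta) = (\beta\,
#' \overline{|x|^\beta})^{1/\beta}} and the exponent is found by 1-D
#' optimization of the profile log-likelihood.
#'
#' @param repeats data.frame with columns \code{lp_id} and
#'   \code{energy_meV} (at least 2 repeats per LP, \eqn{\ge 30} total
#'   fluctuation samples), or a numeric matrix with one row per LP.
#' @param beta_range search interval for \eqn{\beta} (default
#'   \code{c(0.3, 8)}).
#' @return an object of class \code{"lp_noisefit"} with \code{alpha},
#'   \code{beta}, \code{n_lines}, \code{loglik}.
#' @export
fit_noise <- function(repeats, beta_range = c(0.3, 8)) {
  if (is.matrix(repeats)) {
    x <- as.vector(repeats - rowMeans(repeats))
    n_lp <- nrow(repeats)
  } else {
    if (!all(c("lp_id", "energy_meV") %in% names(repeats)))
      stop("'repeats' needs columns lp_id and energy_meV")
    reps <- table(repeats$lp_id)
    if (any(reps < 2)) stop("every LP needs at least 2 repeats")
    x <- repeats$energy_meV -
      stats::ave(repeats$energy_meV, repeats$lp_id)
    n_lp <- length(reps)
  }
  if (length(x) < 30) stop("need at least 30 fluctuation samples")
  if (all(x == 0)) stop("degenerate fit: all fluctuations are zero")
  ax <- abs(x)
  n <- length(x)
  profile <- function(beta) {
    alpha <- (beta * mean(ax^beta))^(1 / beta)
    n * (log(beta) - log(2) - log(alpha) - lgamma(1 / beta) - 1 / beta)
  }
  opt <- stats::optimize(profile, interval = beta_range, maximum = TRUE)
  beta <- opt$maximum
  alpha <- (beta * mean(ax^beta))^(1 / beta)
  structure(list(alpha = alpha, beta = beta, n_lines = n, n_lp = n_lp,
                 loglik = opt$objective),
            class = "lp_noisefit")
}

#' @export
print.lp_noisefit <- function(x, ...) {
  cat("Generalized-Gaussian noise fit\n")
  cat(sprintf("  alpha = %.4g meV, beta = %.3f  (%d fluctuation samples, %d LPs)\n",
              x$alpha, x$beta, x$n_lines, x$n_lp))
  cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.lp_noisefit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.lp_noisefit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n_lines, class = "logLik")
}

#' Convert a noise fit to a noise model
#' @param fit an \code{"lp_noisefit"}.
#' @return a \code{\link{noise_model}}.
#' @export
as_noise_model <- function(fit) {
  stopifnot(inherits(fit, "lp_noisefit"))
  noise_model("generalized-gaussian", alpha = fit$alpha, beta = fit$beta)
}
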