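# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation so every sub-simulation is independently
# reproducible from one root seed. Kept below 2^31 - 1.
split_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
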