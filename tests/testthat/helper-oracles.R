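# Independent oracles used across test files.

# Brute-force Chebyshev duplicate flags in plain R (rows of E sorted).
r_cheb_dup <- function(E, delta) {
  n <- nrow(E)
  dup <- logical(n)
  if (n < 2) return(dup)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(E[i, ] - E[j, ])) <= delta) {
        dup[i] <- TRUE; dup[j] <- TRUE
      }
    }
  }
  dup
}

# Exhaustive search over all monotone one-to-one assignments between two
# sorted lists: maximize matched pairs, then minimize summed |dE|.
exhaustive_align <- function(a, b, gate) {
  best_k <- 0
  best_s <- 0
  rec <- function(i, j, k, s) {
    if (k > best_k || (k == best_k && s < best_s)) {
      best_k <<- k; best_s <<- s
    }
    if (i > length(a) || j > length(b)) return(invisible())
    for (ii in i:length(a)) {
      for (jj in j:length(b)) {
        d <- abs(a[ii] - b[jj])
        if (d <= gate) rec(ii + 1, jj + 1, k + 1, s + d)
      }
    }
  }
  rec(1, 1, 0, 0)
  list(k = best_k, sum_abs_de = best_s)
}

# Small random pool with mixed multiplicities for oracle comparisons.
random_test_pool <- function(n, seed, delta_big = 30, m_max = 4) {
  set.seed(seed)
  energies <- lapply(seq_len(n), function(i)
    sort(runif(sample(m_max, 1), 900, 900 + delta_big)))
  barcode_pool(sprintf("c%04d", seq_len(n)), energies)
}

uniform_joint <- function(delta_big = 100, center = 950)
  joint_barcode_distribution(
    spectral_distribution("uniform", delta_big = delta_big, center = center))

gaussian_joint <- function(delta_big = 100, center = 950)
  joint_barcode_distribution(
    spectral_distribution("gaussian", delta_big = delta_big,
                          center = center))
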