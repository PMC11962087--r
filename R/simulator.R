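#' Barcode pool container
#'
#' A pool of per-cell optical barcodes: each barcode is the ascending-sorted
#' list of line energies (meV) measured for one cell. Internally stored as a
#' concatenated energy vector with per-cell offsets, so that large pools
#' stay flat and fast; an optional \code{plet_id} groups lines into physical
#' units (singlet LPs, dual-mode line pairs, or k-plets).
#'
#' @param cell_id character or integer vector of unique cell identifiers.
#' @param energies list of numeric vectors (one per cell), sorted on
#'   construction.
#' @param plet_id optional list matching \code{energies}: physical-unit id
#'   per line.
#' @param provenance free-form list (generating config, seed, version).
#' @return an object of class \code{"barcode_pool"}.
#' @export
barcode_pool <- function(cell_id, energies, plet_id = NULL,
                         provenance = list()) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("'cell_id' values must be unique")
  if (length(cell_id) != length(energies))
    stop("'cell_id' and 'energies' lengths differ")
  m <- lengths(energies)
  ord <- lapply(energies, order)
  en <- unlist(lapply(seq_along(energies),
                      function(i) energies[[i]][ord[[i]]]), use.names = FALSE)
  if (is.null(en)) en <- numeric(0)
  pl <- NULL
  if (!is.null(plet_id)) {
    if (!identical(lengths(plet_id), m)) stop("'plet_id' shape mismatch")
    pl <- unlist(lapply(seq_along(plet_id),
                        function(i) plet_id[[i]][ord[[i]]]), use.names = FALSE)
  }
  new_barcode_pool(cell_id, en, c(0L, cumsum(m)), pl, provenance)
}

# low-level constructor from flat representation (energies already sorted
# within cells, offsets 0-based of length n+1)
new_barcode_pool <- function(cell_id, energies, offsets, plet_id = NULL,
                             provenance = list()) {
  structure(list(cell_id = as.character(cell_id),
                 energies = as.numeric(energies),
                 offsets = as.integer(offsets),
                 plet_id = plet_id,
                 provenance = provenance),
            class = "barcode_pool")
}

#' @export
print.barcode_pool <- function(x, ...) {
  m <- pool_multiplicities(x)
  cat(sprintf("Barcode pool: %d cells, %d lines\n", length(x$cell_id),
              length(x$energies)))
  if (length(m)) {
    tb <- table(m)
    cat("  multiplicities:",
        paste(sprintf("m=%s:%d", names(tb), as.integer(tb)), collapse = " "),
        "\n")
    cat(sprintf("  energy range: [%.2f, %.2f] meV\n",
                min(x$energies), max(x$energies)))
  }
  invisible(x)
}

#' @export
length.barcode_pool <- function(x) length(x$cell_id)

#' Per-cell multiplicities of a pool
#' @param pool a \code{\link{barcode_pool}}.
#' @return integer vector of line counts per cell.
#' @export
pool_multiplicities <- function(pool) diff(pool$offsets)

#' Extract one barcode from a pool
#' @param pool a \code{\link{barcode_pool}}.
#' @param i cell position or cell id.
#' @return sorted numeric vector of line energies (meV).
#' @export
pool_barcode <- function(pool, i) {
  if (is.character(i)) i <- match(i, pool$cell_id)
  pool$energies[(pool$offsets[i] + 1):pool$offsets[i + 1]]
}

#' @export
as.data.frame.barcode_pool <- function(x, ...) {
  m <- pool_multiplicities(x)
  data.frame(cell_id = rep(x$cell_id, m),
             line_index = unlist(lapply(m, seq_len), use.names = FALSE),
             energy_meV = x$energies,
             plet_id = if (is.null(x$plet_id)) NA_integer_ else x$plet_id,
             stringsAsFactors = FALSE)
}

#' Draw a barcode pool from a joint distribution and tagging model
#'
#' Simulates \code{N} cells: per cell the LP count comes from the tagging
#' model (fixed \code{m} or Poisson \eqn{\lambda}; untagged \eqn{m=0} cells
#' are dropped and counted), and each LP is single-mode with probability
#' \eqn{1 - f_{dm}} (one line drawn from \eqn{g}) or dual-mode (two lines
#' separated by an FSR drawn from the spacing distribution). Lines are
#' sorted into the cell's barcode; each LP forms one physical unit in
#' \code{plet_id}. Fully reproducible from \code{seed}.
#'
#' @param joint a \code{\link{joint_barcode_distribution}}.
#' @param tagging a \code{\link{tagging_mixture}}.
#' @param N number of cells to tag (\eqn{\ge 1}).
#' @param seed integer seed.
#' @return a \code{\link{barcode_pool}}; attribute \code{"n_untagged"}
#'   carries the count of dropped \eqn{m=0} cells.
#' @export
sample_pool <- function(joint, tagging, N, seed) {
  stopifnot(inherits(joint, "joint_barcode_distribution"),
            inherits(tagging, "tagging_mixture"))
  stopifnot_scalar(N, "N", 1)
  with_seed(seed, {
    n_lp <- if (tagging$mode == "fixed") rep(tagging$m, N)
            else stats::rpois(N, tagging$lambda)
    keep <- n_lp > 0
    n_untagged <- sum(!keep)
    n_lp <- n_lp[keep]
    n <- length(n_lp)
    if (n == 0) {
      p <- new_barcode_pool(character(0), numeric(0), 0L, integer(0),
                            list(seed = seed))
      attr(p, "n_untagged") <- n_untagged
      attr(p, "status") <- "empty-pool"
      return(p)
    }
    total_lp <- sum(n_lp)
    lp_cell <- rep.int(seq_len(n), n_lp)
    base <- sample_lines(joint$base, total_lp)
    dual <- if (joint$f_dm > 0)
      stats::runif(total_lp) < joint$f_dm else rep(FALSE, total_lp)
    fsr <- stats::runif(sum(dual), joint$fsr[1], joint$fsr[2])
    energy <- c(base, base[dual] + fsr)
    cell <- c(lp_cell, lp_cell[dual])
    plet <- c(seq_len(total_lp), seq_len(total_lp)[dual])
    ord <- order(cell, energy)
    energy <- energy[ord]; cell <- cell[ord]; plet <- plet[ord]
    m <- tabulate(cell, nbins = n)
    ids <- sprintf("cell_%06d", seq_len(n))
    p <- new_barcode_pool(ids, energy, c(0L, cumsum(m)), plet,
                          list(seed = seed, N = N,
                               tagging = unclass(tagging),
                               f_dm = joint$f_dm))
    attr(p, "n_untagged") <- n_untagged
    p
  })
}

#' Apply measurement noise to a pool
#'
#' Perturbs every line independently with a draw from the noise model
#' \eqn{\varphi(E')} and re-sorts lines within each cell; the physical-unit
#' map is carried along.
#'
#' @param pool a \code{\link{barcode_pool}}.
#' @param noise a \code{\link{noise_model}}.
#' @param seed integer seed.
#' @return a noised \code{\link{barcode_pool}}.
#' @export
apply_noise <- function(pool, noise, seed) {
  stopifnot(inherits(pool, "barcode_pool"), inherits(noise, "noise_model"))
  with_seed(seed, {
    L <- length(pool$energies)
    en <- pool$energies + noise_sample(noise, L)
    m <- pool_multiplicities(pool)
    cell <- rep.int(seq_along(pool$cell_id), m)
    ord <- order(cell, en)
    new_barcode_pool(pool$cell_id, en[ord], pool$offsets,
                     if (is.null(pool$plet_id)) NULL else pool$plet_id[ord],
                     c(pool$provenance, list(noise = unclass(noise))))
  })
}

# group pool cells by multiplicity; returns list of (matrix, cell index)
split_by_multiplicity <- function(pool) {
  m <- pool_multiplicities(pool)
  out <- list()
  for (mm in sort(unique(m[m > 0]))) {
    idx <- which(m == mm)
    take <- unlist(lapply(idx, function(i)
      (pool$offsets[i] + 1):pool$offsets[i + 1]), use.names = FALSE)
    E <- matrix(pool$energies[take], nrow = length(idx), ncol = mm,
                byrow = TRUE)
    out[[as.character(mm)]] <- list(E = E, idx = idx)
  }
  out
}

#' Empirical duplicate counting under the Chebyshev metric
#'
#' Within each multiplicity class, a barcode is a duplicate iff at least one
#' other barcode of the same class lies within Chebyshev distance
#' \eqn{\le \delta} of it (on the sorted energy vectors). Two execution
#' paths are provided: an exact indexed search (sliding window on the first
#' sorted coordinate) and a brute-force \eqn{O(n^2)} oracle; they agree
#' exactly on every pool.
#'
#' @param pool a \code{\link{barcode_pool}}.
#' @param delta matching half-gap in meV (> 0).
#' @param method \code{"window"} (indexed, default) or \code{"brute"}.
#' @return list with \code{per_m} (data.frame: m, n, n_dup, frac_dup),
#'   pooled \code{frac_dup}, and \code{is_dup} (logical per cell, pool
#'   order).
#' @export
count_duplicates <- function(pool, delta, method = c("window", "brute")) {
  method <- match.arg(method)
  stopifnot_scalar(delta, "delta", 0, strict_lower = TRUE)
  groups <- split_by_multiplicity(pool)
  is_dup <- logical(length(pool$cell_id))
  per_m <- data.frame(m = integer(0), n = integer(0), n_dup = integer(0),
                      frac_dup = numeric(0))
  for (g in groups) {
    flags <- if (method == "window") .cheb_dup_window(g$E, delta)
             else .cheb_dup_brute(g$E, delta)
    is_dup[g$idx] <- flags
    per_m <- rbind(per_m, data.frame(m = ncol(g$E), n = nrow(g$E),
                                     n_dup = sum(flags),
                                     frac_dup = mean(flags)))
  }
  n_tot <- sum(per_m$n)
  list(per_m = per_m,
       frac_dup = if (n_tot > 0) sum(per_m$n_dup) / n_tot else 0,
       is_dup = is_dup)
}

#' Division-simulation configuration
#'
#' @param plet_size lines per physical unit \code{k} (1 = singlet LPs).
#' @param lambda mean LP lines per cell at tagging; mean plets per cell is
#'   \code{lambda / plet_size}.
#' @param generations number of division rounds to simulate.
#' @param eps0 identification noise budget used to set the per-generation
#'   gate.
#' @param seed integer seed.
#' @param inheritance \code{"bernoulli"} (each plet goes to either daughter
#'   with probability 1/2, default) or \code{"symmetric"} (plets split as
#'   evenly as possible, remainder randomized).
#' @return an object of class \code{"division_config"}.
#' @export
division_config <- function(plet_size = 1, lambda, generations, eps0 = 0.01,
                            seed, inheritance = c("bernoulli", "symmetric")) {
  stopifnot_scalar(plet_size, "plet_size", 1)
  stopifnot_scalar(lambda, "lambda", 0, strict_lower = TRUE)
  stopifnot_scalar(generations, "generations", 0)
  stopifnot_scalar(eps0, "eps0", 0, strict_lower = TRUE)
  structure(list(plet_size = as.integer(plet_size), lambda = lambda,
                 generations = as.integer(generations), eps0 = eps0,
                 seed = seed, inheritance = match.arg(inheritance)),
            class = "division_config")
}

#' Multiplet inheritance across cell divisions
#'
#' Simulates the dilution of optical barcodes over successive cell
#' divisions. Cells are tagged with Poisson\eqn{(\lambda/k)} k-plets (k
#' lines each, energies drawn from the line distribution and immutable
#' thereafter). At each division every plet is independently inherited by
#' one of the two daughters. Per generation, the matching gate \eqn{\delta}
#' is set so that the multiplicity-weighted noise error equals \code{eps0},
#' and a cell counts as identifiable iff it carries at least one line and
#' has no same-multiplicity Chebyshev neighbor within \eqn{\delta}.
#'
#' @param joint a \code{\link{joint_barcode_distribution}} (dual-mode lines
#'   are not used here: only the base line distribution is sampled).
#' @param config a \code{\link{division_config}}.
#' @param noise a \code{\link{noise_model}} (enters through the gate rule).
#' @param N initial number of cells.
#' @return data.frame with one row per generation: \code{generation},
#'   \code{n_cells}, \code{n_tagged}, \code{n_identifiable},
#'   \code{n_lines} (conserved total), \code{delta_meV}.
#' @export
simulate_divisions <- function(joint, config, noise, N) {
  stopifnot(inherits(config, "division_config"))
  stopifnot_scalar(N, "N", 1)
  k <- config$plet_size
  with_seed(config$seed, {
    n_plets_per_cell <- stats::rpois(N, config$lambda / k)
    n_plets <- sum(n_plets_per_cell)
    plet_cell <- rep.int(seq_len(N), n_plets_per_cell)
    plet_lines <- matrix(sample_lines(joint$base, n_plets * k), n_plets, k)
    out <- vector("list", config$generations + 1)
    for (g in 0:config$generations) {
      if (g > 0) {
        b <- if (config$inheritance == "bernoulli") {
          stats::rbinom(n_plets, 1, 0.5)
        } else {
          # as-even-as-possible split per cell, remainder randomized
          unlist(lapply(split(seq_len(n_plets), plet_cell), function(ix) {
            nn <- length(ix)
            sample(rep_len(c(0L, 1L), nn))
          }), use.names = FALSE)[order(order(plet_cell))]
        }
        plet_cell <- 2L * plet_cell - 1L + b
      }
      n_cells <- N * 2^g
      res <- .division_census(plet_cell, plet_lines, noise, config$eps0)
      out[[g + 1]] <- data.frame(generation = g, n_cells = n_cells,
                                 n_tagged = res$n_tagged,
                                 n_identifiable = res$n_identifiable,
                                 n_lines = res$n_lines,
                                 delta_meV = res$delta)
    }
    do.call(rbind, out)
  })
}

# Count identifiable cells for one generation of a division simulation.
.division_census <- function(plet_cell, plet_lines, noise, eps0) {
  k <- ncol(plet_lines)
  n_plets <- nrow(plet_lines)
  line_cell <- rep(plet_cell, k)
  line_en <- as.vector(plet_lines)
  cells <- sort(unique(plet_cell))
  ci <- match(line_cell, cells)
  ord <- order(ci, line_en)
  ci <- ci[ord]; line_en <- line_en[ord]
  m <- tabulate(ci, nbins = length(cells))
  pool <- new_barcode_pool(as.character(cells), line_en, c(0L, cumsum(m)))
  # gate: multiplicity-weighted noise error == eps0
  tb <- table(m)
  mm <- as.integer(names(tb)); w <- as.integer(tb) / length(cells)
  wnoise <- function(d) sum(w * (1 - noise_interval_prob(noise, d)^mm))
  delta <- if (noise_sd(noise) == 0) 1e-9
           else stats::uniroot(function(d) wnoise(d) - eps0,
                               c(1e-9, 1e4), tol = 1e-10)$root
  dup <- count_duplicates(pool, delta)
  list(n_tagged = length(cells),
       n_identifiable = sum(!dup$is_dup),
       n_lines = length(line_en),
       delta = delta)
}
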