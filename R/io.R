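#' Read a barcode table CSV into a pool
#'
#' Long-format CSV with required columns \code{cell_id}, \code{line_index},
#' \code{energy_meV} and optional \code{plet_id}. Energies are re-sorted
#' within each cell on read. Malformed rows (non-numeric energies) raise an
#' error naming the offending row numbers.
#'
#' @param path CSV path.
#' @return a \code{\link{barcode_pool}}.
#' @export
read_barcode_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cell_id", "line_index", "energy_meV")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  en <- suppressWarnings(as.numeric(df$energy_meV))
  bad <- which(!is.finite(en))
  if (length(bad))
    stop("non-numeric energy_meV in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  cell <- df$cell_id
  ids <- unique(cell)
  ci <- match(cell, ids)
  pl <- if ("plet_id" %in% names(df))
    suppressWarnings(as.integer(df$plet_id)) else NULL
  ord <- order(ci, en)
  m <- tabulate(ci, nbins = length(ids))
  new_barcode_pool(ids, en[ord], c(0L, cumsum(m)),
                   if (is.null(pl)) NULL else pl[ord],
                   provenance = list(source = path))
}

#' Write a pool as a barcode table CSV
#'
#' Numbers are serialized with 17 significant digits so that
#' write-then-read round-trips to full double precision.
#'
#' @param pool a \code{\link{barcode_pool}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_barcode_table <- function(pool, path) {
  df <- as.data.frame(pool)
  df$energy_meV <- vapply(df$energy_meV, fmt_num, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format spectra CSV
#'
#' Columns: \code{origin_id}, optional \code{x}, \code{y}, then
#' \code{energy_meV}, \code{intensity}; one row per grid point.
#'
#' @param path CSV path.
#' @return data.frame split-ready by \code{origin_id} (and pixel).
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("origin_id", "energy_meV", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' Read a planning configuration JSON
#'
#' Schema: \code{distribution} (\code{kind} plus \code{delta_meV} /
#' \code{sigma_meV} / \code{components}), \code{noise} (\code{family} plus
#' \code{sigma_phi_meV} or \code{alpha_meV}, \code{beta}), \code{tagging}
#' (\code{mode} plus \code{m} or \code{lambda}), \code{N}, \code{eps0},
#' optional \code{mc} (\code{n_samples}, \code{seed}). Unknown keys are
#' rejected with a message listing them.
#'
#' @param path JSON path.
#' @return list with constructed \code{joint}, \code{noise},
#'   \code{tagging}, and scalars \code{N}, \code{eps0}, \code{n_mc},
#'   \code{seed}.
#' @export
read_plan_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("distribution", "noise", "tagging", "N", "eps0", "mc")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  miss <- setdiff(c("distribution", "noise", "N", "eps0"), names(cfg))
  if (length(miss))
    stop("missing config keys: ", paste(miss, collapse = ", "))
  d <- cfg$distribution
  dist <- switch(d$kind,
    uniform = spectral_distribution("uniform", delta_big = d$delta_meV,
                                    center = d$center_meV %||% 950),
    gaussian = spectral_distribution("gaussian",
                                     sigma = d$sigma_meV %||%
                                       (d$delta_meV / sqrt(12)),
                                     center = d$center_meV %||% 950),
    `gaussian-mixture` = spectral_distribution("gaussian-mixture",
                                               components = d$components),
    stop("unknown distribution kind: ", d$kind))
  joint <- joint_barcode_distribution(dist, f_dm = d$f_dm %||% 0,
                                      fsr = d$fsr %||% c(50, 70))
  nz <- cfg$noise
  noise <- if (identical(nz$family, "gaussian"))
    noise_model("gaussian", sigma_phi = nz$sigma_phi_meV)
  else
    noise_model("generalized-gaussian", alpha = nz$alpha_meV,
                beta = nz$beta)
  tagging <- if (is.null(cfg$tagging)) NULL
  else if (identical(cfg$tagging$mode, "fixed"))
    tagging_mixture("fixed", m = cfg$tagging$m)
  else tagging_mixture("poisson", lambda = cfg$tagging$lambda)
  list(joint = joint, noise = noise, tagging = tagging,
       N = cfg$N, eps0 = cfg$eps0,
       n_mc = cfg$mc$n_samples %||% 1e5, seed = cfg$mc$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an error report to JSON
#'
#' @param report an \code{\link{lp_plan}} result (or any named list of
#'   numbers).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_error_report <- function(report, path) {
  jsonlite::write_json(unclass_shallow(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_shallow <- function(x) {
  x <- unclass(x)
  x[!vapply(x, is.function, logical(1))]
}

# provenance sidecar written next to CLI outputs
write_provenance <- function(path, config, seed) {
  jsonlite::write_json(list(config = config, seed = seed,
                            package = "lpbarcode",
                            version = as.character(
                              utils::packageVersion("lpbarcode"))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}
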