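#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Midpoints of panel loci in bp
#' @keywords internal
#' @noRd
locus_midpoints <- function(panel) {
  (panel$start + panel$end) / 2
}

#' Log-spaced genomic-distance bin index
#'
#' Bins positive genomic distances into log10-spaced bins
#' (`bins_per_decade` per decade, default 20), the binning used for
#' observed/expected normalization and genomic-distance-controlled medians.
#'
#' @param gdist numeric vector of genomic distances in bp (> 0)
#' @param bins_per_decade number of bins per decade
#' @return integer bin index (1-based)
#' @export
genomic_distance_bin <- function(gdist, bins_per_decade = 20) {
  stopifnot(all(gdist > 0, na.rm = TRUE))
  as.integer(floor(log10(gdist) * bins_per_decade)) + 1L
}

#' Equal-count bins
#'
#' Splits values into `n_bins` bins with counts differing by at most 1,
#' ordered by value (ties broken by original order for determinism).
#'
#' @param x numeric vector (no NAs)
#' @param n_bins number of bins
#' @return integer bin index in 1..n_bins, same length as `x`
#' @export
equal_count_bins <- function(x, n_bins) {
  stopifnot(n_bins >= 1, !anyNA(x))
  n <- length(x)
  if (n < n_bins) stop("fewer values (", n, ") than bins (", n_bins, ")")
  ord <- order(x)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Derive a per-unit RNG seed from a master seed and a counter
#'
#' Counter-based scheme so that each simulated cell gets an independent,
#' reproducible stream regardless of generation order. Stays below 2^31.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, counter) {
  # splitmix-style integer hash, folded to a positive 31-bit value
  h <- (as.numeric(seed) * 2654435761 + as.numeric(counter) * 40503 + 12345) %%
    2147483647
  as.integer(h) + 1L
}

#' Simple leveled logging
#'
#' Writes a timestamped message to stderr when the package verbosity
#' (option `chromtrace.verbose`, default "info") admits the level.
#'
#' @param ... message parts, pasted together
#' @param level one of "debug", "info", "warn"
#' @export
ct_log <- function(..., level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  opt <- getOption("chromtrace.verbose", "info")
  if (levels[[level]] >= levels[[opt]]) {
    message(sprintf("[%s] %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), paste0(...)))
  }
  invisible(NULL)
}
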