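#' Canonical frequency bands
#'
#' The seven canonical bands used throughout the pipeline: delta (1-3 Hz),
#' theta (4-7 Hz), alpha (8-14 Hz), beta (15-30 Hz), low gamma1 (30-55 Hz),
#' low gamma2 (65-80 Hz) and high gamma (80-150 Hz).
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` (Hz), ordered by
#'   `f_lo`.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "lgamma1", "lgamma2", "hgamma"),
    f_lo = c(1, 4, 8, 15, 30, 65, 80),
    f_hi = c(3, 7, 14, 30, 55, 80, 150),
    stringsAsFactors = FALSE
  )
}

#' Frequency limits of a canonical band
#'
#' @param band Band name, one of [canonical_bands()]`$band`.
#' @return Numeric length-2 vector `c(f_lo, f_hi)` in Hz.
#' @export
band_limits <- function(band) {
  tab <- canonical_bands()
  i <- match(band, tab$band)
  if (is.na(i)) {
    stop("unknown band '", band, "'; canonical bands are: ",
         paste(tab$band, collapse = ", "), call. = FALSE)
  }
  c(tab$f_lo[i], tab$f_hi[i])
}

assert_bands <- function(bands) {
  ok <- bands %in% canonical_bands()$band
  if (!all(ok)) {
    stop("unknown band(s): ", paste(bands[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(bands)
}
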