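# Regional power spectral density: Welch per epoch, averaged over epochs,
# binned into canonical bands, lobe-averaged spectra and peak alpha.

#' Welch power spectral density of epoched virtual sensors
#'
#' Per epoch, the mean of windowed periodograms (Hann window, one-sided
#' density scaling); the final PSD is the average over all retained epochs.
#' Defaults (2 s windows, 50% overlap) give 0.5 Hz resolution — enough to
#' resolve the 1-3 Hz delta band — while averaging 9 windows per 10 s epoch.
#'
#' @param se A `source_epochs` object.
#' @param window_length Window length in seconds (default 2); must not
#'   exceed the epoch length.
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return Object of class `psd_result`: list with `psd`
#'   (`seeds x frequencies`, a.u.^2/Hz), `freq` (Hz), `labels`.
#' @export
welch_psd <- function(se, window_length = 2, overlap = 0.5) {
  stopifnot(inherits(se, "source_epochs"), n_epochs(se) >= 1)
  fs <- se$sampling_rate
  nw <- round(window_length * fs)
  spe <- dim(se$data)[2]
  if (nw > spe) stop("window longer than epoch", call. = FALSE)
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, spe - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / nw)
  scale <- 1 / (fs * sum(w^2))
  nf <- nw %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / nw
  ns <- n_seeds_of(se)
  acc <- matrix(0, ns, nf)
  for (e in seq_len(n_epochs(se))) {
    Xe <- matrix(se$data[, , e], ns)
    segs <- matrix(0, nw, length(starts) * ns)
    for (s in seq_along(starts)) {
      idx <- starts[s] + seq_len(nw) - 1
      segs[, (s - 1) * ns + seq_len(ns)] <- t(Xe[, idx, drop = FALSE]) * w
    }
    P <- Mod(mvfft(segs))^2 * scale
    P <- P[seq_len(nf), , drop = FALSE]
    if (nw %% 2 == 0) {
      P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
    } else {
      P[2:nf, ] <- 2 * P[2:nf, ]
    }
    # mean over windows for this epoch
    pe <- matrix(0, ns, nf)
    for (s in seq_along(starts)) {
      pe <- pe + t(P[, (s - 1) * ns + seq_len(ns), drop = FALSE])
    }
    acc <- acc + pe / length(starts)
  }
  structure(list(psd = acc / n_epochs(se), freq = freq, labels = se$labels),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat("<psd_result>", nrow(x$psd), "seeds x", length(x$freq),
      "frequency bins (", x$freq[1], "-", max(x$freq), "Hz )\n")
  invisible(x)
}

#' Bin a PSD into canonical frequency bands
#'
#' Per band, the mean density over frequency bins whose centre lies in
#' `[f_lo, f_hi]` (mean, not integral: comparable across bands of unequal
#' width).
#'
#' @param psd A `psd_result`.
#' @param bands Character vector of canonical band names, or a data.frame
#'   with columns `band`, `f_lo`, `f_hi`.
#' @return `seeds x bands` matrix of mean in-band density.
#' @export
bin_bands <- function(psd, bands = canonical_bands()) {
  stopifnot(inherits(psd, "psd_result"))
  if (is.character(bands)) {
    assert_bands(bands)
    tab <- canonical_bands()
    bands <- tab[match(bands, tab$band), ]
  }
  out <- matrix(NA_real_, nrow(psd$psd), nrow(bands),
                dimnames = list(psd$labels, bands$band))
  for (i in seq_len(nrow(bands))) {
    sel <- psd$freq >= bands$f_lo[i] & psd$freq <= bands$f_hi[i]
    if (!any(sel)) {
      stop("band '", bands$band[i], "' contains no frequency bins",
           call. = FALSE)
    }
    out[, i] <- rowMeans(psd$psd[, sel, drop = FALSE])
  }
  out
}

#' Lobe-averaged power spectra
#'
#' Unweighted mean PSD over the member seeds of each lobe x hemisphere cell;
#' empty cells are dropped with a warning.
#'
#' @param psd A `psd_result` whose seeds match `source_model` rows.
#' @param source_model A `source_model` (provides lobe and hemisphere).
#' @return Matrix `(lobe_hemisphere) x frequencies` with attribute `freq`.
#' @export
lobe_psd <- function(psd, source_model) {
  stopifnot(inherits(psd, "psd_result"),
            nrow(psd$psd) == nrow(source_model))
  cells <- unique(source_model[, c("lobe", "hemisphere")])
  cells <- cells[order(cells$lobe, cells$hemisphere), ]
  out <- matrix(NA_real_, nrow(cells), length(psd$freq),
                dimnames = list(paste(cells$lobe, cells$hemisphere, sep = "_"),
                                NULL))
  keep <- rep(TRUE, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- source_model$lobe == cells$lobe[i] &
      source_model$hemisphere == cells$hemisphere[i]
    if (!any(sel)) {
      warning("empty lobe cell ", rownames(out)[i], "; excluded")
      keep[i] <- FALSE
      next
    }
    out[i, ] <- colMeans(psd$psd[sel, , drop = FALSE])
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "freq") <- psd$freq
  out
}

#' Peak alpha frequency and power
#'
#' Maximum spectral density, and its frequency, within the alpha band
#' (8-14 Hz) of one spectrum. A monotone spectrum returns the band boundary.
#'
#' @param spectrum Numeric vector of densities.
#' @param freq Frequency grid (Hz) of `spectrum`; defaults to
#'   `attr(spectrum, "freq")`.
#' @return Named numeric `c(peak_frequency =, peak_power =)`.
#' @export
peak_alpha <- function(spectrum, freq = NULL) {
  if (is.null(freq)) freq <- attr(spectrum, "freq")
  stopifnot(!is.null(freq), length(freq) == length(spectrum))
  lim <- band_limits("alpha")
  sel <- which(freq >= lim[1] & freq <= lim[2])
  if (!length(sel)) stop("alpha band not covered by the grid", call. = FALSE)
  i <- sel[which.max(spectrum[sel])]
  c(peak_frequency = freq[i], peak_power = spectrum[i])
}
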