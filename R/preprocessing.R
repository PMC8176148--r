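# Cleaning and epoching of continuous recordings: zero-phase Butterworth
# band-pass, FFT notch, ICA artifact attenuation, 10 s epoching, and
# motion/jump epoch rejection.

as_data_matrix <- function(x) if (inherits(x, "sensor_recording")) x$data else x

put_data <- function(x, m) {
  if (inherits(x, "sensor_recording")) { x$data <- m; x } else m
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth design applied forward and backward (zero phase;
#' the effective magnitude response is squared).
#'
#' @param x A `sensor_recording` or `channels x samples` matrix.
#' @param f_lo,f_hi Band edges, Hz (defaults 1 and 150).
#' @param order Filter order (default 4).
#' @param sampling_rate Hz; taken from the recording when omitted.
#' @return Filtered object of the same type/shape.
#' @export
bandpass_butterworth <- function(x, f_lo = 1, f_hi = 150, order = 4,
                                 sampling_rate = NULL) {
  if (inherits(x, "sensor_recording")) sampling_rate <- x$sampling_rate
  stopifnot(!is.null(sampling_rate))
  nyq <- sampling_rate / 2
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq)) {
    stop("need 0 < f_lo < f_hi < Nyquist (", nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, "pass")
  m <- as_data_matrix(x)
  for (i in seq_len(nrow(m))) m[i, ] <- signal::filtfilt(bf, m[i, ])
  put_data(x, m)
}

#' Fourier-transform notch filter
#'
#' Suppresses narrow bands around the given line frequencies by zeroing FFT
#' bins within `+/- width` Hz (both spectral half-axes), then inverse
#' transforming. Literal frequency-domain notching: > 30 dB suppression at
#' the notch, < 1 dB at +/- 5 Hz.
#'
#' @param x A `sensor_recording` or `channels x samples` matrix.
#' @param freqs Notch frequencies, Hz (default 60 and 120).
#' @param width Half-width of each notch, Hz (default 1).
#' @param sampling_rate Hz; taken from the recording when omitted.
#' @return Filtered object of the same type/shape.
#' @export
notch_filter <- function(x, freqs = c(60, 120), width = 1,
                         sampling_rate = NULL) {
  if (inherits(x, "sensor_recording")) sampling_rate <- x$sampling_rate
  stopifnot(!is.null(sampling_rate))
  if (any(freqs >= sampling_rate / 2)) {
    stop("notch frequencies must be below Nyquist", call. = FALSE)
  }
  m <- as_data_matrix(x)
  n <- ncol(m)
  fgrid <- (seq_len(n) - 1) * sampling_rate / n
  fgrid <- pmin(fgrid, sampling_rate - fgrid)  # distance to 0 on the circle
  kill <- rep(FALSE, n)
  for (f in freqs) kill <- kill | abs(fgrid - f) <= width
  Ft <- mvfft(t(m))
  Ft[kill, ] <- 0
  put_data(x, t(Re(mvfft(Ft, inverse = TRUE)) / n))
}

# FastICA: symmetric fixed-point with tanh nonlinearity on a PCA-reduced,
# whitened subspace. Directions without independent non-Gaussian structure
# (e.g. a Gaussian background subspace) have no ICA contrast and can rotate
# freely between iterations, so — as is standard for this algorithm — the
# decomposition after max_iter is used even when the strict tolerance was
# not met (`converged` records which); NULL is returned only on numerical
# failure.
fast_ica <- function(m, n_components = 30, max_iter = 200, tol = 1e-4,
                     seed = 1) {
  set.seed(seed)
  nchan <- nrow(m)
  ns <- ncol(m)
  if (ns <= nchan) stop("need more samples than channels for ICA",
                        call. = FALSE)
  mu <- rowMeans(m)
  Xc <- m - mu
  ev <- eigen(tcrossprod(Xc) / ns, symmetric = TRUE)
  ncomp <- min(n_components, sum(ev$values > 1e-12 * ev$values[1]))
  K <- t(ev$vectors[, seq_len(ncomp), drop = FALSE]) /
    sqrt(ev$values[seq_len(ncomp)])
  Z <- K %*% Xc                       # whitened, ncomp x samples
  W <- qr.Q(qr(matrix(rnorm(ncomp^2), ncomp)))
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wnew <- G %*% t(Z) / ns - rowMeans(1 - G^2) * W
    Wnew <- sym_decor(Wnew)
    delta <- max(abs(1 - abs(rowSums(Wnew * W))))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z
  if (!all(is.finite(S))) return(NULL)
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  list(S = S, A = A, mean = mu, converged = converged)
}

#' ICA-based artifact attenuation
#'
#' Decomposes the continuous data into independent components (FastICA on a
#' PCA-reduced subspace) and zeroes, before back-projection, every component
#' whose time course correlates with any supplied artifact template above
#' the threshold. Template matching replaces manual component inspection so
#' the step is deterministic and testable.
#'
#' @param x A `sensor_recording` or `channels x samples` matrix.
#' @param artifact_templates List (or matrix rows) of artifact time courses,
#'   same length as the recording; NULL/empty returns the input unchanged.
#' @param threshold Absolute Pearson correlation above which a component is
#'   removed (default 0.5).
#' @param n_components Number of ICA components (default 30).
#' @param seed RNG seed for the ICA initialization.
#' @return The cleaned object; attribute `"ica_report"` is a data.frame of
#'   component-template correlations with a `removed` flag, plus a `status`
#'   attribute (`"ok"`, `"no_templates"` or `"not_converged"`, the latter
#'   passing the recording through unmodified with a warning).
#' @export
ica_attenuate <- function(x, artifact_templates = NULL, threshold = 0.5,
                          n_components = 30, seed = 1) {
  m <- as_data_matrix(x)
  if (is.null(artifact_templates) || length(artifact_templates) == 0) {
    out <- put_data(x, m)
    attr(out, "ica_report") <- data.frame()
    attr(out, "ica_status") <- "no_templates"
    return(out)
  }
  if (is.matrix(artifact_templates)) {
    artifact_templates <- split(artifact_templates, row(artifact_templates))
  }
  stopifnot(all(vapply(artifact_templates, length, 1L) == ncol(m)))
  fit <- fast_ica(m, n_components = n_components, seed = seed)
  if (is.null(fit)) {
    warning("ICA did not converge; recording passed through unmodified")
    out <- put_data(x, m)
    attr(out, "ica_report") <- data.frame()
    attr(out, "ica_status") <- "not_converged"
    return(out)
  }
  ncomp <- nrow(fit$S)
  rep_rows <- list()
  removed <- logical(ncomp)
  for (ti in seq_along(artifact_templates)) {
    r <- as.numeric(cor(t(fit$S), artifact_templates[[ti]]))
    hit <- abs(r) > threshold
    removed <- removed | hit
    rep_rows[[ti]] <- data.frame(template = ti, component = seq_len(ncomp),
                                 correlation = r, removed = hit)
  }
  if (any(removed)) {
    m <- m - fit$A[, removed, drop = FALSE] %*%
      fit$S[removed, , drop = FALSE]
  }
  out <- put_data(x, m)
  attr(out, "ica_report") <- do.call(rbind, rep_rows)
  attr(out, "ica_status") <- "ok"
  out
}

#' Epoch a continuous sensor recording
#'
#' Non-overlapping `epoch_length` segments; the trailing partial segment is
#' dropped. The head-position trace is carried along per epoch.
#'
#' @param recording A `sensor_recording`.
#' @param epoch_length Seconds (default 10).
#' @return Object of class `epoched_recording`: `data`
#'   (`channels x samples x epochs`), `head_position`
#'   (`samples x 3 x epochs`, mm), `sampling_rate`, `epoch_length`,
#'   `subject_id`, and a `flags` data.frame (filled by [reject_epochs()]).
#' @export
epoch_recording <- function(recording, epoch_length = 10) {
  stopifnot(inherits(recording, "sensor_recording"))
  fs <- recording$sampling_rate
  spe <- round(epoch_length * fs)
  ne <- floor(ncol(recording$data) / spe)
  if (ne == 0) warning("recording shorter than one epoch; 0 epochs")
  nchan <- nrow(recording$data)
  keep <- seq_len(ne * spe)
  structure(list(
    data = array(recording$data[, keep], c(nchan, spe, ne)),
    head_position = array(t(recording$head_position[keep, , drop = FALSE]),
                          c(3, spe, ne)),
    sampling_rate = fs, epoch_length = epoch_length,
    subject_id = recording$subject_id,
    median_position = apply(recording$head_position, 2, median),
    flags = data.frame(epoch = seq_len(ne),
                       max_displacement = rep(NA_real_, ne),
                       max_jump = rep(NA_real_, ne),
                       reason = rep("none", ne),
                       stringsAsFactors = FALSE)
  ), class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  nrej <- sum(x$flags$reason != "none")
  cat("<epoched_recording>", x$subject_id, ":", d[1], "channels x", d[2],
      "samples x", d[3], "epochs;", nrej, "rejected\n")
  invisible(x)
}

#' Flag epochs contaminated by head motion or signal jumps
#'
#' An epoch is rejected when (a) any within-epoch head displacement from the
#' whole-recording median position exceeds `motion_threshold`, or (b) any
#' channel's absolute sample-to-sample difference exceeds `jump_threshold`.
#' Motion takes precedence in the reason code when both apply. The
#' per-subject head-motion covariate is the mean of the per-epoch maximum
#' displacement over retained epochs.
#'
#' @param ep An `epoched_recording`.
#' @param motion_threshold mm (default 10).
#' @param jump_threshold fT (default 2000).
#' @return The `epoched_recording` with `flags` filled and attribute
#'   `head_motion` (mm).
#' @export
reject_epochs <- function(ep, motion_threshold = 10, jump_threshold = 2000) {
  stopifnot(inherits(ep, "epoched_recording"))
  ne <- dim(ep$data)[3]
  for (e in seq_len(ne)) {
    hp <- matrix(ep$head_position[, , e], 3)
    disp <- sqrt(colSums((hp - ep$median_position)^2))
    mx <- max(disp)
    dj <- max(abs(ep$data[, -1, e, drop = FALSE] -
                    ep$data[, -dim(ep$data)[2], e, drop = FALSE]))
    ep$flags$max_displacement[e] <- mx
    ep$flags$max_jump[e] <- dj
    ep$flags$reason[e] <- if (mx > motion_threshold) "motion"
      else if (dj > jump_threshold) "jump" else "none"
  }
  retained <- ep$flags$reason == "none"
  attr(ep, "head_motion") <-
    if (any(retained)) mean(ep$flags$max_displacement[retained]) else NA_real_
  ep
}

#' Retained epochs as a source_epochs-style array object
#'
#' @param ep An `epoched_recording` after [reject_epochs()].
#' @return A `source_epochs` object holding the retained sensor epochs
#'   (channels in the seed slot).
#' @export
retained_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoched_recording"))
  keep <- ep$flags$reason == "none"
  source_epochs(ep$data[, , keep, drop = FALSE], ep$sampling_rate,
                paste0("ch_", seq_len(dim(ep$data)[1])))
}

#' Full cleaning pipeline for one continuous recording
#'
#' Band-pass, notch, optional ICA attenuation, epoching and rejection in the
#' fixed order of the preprocessing stage.
#'
#' @param recording A `sensor_recording`.
#' @param config List of thresholds; see [preproc_config()].
#' @param artifact_templates Passed to [ica_attenuate()].
#' @return An `epoched_recording` (with flags, `head_motion` attribute and
#'   ICA report attribute).
#' @export
preprocess_recording <- function(recording, config = preproc_config(),
                                 artifact_templates = NULL) {
  rec <- bandpass_butterworth(recording, config$bandpass[1],
                              config$bandpass[2], config$filter_order)
  rec <- notch_filter(rec, config$notch)
  rec <- ica_attenuate(rec, artifact_templates,
                       threshold = config$ica_correlation_threshold)
  report <- attr(rec, "ica_report")
  ep <- epoch_recording(rec, config$epoch_length)
  ep <- reject_epochs(ep, config$motion_threshold, config$jump_threshold)
  attr(ep, "ica_report") <- report
  ep
}

#' Preprocessing configuration
#'
#' @param bandpass Band edges, Hz.
#' @param filter_order Butterworth order.
#' @param notch Notch frequencies, Hz.
#' @param epoch_length Seconds.
#' @param motion_threshold mm.
#' @param jump_threshold fT.
#' @param ica_correlation_threshold Component-template |r| threshold.
#' @return A named list.
#' @export
preproc_config <- function(bandpass = c(1, 150), filter_order = 4,
                           notch = c(60, 120), epoch_length = 10,
                           motion_threshold = 10, jump_threshold = 2000,
                           ica_correlation_threshold = 0.5) {
  list(bandpass = bandpass, filter_order = filter_order, notch = notch,
       epoch_length = epoch_length, motion_threshold = motion_threshold,
       jump_threshold = jump_threshold,
       ica_correlation_threshold = ica_correlation_threshold)
}
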