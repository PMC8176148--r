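# Band-specific, leakage-corrected amplitude-envelope-correlation (AEC)
# connectomes. Fixed pipeline order per epoch:
#   band-pass FIR -> symmetric orthogonalization -> Hilbert envelope ->
#   1 Hz block-mean downsampling -> Pearson correlation -> average epochs.

# windowed-sinc FIR band-pass kernel for zero-phase two-pass application:
# returns the combined (forward-backward) kernel b * rev(b) and its delay
fir_twopass_kernel <- function(band, sampling_rate) {
  lim <- if (is.character(band)) band_limits(band) else band
  if (lim[2] >= sampling_rate / 2) {
    stop("band upper edge ", lim[2], " Hz is not below Nyquist (",
         sampling_rate / 2, " Hz)", call. = FALSE)
  }
  # >= 3 cycles of the lowest band frequency in the impulse response
  ord <- max(2 * ceiling(3 * sampling_rate / lim[1] / 2), 66)
  b <- signal::fir1(ord, lim / (sampling_rate / 2), type = "pass")
  list(kernel = stats::convolve(b, rev(b), type = "open"), delay = ord)
}

# zero-padded FFT convolution of every row of X with kern; output aligned so
# the two-pass filter is zero-phase
fir_apply_rows <- function(X, kern, delay) {
  n <- ncol(X)
  nfft <- stats::nextn(n + length(kern) - 1, 2)
  Ft <- mvfft(rbind(t(X), matrix(0, nfft - n, nrow(X))))
  K <- fft(c(kern, rep(0, nfft - length(kern))))
  Z <- Re(mvfft(Ft * K, inverse = TRUE)) / nfft
  t(Z[delay + seq_len(n), , drop = FALSE])
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR design applied forward and backward (realized
#' as one symmetric two-pass kernel via FFT convolution with zero padding),
#' so the passband is amplitude-preserving with exactly zero phase shift.
#' The filter order is `max(3 * rate / f_lo (rounded even), 66)`, at least
#' three cycles of the lowest band frequency.
#'
#' @param x A `source_epochs` object, or a `channels x samples` matrix.
#' @param band Canonical band name or `c(f_lo, f_hi)` in Hz.
#' @param sampling_rate Hz; taken from `x` when it is a `source_epochs`.
#' @return Same shape as the input, band-passed.
#' @export
fir_bandpass <- function(x, band, sampling_rate = NULL) {
  if (inherits(x, "source_epochs")) {
    k <- fir_twopass_kernel(band, x$sampling_rate)
    for (e in seq_len(n_epochs(x))) {
      x$data[, , e] <- fir_apply_rows(matrix(x$data[, , e], dim(x$data)[1]),
                                      k$kernel, k$delay)
    }
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(sampling_rate))
  k <- fir_twopass_kernel(band, sampling_rate)
  fir_apply_rows(x, k$kernel, k$delay)
}

#' Symmetric orthogonalization (closest orthogonal matrix)
#'
#' Finds the set of mutually orthogonal time series closest (in Frobenius
#' norm) to the input rows, removing zero-lag leakage correlations induced by
#' source reconstruction. Iterative Procrustes scheme: alternately fit an
#' orthonormal row basis (polar decomposition via SVD) and per-row scale
#' factors; the objective is non-increasing and iteration stops when its
#' relative change falls below `tol`.
#'
#' All iterations run in the k-dimensional row-space basis of the input, so
#' the per-iteration cost is O(k^3) regardless of the number of samples.
#'
#' @param X `seeds x samples` matrix (more samples than seeds).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum iterations; non-convergence is flagged with a
#'   warning and `attr(, "converged") = FALSE`.
#' @return Matrix of the same shape with exactly orthogonal rows;
#'   attributes `iterations`, `converged`, `objective` (final squared
#'   Frobenius residual), `objective_trace`.
#' @export
orthogonalize_symmetric <- function(X, tol = 1e-8, max_iter = 200) {
  stopifnot(is.matrix(X))
  k <- nrow(X)
  if (ncol(X) <= k) {
    stop("need more samples than seeds to orthogonalize", call. = FALSE)
  }
  rn <- sqrt(rowSums(X^2))
  if (any(rn == 0)) {
    stop("degenerate input: all-zero row(s) ",
         paste(which(rn == 0), collapse = ", "), call. = FALSE)
  }
  # run the iteration in the k-dim row-space basis: X = C %*% B with B
  # orthonormal rows. Fast path via the k x k Gram matrix; fall back to a
  # full SVD when the input is (near) rank-deficient, where LAPACK
  # completes the basis for zero singular values (so duplicated rows work)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) > 1e-12 * max(eg$values)) {
    s <- sqrt(eg$values)
    C <- eg$vectors * rep(s, each = k)          # k x k
    B <- (t(eg$vectors) / s) %*% X              # orthonormal rows
  } else {
    sv <- svd(X)
    C <- sv$u * rep(sv$d, each = k)
    B <- t(sv$v)
  }
  d <- rep(1, k)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  O_red <- NULL
  converged <- FALSE
  polar_factor <- function(A) {
    # O = A (A'A)^{-1/2}; symmetric-eigen fast path, SVD when singular
    E <- eigen(crossprod(A), symmetric = TRUE)
    if (min(E$values) > 1e-12 * max(E$values, .Machine$double.eps)) {
      A %*% (E$vectors %*% (t(E$vectors) / sqrt(E$values)))
    } else {
      ps <- svd(A)
      ps$u %*% t(ps$v)
    }
  }
  for (it in seq_len(max_iter)) {
    O_red <- polar_factor(C * d)  # polar factor of diag(d) %*% C
    d <- rowSums(C * O_red)
    obj <- sum((C - d * O_red)^2)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged) {
    warning("symmetric orthogonalization did not converge in ", max_iter,
            " iterations")
  }
  out <- (d * O_red) %*% B
  attr(out, "iterations") <- length(obj_trace)
  attr(out, "converged") <- converged
  attr(out, "objective") <- obj_trace[length(obj_trace)]
  attr(out, "objective_trace") <- obj_trace
  out
}

#' Instantaneous amplitude envelope via the analytic signal
#'
#' Modulus of the Hilbert analytic signal, computed per row by FFT.
#'
#' @param X `seeds x samples` matrix.
#' @return Non-negative matrix of the same shape.
#' @export
hilbert_envelope <- function(X) {
  stopifnot(is.matrix(X))
  n <- ncol(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Ft <- mvfft(t(X)) * h
  t(Mod(mvfft(Ft, inverse = TRUE)) / n)
}

#' Temporally downsample an envelope by block averaging
#'
#' Mean over consecutive non-overlapping windows of `1 / target_rate`
#' seconds (anti-aliasing comes free with the block mean).
#'
#' @param env `seeds x samples` envelope matrix.
#' @param sampling_rate Hz of `env`.
#' @param target_rate Hz (default 1).
#' @return `seeds x (duration * target_rate)` matrix.
#' @export
downsample_envelope <- function(env, sampling_rate, target_rate = 1) {
  stopifnot(is.matrix(env))
  w <- sampling_rate / target_rate
  if (abs(w - round(w)) > 1e-9 || ncol(env) %% round(w) != 0) {
    stop("epoch length must be an integer number of 1/target_rate windows",
         call. = FALSE)
  }
  w <- round(w)
  nb <- ncol(env) / w
  out <- matrix(0, nrow(env), nb)
  for (j in seq_len(nb)) {
    out[, j] <- rowMeans(env[, (j - 1) * w + seq_len(w), drop = FALSE])
  }
  out
}

#' Per-epoch amplitude-envelope-correlation matrix
#'
#' Pearson correlation between seed envelopes across one epoch; symmetric,
#' with the diagonal set to 0 by convention. Pairs involving a constant
#' envelope are set missing (with a warning).
#'
#' @param env `seeds x samples` (downsampled) envelope matrix, >= 3 samples.
#' @return `seeds x seeds` correlation matrix.
#' @export
aec_matrix <- function(env) {
  stopifnot(is.matrix(env))
  if (ncol(env) < 3) stop("need at least 3 samples per epoch", call. = FALSE)
  sdv <- apply(env, 1, sd)
  if (any(sdv == 0)) {
    warning("constant envelope(s) in seed(s) ",
            paste(which(sdv == 0), collapse = ", "),
            "; their AEC values are set missing")
  }
  r <- suppressWarnings(cor(t(env)))
  diag(r) <- 0
  r
}

#' Static AEC: average per-epoch matrices
#'
#' @param mats List of per-epoch `seeds x seeds` matrices, or a
#'   `seeds x seeds x epochs` array.
#' @return Element-wise mean matrix.
#' @export
static_aec <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) {
    stopifnot(dim(mats)[3] >= 1)
    return(apply(mats, c(1, 2), mean))
  }
  stopifnot(is.list(mats), length(mats) >= 1)
  Reduce(`+`, mats) / length(mats)
}

#' Band-limited leakage-corrected AEC connectome of one subject
#'
#' Runs the fixed per-epoch pipeline (band-pass FIR, symmetric
#' orthogonalization, Hilbert envelope, block-mean downsampling to 1 Hz,
#' Pearson correlation) and averages the per-epoch matrices into a static
#' connectome.
#'
#' @param se A `source_epochs` object.
#' @param band Canonical band name.
#' @param orthogonalize Apply leakage correction (default TRUE; FALSE exists
#'   for demonstrating leakage suppression, not for analysis).
#' @param target_rate Envelope sampling rate after downsampling, Hz.
#' @param keep_epochs Also return the per-epoch stack.
#' @return `seeds x seeds` static AEC matrix; attributes `band`, `n_epochs`
#'   and (optionally) `epochs`.
#' @export
connectivity_aec <- function(se, band, orthogonalize = TRUE,
                             target_rate = 1, keep_epochs = FALSE) {
  stopifnot(inherits(se, "source_epochs"), n_epochs(se) >= 1)
  k <- fir_twopass_kernel(band, se$sampling_rate)
  ne <- n_epochs(se)
  per_epoch <- vector("list", ne)
  for (e in seq_len(ne)) {
    Xf <- fir_apply_rows(matrix(se$data[, , e], dim(se$data)[1]),
                         k$kernel, k$delay)
    if (orthogonalize) Xf <- orthogonalize_symmetric(Xf)
    env <- hilbert_envelope(Xf)
    env <- downsample_envelope(env, se$sampling_rate, target_rate)
    per_epoch[[e]] <- aec_matrix(env)
  }
  out <- static_aec(per_epoch)
  dimnames(out) <- list(se$labels, se$labels)
  attr(out, "band") <- if (is.character(band)) band else paste(band, collapse = "-")
  attr(out, "n_epochs") <- ne
  if (keep_epochs) attr(out, "epochs") <- per_epoch
  out
}
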