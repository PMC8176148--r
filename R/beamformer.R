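# LCMV beamformer: broadband virtual sensors at the seed locations, with
# 5% Tikhonov regularization of the pooled sensor covariance and a scalar
# (power-maximizing) orientation per seed.

#' Beamformer configuration
#'
#' @param regularization_fraction Tikhonov loading as a fraction of the mean
#'   sensor variance, i.e. lambda = fraction * trace(C) / n_channels
#'   (default 0.05).
#' @return A named list.
#' @export
beamformer_config <- function(regularization_fraction = 0.05) {
  stopifnot(regularization_fraction >= 0)
  list(regularization_fraction = regularization_fraction)
}

#' LCMV beamformer reconstruction at seed locations
#'
#' Pools the sensor covariance over retained epochs, regularizes it with
#' `lambda = fraction * trace(C) / n_channels`, picks per seed the scalar
#' orientation in the tangential plane that maximizes beamformer output
#' power (the minimizer of `u' L' C^-1 L u`), and applies the unit-gain
#' minimum-variance weights `w = C^-1 l / (l' C^-1 l)` to every epoch.
#'
#' @param ep An `epoched_recording` after rejection, or a `source_epochs`
#'   holding sensor epochs (retained epochs only).
#' @param source_model Seed table; leadfields are computed from it and the
#'   recording's head model unless `leadfields` is given.
#' @param head_model Needed when `ep` carries no head model.
#' @param leadfields Optional precomputed list of `channels x 2` gain
#'   matrices (one per seed), as from [compute_leadfield()].
#' @param config A [beamformer_config()].
#' @return A `source_epochs` object (`seeds x samples x epochs`) with
#'   attributes `weights` (channels x seeds), `orientations` (seeds x 3)
#'   and `leadfields`.
#' @export
lcmv_beamformer <- function(ep, source_model, head_model = NULL,
                            leadfields = NULL,
                            config = beamformer_config()) {
  if (inherits(ep, "epoched_recording")) {
    keep <- ep$flags$reason == "none"
    arr <- ep$data[, , keep, drop = FALSE]
    fs <- ep$sampling_rate
  } else if (inherits(ep, "source_epochs")) {
    arr <- ep$data
    fs <- ep$sampling_rate
  } else stop("need an epoched_recording or source_epochs", call. = FALSE)
  ne <- dim(arr)[3]
  if (ne < 1) stop("no retained epochs", call. = FALSE)
  nchan <- dim(arr)[1]
  spe <- dim(arr)[2]
  if (is.null(leadfields)) {
    stopifnot(!is.null(head_model))
    pos <- seed_positions(source_model)
    leadfields <- lapply(seq_len(nrow(pos)), function(i) {
      compute_leadfield(head_model, pos[i, ])
    })
  }
  stopifnot(all(vapply(leadfields, nrow, 1L) == nchan))
  C <- matrix(0, nchan, nchan)
  for (e in seq_len(ne)) {
    Xe <- matrix(arr[, , e], nchan)
    Xe <- Xe - rowMeans(Xe)
    C <- C + tcrossprod(Xe) / (spe - 1)
  }
  C <- C / ne
  lambda <- config$regularization_fraction * sum(diag(C)) / nchan
  Ci <- solve(C + diag(lambda, nchan))
  nseed <- length(leadfields)
  W <- matrix(0, nchan, nseed)
  orient <- matrix(0, nseed, 3)
  for (s in seq_len(nseed)) {
    L <- leadfields[[s]]
    M <- crossprod(L, Ci %*% L)        # 2 x 2
    evd <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- evd$vectors[, 2]              # smallest eigenvalue -> max power
    l <- as.numeric(L %*% u)
    Cil <- Ci %*% l
    W[, s] <- Cil / sum(l * Cil)
    tg <- attr(L, "tangentials")
    if (!is.null(tg)) orient[s, ] <- u[1] * tg[1, ] + u[2] * tg[2, ]
  }
  out <- array(0, c(nseed, spe, ne))
  for (e in seq_len(ne)) {
    out[, , e] <- crossprod(W, matrix(arr[, , e], nchan))
  }
  se <- source_epochs(out, fs, source_model$label)
  attr(se, "weights") <- W
  attr(se, "orientations") <- orient
  attr(se, "leadfields") <- leadfields
  se
}
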