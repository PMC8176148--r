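# Core containers: epoched virtual-sensor time series.

#' Construct a source_epochs container
#'
#' @param data `seeds x samples x epochs` numeric array.
#' @param sampling_rate Hz.
#' @param labels Seed labels (length = first dim).
#' @return Object of class `source_epochs`.
#' @export
source_epochs <- function(data, sampling_rate, labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(labels)) labels <- paste0("seed_", seq_len(dim(data)[1]))
  stopifnot(length(labels) == dim(data)[1])
  structure(list(data = data, sampling_rate = sampling_rate, labels = labels),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<source_epochs>", d[1], "seeds x", d[2], "samples x", d[3],
      "epochs @", x$sampling_rate, "Hz\n")
  invisible(x)
}

n_epochs <- function(se) dim(se$data)[3]
n_seeds_of <- function(se) dim(se$data)[1]

#' Epoch a continuous multichannel matrix
#'
#' Cuts `floor(duration / epoch_length)` non-overlapping epochs; a trailing
#' partial segment is dropped.
#'
#' @param x `channels x samples` matrix with a `sampling_rate` attribute, or
#'   supply `sampling_rate`.
#' @param epoch_length Seconds (default 10).
#' @param sampling_rate Hz; defaults to `attr(x, "sampling_rate")`.
#' @return A `source_epochs` object (0 epochs, with a warning, when the
#'   input is shorter than one epoch).
#' @export
epoch_sources <- function(x, epoch_length = 10, sampling_rate = NULL) {
  if (is.null(sampling_rate)) sampling_rate <- attr(x, "sampling_rate")
  stopifnot(!is.null(sampling_rate), is.matrix(x))
  spe <- round(epoch_length * sampling_rate)
  ne <- floor(ncol(x) / spe)
  if (ne == 0) {
    warning("recording shorter than one epoch; returning 0 epochs")
    return(source_epochs(array(0, c(nrow(x), spe, 0)), sampling_rate,
                         rownames(x)))
  }
  arr <- array(x[, seq_len(ne * spe)], c(nrow(x), spe, ne))
  source_epochs(arr, sampling_rate, rownames(x))
}

#' Z-score virtual-sensor time series over concatenated epochs
#'
#' Each seed's series, concatenated across retained epochs, is standardized
#' to mean 0 and SD 1 (per-epoch means are not individually zero).
#'
#' @param se A `source_epochs` object.
#' @return The standardized `source_epochs`.
#' @export
zscore_sources <- function(se) {
  stopifnot(inherits(se, "source_epochs"))
  d <- dim(se$data)
  flat <- matrix(se$data, d[1], d[2] * d[3])
  mu <- rowMeans(flat)
  sdv <- sqrt(rowMeans((flat - mu)^2) * (d[2] * d[3]) / (d[2] * d[3] - 1))
  if (any(sdv == 0)) {
    stop("constant series cannot be z-scored (seed ",
         paste(which(sdv == 0), collapse = ", "), ")", call. = FALSE)
  }
  se$data <- array((flat - mu) / sdv, d)
  se
}
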