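# Sensor-level synthesis: forward projection of source signals through the
# spherical head model, head-position traces, and artifact injection.

#' Construct a sensor_recording container
#'
#' @param data `channels x samples` matrix, fT.
#' @param sampling_rate Hz.
#' @param head_model The `head_model` the channels belong to.
#' @param head_position `samples x 3` head-position trace in mm (optional;
#'   zeros when absent).
#' @param subject_id Identifier string.
#' @return Object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, sampling_rate, head_model,
                             head_position = NULL, subject_id = "subject") {
  stopifnot(is.matrix(data), nrow(data) == nrow(head_model$sensor_positions))
  if (!all(is.finite(data))) stop("non-finite sensor data", call. = FALSE)
  if (is.null(head_position)) head_position <- matrix(0, ncol(data), 3)
  stopifnot(nrow(head_position) == ncol(data), ncol(head_position) == 3)
  structure(list(data = data, sampling_rate = sampling_rate,
                 head_model = head_model, head_position = head_position,
                 subject_id = subject_id),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording>", x$subject_id, ":", nrow(x$data), "channels x",
      ncol(x$data), "samples @", x$sampling_rate, "Hz (",
      round(ncol(x$data) / x$sampling_rate, 1), "s )\n")
  invisible(x)
}

#' Simulate a head-position trace
#'
#' Slow (< 0.05 Hz) three-axis wander, self-scaled so that the mean
#' per-epoch maximum displacement from the recording median matches the
#' subject's head-motion covariate.
#'
#' @param n_samples,sampling_rate Trace length and rate.
#' @param head_motion Target mean per-epoch (10 s) max displacement, mm.
#' @param epoch_length Epoch length used for the self-scaling, s.
#' @return `n_samples x 3` matrix, mm.
#' @export
simulate_head_position <- function(n_samples, sampling_rate, head_motion,
                                   epoch_length = 10) {
  lp <- signal::butter(2, min(0.05 / (sampling_rate / 2), 0.99), "low")
  tr <- filter_ba(lp, matrix(rnorm(n_samples * 3), n_samples, 3))
  med <- apply(tr, 2, median)
  disp <- sqrt(rowSums(sweep(tr, 2, med)^2))
  spe <- round(epoch_length * sampling_rate)
  ne <- max(1, floor(n_samples / spe))
  m0 <- mean(sapply(seq_len(ne), function(e) {
    max(disp[(e - 1) * spe + seq_len(spe)])
  }))
  if (m0 <= 0) m0 <- 1
  tr * (head_motion / m0)
}

#' Project source signals to the sensor array
#'
#' Sensor data = leadfield x source signals + white noise. Each seed
#' contributes through its fixed tangential dipole orientation scaled by
#' `dipole_moment` (radial moments are magnetically silent in the spherical
#' model, which is why orientations are constrained tangential).
#'
#' @param source_signal `seeds x samples` matrix (arbitrary units).
#' @param source_model,head_model Geometry.
#' @param dipole_moment Moment magnitude per unit source amplitude, A*m
#'   (default 10 nAm).
#' @param sensor_noise_sd White sensor noise SD, fT.
#' @param head_position Optional `samples x 3` trace (mm) to attach.
#' @param subject_id Identifier.
#' @return A `sensor_recording`.
#' @export
project_to_sensors <- function(source_signal, source_model, head_model,
                               dipole_moment = 1e-8, sensor_noise_sd = 0,
                               head_position = NULL,
                               subject_id = "subject") {
  validate_head_model(head_model)
  validate_source_model(source_model, head_model)
  stopifnot(nrow(source_signal) == nrow(source_model))
  orient <- seed_orientations(source_model, head_model)
  pos <- seed_positions(source_model)
  G <- sapply(seq_len(nrow(pos)), function(i) {
    leadfield_for_moment(head_model, pos[i, ], dipole_moment * orient[i, ])
  })
  data <- G %*% source_signal
  if (sensor_noise_sd > 0) {
    data <- data + matrix(rnorm(length(data), sd = sensor_noise_sd),
                          nrow(data))
  }
  fs <- attr(source_signal, "sampling_rate")
  if (is.null(fs)) stop("source_signal needs a sampling_rate attribute",
                        call. = FALSE)
  rec <- sensor_recording(data, fs, head_model, head_position, subject_id)
  attr(rec, "gain") <- G
  rec
}

#' Inject ocular/cardiac/motion/jump artifacts
#'
#' Adds (a) a spatially fixed frontal blink component (Poisson events,
#' smooth ~300 ms bumps), (b) a ~1.2 Hz cardiac QRS-like train with a fixed
#' spatial pattern, (c) occasional smooth head-position excursions whose
#' magnitudes straddle the motion-rejection threshold, and (d) step jumps in
#' random channels. The injected time courses are returned as ground truth.
#'
#' @param recording A `sensor_recording`.
#' @param artifact_model See [default_artifact_model()]. Zero amplitudes /
#'   probabilities leave the recording untouched.
#' @param seed RNG seed for the artifact draws.
#' @param epoch_length Epoch grid (s) used for excursion/jump placement.
#' @return The contaminated `sensor_recording`; attribute `"artifacts"`
#'   holds the ground-truth time courses and event tables.
#' @export
inject_artifacts <- function(recording, artifact_model = default_artifact_model(),
                             seed = 1, epoch_length = 10) {
  stopifnot(inherits(recording, "sensor_recording"))
  set.seed(seed)
  am <- artifact_model
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  nchan <- nrow(recording$data)
  dur <- n / fs
  spe <- round(epoch_length * fs)
  ne <- floor(n / spe)
  truth <- list()

  bump <- function(width_s) {
    m <- round(width_s * fs)
    0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  }
  add_events <- function(course, times, kern, amps) {
    for (k in seq_along(times)) {
      i0 <- round(times[k] * fs)
      idx <- i0 + seq_along(kern)
      ok <- idx >= 1 & idx <= n
      course[idx[ok]] <- course[idx[ok]] + amps[k] * kern[ok]
    }
    course
  }

  # (a) ocular: frontal topography, slow blinks
  if (am$ocular_amplitude > 0 && am$blink_rate > 0) {
    n_ev <- stats::rpois(1, am$blink_rate * dur)
    u <- add_events(numeric(n), sort(runif(n_ev, 0, dur - 0.5)),
                    bump(0.3), rep(1, n_ev))
    y <- recording$head_model$sensor_positions[, 2]
    w <- exp((y - max(y)) / 0.03)
    recording$data <- recording$data +
      (w * am$ocular_amplitude) %o% u
    truth$ocular_course <- u
    truth$ocular_pattern <- w
  }
  # (b) cardiac: QRS-like biphasic train, fixed random smooth pattern
  if (am$cardiac_amplitude > 0 && am$cardiac_rate > 0) {
    beats <- cumsum(pmax(0.3, rnorm(ceiling(dur * am$cardiac_rate * 1.5),
                                    1 / am$cardiac_rate,
                                    0.05 / am$cardiac_rate)))
    beats <- beats[beats < dur - 0.2]
    tt <- seq(-0.05, 0.05, by = 1 / fs)
    qrs <- -tt / 0.02 * exp(0.5 - (tt / 0.02)^2 / 2)  # derivative-of-Gaussian
    v <- add_events(numeric(n), beats, qrs, rep(1, length(beats)))
    p <- rnorm(nchan)
    p <- p / max(abs(p))
    recording$data <- recording$data + (p * am$cardiac_amplitude) %o% v
    truth$cardiac_course <- v
    truth$cardiac_pattern <- p
  }
  # (c) motion excursions on the head-position trace
  if (am$excursion_prob > 0 && ne > 0) {
    hit <- which(runif(ne) < am$excursion_prob)
    exc <- data.frame(epoch = integer(0), magnitude = numeric(0))
    for (e in hit) {
      mag <- runif(1, am$excursion_range[1], am$excursion_range[2])
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      kern <- bump(2) * mag
      i0 <- (e - 1) * spe + sample.int(spe - length(kern), 1)
      idx <- i0 + seq_along(kern)
      recording$head_position[idx, ] <- recording$head_position[idx, ] +
        kern %o% dir
      exc <- rbind(exc, data.frame(epoch = e, magnitude = mag))
    }
    truth$excursions <- exc
  }
  # (d) step jumps in random channels
  if (am$jump_prob > 0 && ne > 0) {
    hit <- which(runif(ne) < am$jump_prob)
    jm <- data.frame(epoch = integer(0), channel = integer(0),
                     sample = integer(0), amplitude = numeric(0))
    for (e in hit) {
      ch <- sample.int(nchan, 1)
      i0 <- (e - 1) * spe + sample.int(spe, 1)
      a <- sample(c(-1, 1), 1) * am$jump_amplitude
      recording$data[ch, i0:n] <- recording$data[ch, i0:n] + a
      jm <- rbind(jm, data.frame(epoch = e, channel = ch, sample = i0,
                                 amplitude = a))
    }
    truth$jumps <- jm
  }
  attr(recording, "artifacts") <- truth
  recording
}
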