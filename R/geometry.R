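# Head and source geometry for the spherical forward model.
#
# Coordinate convention (head frame, metres): x = left(-)/right(+),
# y = posterior(-)/anterior(+), z = inferior(-)/superior(+), sphere centred
# at the origin.

#' Spherical head model with a helmet-like sensor array
#'
#' A homogeneous conducting sphere with axial sensors arranged on a
#' helmet-shaped cap outside the sphere, oriented radially. This is the
#' forward-model geometry used both to project simulated sources to the
#' sensors and to build beamformer leadfields.
#'
#' @param n_sensors Number of sensors (default 151).
#' @param sphere_radius Conductor sphere radius in metres (default 0.09).
#' @param sensor_radius Radial distance of the sensors from the sphere centre
#'   in metres (default 0.11); must exceed `sphere_radius`.
#' @return An object of class `head_model`: list with `sphere_center` (3),
#'   `sphere_radius`, `sensor_positions` (n x 3, m) and `sensor_orientations`
#'   (n x 3, unit radial vectors).
#' @export
default_head_model <- function(n_sensors = 151, sphere_radius = 0.09,
                               sensor_radius = 0.11) {
  stopifnot(n_sensors >= 2, sensor_radius > sphere_radius)
  i <- seq_len(n_sensors)
  # quasi-uniform cap: cos(polar angle) spans [-0.35, 0.95], golden-angle azimuth
  cz <- -0.35 + (0.95 - (-0.35)) * (i - 0.5) / n_sensors
  st <- sqrt(pmax(0, 1 - cz^2))
  az <- 2 * pi * ((i * 0.6180339887498949) %% 1)
  dir <- cbind(st * cos(az), st * sin(az), cz)
  hm <- structure(list(
    sphere_center = c(0, 0, 0),
    sphere_radius = sphere_radius,
    sensor_positions = dir * sensor_radius,
    sensor_orientations = dir
  ), class = "head_model")
  validate_head_model(hm)
  hm
}

validate_head_model <- function(hm) {
  stopifnot(inherits(hm, "head_model"))
  norms <- sqrt(rowSums(hm$sensor_orientations^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop("sensor orientations must be unit vectors", call. = FALSE)
  }
  d <- sweep(hm$sensor_positions, 2, hm$sphere_center)
  if (any(sqrt(rowSums(d^2)) <= hm$sphere_radius)) {
    stop("all sensors must lie outside the conductor sphere", call. = FALSE)
  }
  invisible(hm)
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> spherical conductor, radius",
      format(x$sphere_radius), "m,", nrow(x$sensor_positions),
      "radial sensors\n")
  invisible(x)
}

#' Default 90-seed source model
#'
#' Deterministic atlas-like seed set: 45 seeds per hemisphere placed
#' quasi-uniformly inside the conductor sphere, labelled by lobe (frontal,
#' temporal, parietal, occipital, limbic) and hemisphere. Limbic/subcortical
#' seeds sit on a deep shell, all others on a superficial shell. The layout
#' stands in for an anatomical parcellation seed set (e.g. 90 atlas
#' centroids) when simulating; for real data the seed table is a
#' configuration input.
#'
#' @param n_seeds Total number of seeds; must be even (half per hemisphere).
#' @param shallow_radius,deep_radius Shell radii in metres.
#' @return An object of class `source_model`: data.frame with columns
#'   `label`, `x`, `y`, `z` (m), `lobe`, `hemisphere`.
#' @export
default_source_model <- function(n_seeds = 90, shallow_radius = 0.065,
                                 deep_radius = 0.035) {
  stopifnot(n_seeds >= 2, n_seeds %% 2 == 0)
  nh <- n_seeds / 2
  i <- seq_len(nh)
  cz <- -1 + 2 * (i - 0.5) / nh
  st <- sqrt(pmax(0, 1 - cz^2))
  # azimuth in (0, pi) keeps x > 0: right hemisphere, mirrored for left
  az <- pi * ((i * 0.6180339887498949) %% 1)
  dir <- cbind(st * sin(az), st * cos(az), cz)  # x>0, y in [-1,1], z in [-1,1]
  lobe <- ifelse(dir[, 2] < -0.45 & dir[, 3] < 0.6, "occipital",
          ifelse(dir[, 2] > 0.35, "frontal",
          ifelse(dir[, 3] > 0.55, "parietal",
          ifelse(dir[, 3] < 0.15, "temporal", "limbic"))))
  r <- ifelse(lobe == "limbic", deep_radius, shallow_radius)
  pos_r <- dir * r
  mk <- function(pos, hemi) {
    idx <- stats::ave(seq_along(lobe), lobe, FUN = seq_along)
    data.frame(
      label = paste0(toupper(substring(lobe, 1, 1)), substring(lobe, 2),
                     "_", idx, "_", hemi),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      lobe = lobe, hemisphere = hemi, stringsAsFactors = FALSE
    )
  }
  sm <- rbind(mk(pos_r, "R"), mk(pos_r * cbind(rep(-1, nh), 1, 1), "L"))
  sm <- sm[order(sm$hemisphere, sm$lobe, sm$label), ]
  rownames(sm) <- NULL
  class(sm) <- c("source_model", "data.frame")
  validate_source_model(sm)
  sm
}

validate_source_model <- function(sm, head_model = NULL) {
  stopifnot(inherits(sm, "data.frame"),
            all(c("label", "x", "y", "z", "lobe", "hemisphere") %in% names(sm)))
  if (anyDuplicated(sm$label)) stop("seed labels must be unique", call. = FALSE)
  if (!all(sm$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  lobes <- c("frontal", "temporal", "parietal", "occipital", "limbic")
  if (!all(sm$lobe %in% lobes)) {
    stop("lobe must be one of: ", paste(lobes, collapse = ", "), call. = FALSE)
  }
  if (!is.null(head_model)) {
    d <- sqrt(rowSums(sweep(as.matrix(sm[, c("x", "y", "z")]), 2,
                            head_model$sphere_center)^2))
    if (any(d >= head_model$sphere_radius)) {
      stop("all seeds must lie strictly inside the conductor sphere",
           call. = FALSE)
    }
  }
  invisible(sm)
}

#' @export
print.source_model <- function(x, ...) {
  cat("<source_model>", nrow(x), "seeds;",
      paste(names(table(x$lobe)), table(x$lobe), collapse = ", "), "\n")
  NextMethod()
}

seed_positions <- function(sm) as.matrix(sm[, c("x", "y", "z")])

# fixed tangential unit orientation for each seed: tangential to the sphere,
# deterministic, never radial (radial dipoles are magnetically silent in a
# spherical conductor)
seed_orientations <- function(sm, head_model) {
  pos <- sweep(seed_positions(sm), 2, head_model$sphere_center)
  t(apply(pos, 1, function(p) {
    r <- sqrt(sum(p^2))
    if (r < 1e-12) return(c(1, 0, 0))
    rad <- p / r
    ref <- if (abs(rad[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    tg <- ref - sum(ref * rad) * rad
    tg / sqrt(sum(tg^2))
  }))
}
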