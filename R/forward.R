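# Forward model: magnetic field of a current dipole in a homogeneous
# conducting sphere (Sarvas closed form), sampled at the sensor array.

MU0_4PI <- 1e-7  # mu0 / (4*pi), T*m/A

# Field component along each sensor orientation for one dipole.
# r0: dipole position (3, m, head frame); q: dipole moment (3, A*m).
# Returns fT per sensor.
sarvas_field <- function(hm, r0, q) {
  r0 <- r0 - hm$sphere_center
  rs <- sweep(hm$sensor_positions, 2, hm$sphere_center)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  n <- nrow(rs)
  out <- numeric(n)
  for (k in seq_len(n)) {
    r <- rs[k, ]
    a <- r - r0
    an <- sqrt(sum(a * a))
    rn <- sqrt(sum(r * r))
    adotr <- sum(a * r)
    f <- an * (rn * an + rn^2 - sum(r0 * r))
    gf <- (an^2 / rn + adotr / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + adotr / an) * r0
    b <- (f * qxr0 - sum(qxr0 * r) * gf) * (MU0_4PI / f^2)
    out[k] <- sum(b * hm$sensor_orientations[k, ])
  }
  out * 1e15  # T -> fT
}

#' Leadfield of one seed in the spherical head model
#'
#' Closed-form magnetic field of a current dipole inside a homogeneous
#' conducting sphere, sampled along the sensor orientations, for two
#' tangential unit moments. A dipole at the sphere centre, or any radial
#' moment, produces zero field; only the tangential plane carries signal,
#' which is why the leadfield has two columns.
#'
#' @param head_model A [default_head_model()]-style `head_model`.
#' @param seed_position Numeric length-3 position in metres, strictly inside
#'   the sphere.
#' @return `n_sensors x 2` gain matrix in fT per (A*m); columns correspond to
#'   two orthogonal tangential unit moments (attribute `"tangentials"`,
#'   a 2 x 3 matrix).
#' @export
compute_leadfield <- function(head_model, seed_position) {
  validate_head_model(head_model)
  p <- seed_position - head_model$sphere_center
  r <- sqrt(sum(p^2))
  if (r >= head_model$sphere_radius) {
    stop("seed must lie strictly inside the conductor sphere", call. = FALSE)
  }
  if (r < 1e-12) {
    tg <- rbind(c(1, 0, 0), c(0, 1, 0))
  } else {
    rad <- p / r
    ref <- if (abs(rad[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    t1 <- ref - sum(ref * rad) * rad
    t1 <- t1 / sqrt(sum(t1 * t1))
    t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
            rad[3] * t1[1] - rad[1] * t1[3],
            rad[1] * t1[2] - rad[2] * t1[1])
    tg <- rbind(t1, t2)
  }
  lf <- cbind(sarvas_field(head_model, seed_position, tg[1, ]),
              sarvas_field(head_model, seed_position, tg[2, ]))
  attr(lf, "tangentials") <- tg
  lf
}

# leadfield column for an arbitrary (not necessarily tangential) moment
leadfield_for_moment <- function(head_model, seed_position, moment) {
  sarvas_field(head_model, seed_position, moment)
}
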