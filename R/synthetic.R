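# Synthetic cohort generator: source-level MEG-like data with known,
# plantable group effects, so every downstream stage is testable without
# access to any recording.
#
# Signal model per seed: a sum over canonical bands of band-limited carriers
# (band-passed Gaussian noise, unit RMS) multiplied by slow positive
# envelopes (|low-pass Gaussian| + offset). Group effects enter in exactly
# two places: band amplitude scaling (regional power) and shared envelope
# components between edge endpoints (envelope coupling), the latter
# calibrated empirically against the measured AEC.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: two groups (16 mTBI / 20
#' control), 600 Hz, 5-minute eyes-open rest, 90 seeds, age and head-motion
#' distributions that differ by group (head motion means 1.83 vs 0.64 mm),
#' a delta-band regional power increase (amplitude x 1.5) in occipital seeds
#' of the mTBI group, delta-band hypo-connectivity (AEC shift -0.15 on 30
#' edges) and theta-band hyper-connectivity (+0.10 on 10 edges).
#'
#' @param n_per_group Named counts, `c(mtbi = , control = )`.
#' @param sampling_rate Hz.
#' @param duration Seconds of continuous data per subject.
#' @param n_seeds Number of sources; must match `source_model` when one is
#'   supplied to [generate_cohort()].
#' @param band_amplitudes Named baseline carrier amplitudes per canonical
#'   band (arbitrary units).
#' @param power_effects List of effects, each
#'   `list(band =, seeds =, group =, factor =)` with `factor` > 0
#'   multiplying the band amplitude for that group (power scales with
#'   `factor^2`).
#' @param coupling_effects List of effects, each
#'   `list(band =, edges =, shift =)` with `edges` a 2-column matrix of seed
#'   indices (disjoint within a band) and `shift` in (-1, 1): the target
#'   group difference in measured AEC (mtbi minus control). Negative shifts
#'   plant coupling in the control group, positive in the mTBI group.
#' @param covariate_model Distributions for age (truncated normal, years),
#'   head motion (log-normal, mm) and sex per group.
#' @param artifact_model Amplitudes/rates for ocular, cardiac, motion
#'   excursion and sensor jump artifacts (used by [inject_artifacts()]).
#' @param envelope_cutoff Low-pass cutoff of the envelope dynamics, Hz.
#' @param envelope_offset Positive offset added to the rectified envelope.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(mtbi = 16, control = 20),
                             sampling_rate = 600,
                             duration = 300,
                             n_seeds = 90,
                             band_amplitudes = c(delta = 1.0, theta = 0.9,
                                                 alpha = 1.1, beta = 0.7,
                                                 lgamma1 = 0.4, lgamma2 = 0.3,
                                                 hgamma = 0.25),
                             power_effects = NULL,
                             coupling_effects = NULL,
                             covariate_model = default_covariate_model(),
                             artifact_model = default_artifact_model(),
                             envelope_cutoff = 0.25,
                             envelope_offset = 0.5,
                             seed = 42) {
  stopifnot(all(c("mtbi", "control") %in% names(n_per_group)),
            all(n_per_group >= 1), sampling_rate > 0, duration > 0,
            n_seeds >= 2, envelope_cutoff > 0, envelope_offset >= 0)
  assert_bands(names(band_amplitudes))
  sm <- default_source_model(n_seeds)
  if (is.null(power_effects)) {
    power_effects <- Filter(function(e) e$band %in% names(band_amplitudes),
                            default_power_effects(sm))
  }
  if (is.null(coupling_effects)) {
    coupling_effects <- Filter(function(e) e$band %in% names(band_amplitudes),
                               default_coupling_effects(sm))
  }
  cfg <- structure(list(
    n_per_group = n_per_group, sampling_rate = sampling_rate,
    duration = duration, n_seeds = n_seeds,
    band_amplitudes = band_amplitudes,
    power_effects = power_effects, coupling_effects = coupling_effects,
    covariate_model = covariate_model, artifact_model = artifact_model,
    envelope_cutoff = envelope_cutoff, envelope_offset = envelope_offset,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>", x$n_per_group[["mtbi"]], "mtbi /",
      x$n_per_group[["control"]], "control;", x$n_seeds, "seeds;",
      x$duration, "s @", x$sampling_rate, "Hz;",
      length(x$power_effects), "power effect(s),",
      length(x$coupling_effects), "coupling effect(s); seed", x$seed, "\n")
  invisible(x)
}

#' Default group-dependent covariate distributions
#'
#' Age: truncated normal within 6-18 years (mtbi mean 12.46, SD 3.24;
#' control mean 13.14, SD 2.69). Head motion: log-normal matched to mean/SD
#' 1.83/1.79 mm (mtbi) and 0.64/0.51 mm (control) — motion is deliberately
#' group-dependent so covariate adjustment is genuinely exercised.
#' Sex: Bernoulli on male with group-specific rates (11/16 and 10/20).
#' @return Nested list consumed by [generate_cohort()].
#' @export
default_covariate_model <- function() {
  list(
    age = list(mtbi = c(mean = 12.46, sd = 3.24),
               control = c(mean = 13.14, sd = 2.69),
               range = c(6, 18)),
    head_motion = list(mtbi = c(mean = 1.83, sd = 1.79),
                       control = c(mean = 0.64, sd = 0.51)),
    sex_p_male = c(mtbi = 11 / 16, control = 10 / 20)
  )
}

#' Default artifact model
#'
#' Ocular blinks (Poisson events, smooth ~300 ms bumps, frontal topography),
#' a ~1.2 Hz cardiac QRS-like train with a fixed spatial pattern, per-epoch
#' head-motion excursions whose magnitudes straddle the 10 mm rejection
#' threshold, and step jumps in random channels.
#' @return List of artifact parameters consumed by [inject_artifacts()].
#' @export
default_artifact_model <- function() {
  list(
    ocular_amplitude = 1500,   # fT
    blink_rate = 0.15,         # events / s
    cardiac_amplitude = 400,   # fT
    cardiac_rate = 1.2,        # Hz
    excursion_prob = 0.05,     # per epoch
    excursion_range = c(6, 15),# mm, straddles the 10 mm threshold
    jump_prob = 0.05,          # per epoch
    jump_amplitude = 2500      # fT
  )
}

#' Default planted regional power effects
#' @param source_model A `source_model`.
#' @return List with one effect: delta amplitude x 1.5 in all occipital
#'   seeds of the mTBI group.
#' @export
default_power_effects <- function(source_model) {
  list(list(band = "delta",
            seeds = which(source_model$lobe == "occipital"),
            group = "mtbi", factor = 1.5))
}

#' Default planted coupling effects
#'
#' Delta hypo-connectivity (shift -0.15) on 30 pairwise-disjoint edges and
#' theta hyper-connectivity (+0.10) on 10 disjoint edges, drawn from
#' non-occipital seeds so the power and coupling effects involve different
#' regions.
#' @param source_model A `source_model`.
#' @return List of coupling effects.
#' @export
default_coupling_effects <- function(source_model) {
  cand <- which(source_model$lobe != "occipital")
  mk_edges <- function(idx, n_edges) {
    m <- 2 * n_edges
    stopifnot(length(idx) >= m)
    first <- idx[seq_len(n_edges)]
    second <- idx[n_edges + seq_len(n_edges)]
    cbind(pmin(first, second), pmax(first, second))
  }
  n_delta <- min(30, floor(length(cand) / 2))
  eff <- list(list(band = "delta", edges = mk_edges(cand, n_delta),
                   shift = -0.15))
  # theta hyper-connectivity; edges may share endpoints with the delta set
  # (disjointness is only required within a band)
  n_theta <- min(10, floor(length(cand) / 2))
  if (n_theta >= 1) {
    eff <- c(eff, list(list(band = "theta",
                            edges = mk_edges(rev(cand), n_theta),
                            shift = 0.10)))
  }
  eff
}

validate_synthetic_config <- function(cfg) {
  bands <- names(cfg$band_amplitudes)
  if (any(cfg$band_amplitudes <= 0)) {
    stop("band amplitudes must be positive", call. = FALSE)
  }
  for (ef in cfg$power_effects) {
    if (!ef$band %in% bands) {
      stop("power effect references band '", ef$band,
           "' not in the configured band set", call. = FALSE)
    }
    if (is.null(ef$factor) || ef$factor <= 0) {
      stop("power effect amplitude factor must be > 0", call. = FALSE)
    }
    if (any(ef$seeds < 1 | ef$seeds > cfg$n_seeds)) {
      stop("power effect references seeds outside 1..n_seeds", call. = FALSE)
    }
    if (!ef$group %in% c("mtbi", "control")) {
      stop("power effect group must be 'mtbi' or 'control'", call. = FALSE)
    }
  }
  for (ef in cfg$coupling_effects) {
    if (!ef$band %in% bands) {
      stop("coupling effect references band '", ef$band,
           "' not in the configured band set", call. = FALSE)
    }
    if (abs(ef$shift) >= 1) {
      stop("target AEC shift must lie in (-1, 1)", call. = FALSE)
    }
    ed <- ef$edges
    if (!is.matrix(ed) || ncol(ed) != 2 ||
        any(ed < 1 | ed > cfg$n_seeds) || any(ed[, 1] == ed[, 2])) {
      stop("coupling edges must be a 2-column matrix of distinct seed indices",
           call. = FALSE)
    }
    if (anyDuplicated(as.vector(ed))) {
      stop("coupling edges within one band must be pairwise disjoint ",
           "(no shared endpoints); the envelope-sharing calibration assumes it",
           call. = FALSE)
    }
  }
  # total Nyquist check for the configured bands
  for (b in bands) {
    if (band_limits(b)[2] > cfg$sampling_rate / 2) {
      stop("band '", b, "' exceeds the Nyquist frequency at ",
           cfg$sampling_rate, " Hz; drop it from band_amplitudes",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Turn off all planted effects
#'
#' Convenience for null-calibration studies: identical signal-generating
#' distributions in the two groups (metadata covariates stay
#' group-dependent unless `null_covariates = TRUE`).
#'
#' @param config A `synthetic_config`.
#' @param null_covariates If TRUE, both groups also share the control
#'   covariate distributions.
#' @return The modified config.
#' @export
null_config <- function(config, null_covariates = FALSE) {
  config$power_effects <- list()
  config$coupling_effects <- list()
  if (null_covariates) {
    config$covariate_model$age$mtbi <- config$covariate_model$age$control
    config$covariate_model$head_motion$mtbi <-
      config$covariate_model$head_motion$control
    config$covariate_model$sex_p_male["mtbi"] <-
      config$covariate_model$sex_p_male[["control"]]
  }
  config
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

rlnorm_ms <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject metadata (group, age, sex, head motion) from the
#' configured distributions and assigns each subject an RNG substream so the
#' source signals are reproducible subject-by-subject. Source time series
#' are generated lazily by [generate_source_signals()] /
#' [cohort_source_signals()] — a full-scale cohort does not fit in memory at
#' once, and downstream analyses stream subjects.
#'
#' @param config A [synthetic_config()].
#' @param source_model A `source_model` with `config$n_seeds` seeds
#'   (default: [default_source_model()]).
#' @return An object of class `meg_cohort`: list with `metadata`
#'   (data.frame: subject_id, group, age, sex, head_motion, subject_seed),
#'   `config`, `source_model`.
#' @export
generate_cohort <- function(config, source_model = NULL) {
  validate_synthetic_config(config)
  if (is.null(source_model)) source_model <- default_source_model(config$n_seeds)
  validate_source_model(source_model)
  if (nrow(source_model) != config$n_seeds) {
    stop("source_model has ", nrow(source_model), " seeds but config says ",
         config$n_seeds, call. = FALSE)
  }
  set.seed(config$seed)
  cm <- config$covariate_model
  groups <- c(rep("mtbi", config$n_per_group[["mtbi"]]),
              rep("control", config$n_per_group[["control"]]))
  n <- length(groups)
  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups, stringsAsFactors = FALSE
  )
  meta$age <- NA_real_
  meta$sex <- NA_character_
  meta$head_motion <- NA_real_
  for (g in c("mtbi", "control")) {
    i <- which(groups == g)
    a <- cm$age[[g]]
    meta$age[i] <- rtruncnorm1(length(i), a[["mean"]], a[["sd"]],
                               cm$age$range[1], cm$age$range[2])
    h <- cm$head_motion[[g]]
    meta$head_motion[i] <- rlnorm_ms(length(i), h[["mean"]], h[["sd"]])
    meta$sex[i] <- ifelse(rbinom(length(i), 1, cm$sex_p_male[[g]]) == 1,
                          "m", "f")
  }
  meta$subject_seed <- sample.int(.Machine$integer.max - 1L, n)
  structure(list(metadata = meta, config = config,
                 source_model = source_model),
            class = "meg_cohort")
}

#' @export
print.meg_cohort <- function(x, ...) {
  tb <- table(x$metadata$group)
  cat("<meg_cohort>", nrow(x$metadata), "subjects (",
      paste(names(tb), tb, collapse = ", "), ");", x$config$n_seeds,
      "seeds;", x$config$duration, "s @", x$config$sampling_rate, "Hz\n")
  invisible(x)
}

# linear interpolation of a coarse-grid matrix (time in rows) to the fine
# grid; both grids are regular, so all columns share the same weights
interp_cols <- function(m, t_coarse, t_fine) {
  dt <- t_coarse[2] - t_coarse[1]
  pos <- (t_fine - t_coarse[1]) / dt
  i0 <- pmin(pmax(floor(pos), 0), length(t_coarse) - 2)
  frac <- pmin(pmax(pos - i0, 0), 1)
  n <- length(t_fine)
  L <- n / (length(t_coarse) - 1)
  if (abs(L - round(L)) < 1e-9 &&
      all(i0 == rep(seq_len(length(t_coarse) - 1) - 1, each = round(L))[seq_len(n)])) {
    # regular block structure: build via outer products (fast path)
    L <- round(L)
    nb <- n / L
    f <- frac[seq_len(L)]
    a1 <- (1 - f) %o% m[seq_len(nb), , drop = FALSE]
    a2 <- f %o% m[seq_len(nb) + 1, , drop = FALSE]
    return(matrix(a1 + a2, n, ncol(m)))
  }
  m[i0 + 1, , drop = FALSE] * (1 - frac) + m[i0 + 2, , drop = FALSE] * frac
}

#' Generate the continuous source signals of one subject
#'
#' Each seed's signal is a sum over the configured bands of a band-limited
#' carrier (4th-order Butterworth band-passed Gaussian noise, unit RMS)
#' multiplied by a slow positive envelope (rectified low-pass Gaussian plus
#' offset). Planted power effects scale the band amplitude for the matching
#' group; planted coupling induces a shared envelope component between edge
#' endpoints with a mixing weight calibrated against the measured AEC
#' (see [aec_planting_rho()]).
#'
#' @param config A [synthetic_config()].
#' @param subject One row of a cohort's `metadata` (needs `group` and
#'   `subject_seed`).
#' @return `n_seeds x n_samples` matrix with attributes `sampling_rate` and
#'   `subject_id`.
#' @export
generate_source_signals <- function(config, subject) {
  stopifnot(all(c("group", "subject_seed") %in% names(subject)))
  set.seed(subject$subject_seed)
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  ns <- config$n_seeds
  env_rate <- 4  # envelope dynamics live below envelope_cutoff << 2 Hz
  ne <- ceiling(config$duration * env_rate) + 1
  t_coarse <- (seq_len(ne) - 1) / env_rate
  t_fine <- (seq_len(n) - 1) / fs
  lp <- signal::butter(2, config$envelope_cutoff / (env_rate / 2), "low")
  acc <- matrix(0, n, ns)
  for (b in names(config$band_amplitudes)) {
    lim <- band_limits(b)
    bp <- signal::butter(4, lim / (fs / 2), "pass")
    carriers <- filter_ba(bp, matrix(rnorm(n * ns), n, ns))
    csd <- sqrt((colSums(carriers^2) - n * colMeans(carriers)^2) / (n - 1))
    g <- unit_sd_cols(filter_ba(lp, matrix(rnorm(ne * ns), ne, ns)))
    # envelope coupling: mix a shared low-pass component into both endpoints
    for (ef in config$coupling_effects) {
      if (ef$band != b) next
      target <- if (ef$shift < 0) {
        if (subject$group == "control") -ef$shift else 0
      } else {
        if (subject$group == "mtbi") ef$shift else 0
      }
      # compensate the leakage-correction shrinkage the measurement applies
      target <- min(target / aec_orth_attenuation(b, ns), 0.999)
      rho <- aec_planting_rho(target, b)
      alpha <- sqrt(rho)
      for (k in seq_len(nrow(ef$edges))) {
        s_shared <- filter_ba(lp, rnorm(ne))
        s_shared <- s_shared / sd(s_shared)
        for (seed in ef$edges[k, ]) {
          g[, seed] <- sqrt(1 - alpha^2) * g[, seed] + alpha * s_shared
        }
      }
    }
    env <- abs(interp_cols(g, t_coarse, t_fine)) + config$envelope_offset
    amp <- rep(config$band_amplitudes[[b]], ns)
    for (ef in config$power_effects) {
      if (ef$band == b && subject$group == ef$group) {
        amp[ef$seeds] <- amp[ef$seeds] * ef$factor
      }
    }
    # fold unit-RMS normalization and band amplitude into one column scale
    acc <- acc + carriers * env * rep(amp / csd, each = n)
  }
  X <- t(acc)
  attr(X, "sampling_rate") <- fs
  attr(X, "subject_id") <- subject$subject_id
  X
}

#' Source signals of the i-th cohort subject
#' @param cohort A `meg_cohort`.
#' @param i Subject index into `cohort$metadata`.
#' @return See [generate_source_signals()].
#' @export
cohort_source_signals <- function(cohort, i) {
  generate_source_signals(cohort$config, cohort$metadata[i, ])
}
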