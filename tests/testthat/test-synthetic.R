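# Synthetic cohort generator: determinism, covariate distributions,
# planted-effect calibration, geometry and artifact plumbing.

test_that("cohorts are bit-identical given the same config and seed", {
  cfg <- tiny_config()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(cohort_source_signals(c1, 3), cohort_source_signals(c2, 3))
  cfg2 <- tiny_config(seed = 102)
  expect_false(identical(generate_cohort(cfg2)$metadata$age, c1$metadata$age))
})

test_that("metadata covariates follow the configured group distributions", {
  cfg <- tiny_config(n_mtbi = 300, n_control = 300)
  md <- generate_cohort(cfg)$metadata
  expect_equal(sum(md$group == "mtbi"), 300)
  cm <- cfg$covariate_model
  for (g in c("mtbi", "control")) {
    a <- md$age[md$group == g]
    expect_true(all(a >= 6 & a <= 18))
    expect_equal(mean(a), cm$age[[g]][["mean"]], tolerance = 0.05)
    h <- md$head_motion[md$group == g]
    expect_true(all(h >= 0))
    expect_equal(mean(h), cm$head_motion[[g]][["mean"]], tolerance = 0.15)
  }
})

test_that("default full-scale config reproduces the emulated motion contrast", {
  cfg <- synthetic_config(seed = 1)
  md <- generate_cohort(cfg)$metadata
  expect_equal(nrow(md), 36)
  expect_equal(sum(md$group == "mtbi"), 16)
  # group-wise sample means approximate 1.83 and 0.64 mm (small-n spread)
  expect_equal(mean(md$head_motion[md$group == "mtbi"]), 1.83,
               tolerance = 0.5)
  expect_equal(mean(md$head_motion[md$group == "control"]), 0.64,
               tolerance = 0.35)
  expect_gt(mean(md$head_motion[md$group == "mtbi"]),
            mean(md$head_motion[md$group == "control"]))
})

test_that("with no planted effects the groups share one generating law", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  # swap a subject's group: identical signal given the same subject seed
  s <- coh$metadata[1, ]
  x1 <- generate_source_signals(cfg, s)
  s$group <- "control"
  x2 <- generate_source_signals(cfg, s)
  expect_identical(x1, x2)
})

test_that("config validation rejects inconsistent effect specs", {
  sm <- tiny_source_model(10)
  expect_error(synthetic_config(n_seeds = 10,
    band_amplitudes = c(delta = 1),
    power_effects = list(list(band = "ripple", seeds = 1, group = "mtbi",
                              factor = 1.5)),
    coupling_effects = list()), "band")
  expect_error(synthetic_config(n_seeds = 10,
    band_amplitudes = c(delta = 1), power_effects = list(),
    coupling_effects = list(list(band = "delta",
                                 edges = cbind(1, 11), shift = -0.1))),
    "edges")
  expect_error(synthetic_config(n_seeds = 10,
    band_amplitudes = c(delta = 1),
    power_effects = list(list(band = "delta", seeds = 1, group = "mtbi",
                              factor = -2)),
    coupling_effects = list()), "factor")
  # band above Nyquist at a low sampling rate
  expect_error(synthetic_config(sampling_rate = 100,
    band_amplitudes = c(delta = 1, hgamma = 0.2)), "Nyquist")
})

test_that("planted amplitude factor follows the square law in band power", {
  sm <- tiny_source_model(8)
  cfg <- synthetic_config(
    n_per_group = c(mtbi = 10, control = 10), sampling_rate = 200,
    duration = 60, n_seeds = 8,
    band_amplitudes = c(delta = 1, alpha = 1.1),
    power_effects = list(list(band = "delta", seeds = 1:4, group = "mtbi",
                              factor = 1.5)),
    coupling_effects = list(), seed = 33)
  m <- measure_cohort(generate_cohort(cfg, sm), bands = c("delta", "alpha"),
                      connectivity = FALSE, zscore = FALSE)
  g <- m$metadata$group
  ratio <- mean(m$band_power[g == "mtbi", 1:4, "delta"]) /
    mean(m$band_power[g == "control", 1:4, "delta"])
  expect_equal(ratio, 2.25, tolerance = 0.05 * 2.25)
  # untouched band and seeds unaffected
  r_alpha <- mean(m$band_power[g == "mtbi", 1:4, "alpha"]) /
    mean(m$band_power[g == "control", 1:4, "alpha"])
  expect_equal(r_alpha, 1, tolerance = 0.1)
})

test_that("envelope mixing maps monotonically onto measured AEC", {
  # mixing 0 -> AEC ~ 0; mixing 1 (identical envelopes) -> large AEC;
  # calibrated planting hits its target through the measurement pipeline
  fs <- 600
  spe <- 10 * fs
  n_pairs <- 4
  n <- spe * 12
  set.seed(42)
  lp <- signal::butter(2, 0.25 / 2, "low")
  ne <- ceiling(n / fs * 4) + 1
  bp <- signal::butter(4, c(8, 14) / (fs / 2), "pass")
  # paired design: the same envelope precursors and carriers are reused at
  # every mixing level, so the rho comparison is free of between-pair
  # sampling variance
  draws <- lapply(seq_len(n_pairs), function(i) {
    list(g = megconn:::unit_sd_cols(
           megconn:::filter_ba(lp, matrix(rnorm(ne * 3), ne, 3))),
         carr = megconn:::unit_sd_cols(
           megconn:::filter_ba(bp, matrix(rnorm(n * 2), n, 2))))
  })
  measure <- function(rho) {
    al <- sqrt(rho)
    mean(vapply(draws, function(d) {
      g1 <- sqrt(1 - al^2) * d$g[, 1] + al * d$g[, 3]
      g2 <- sqrt(1 - al^2) * d$g[, 2] + al * d$g[, 3]
      env <- abs(megconn:::interp_cols(cbind(g1, g2), (seq_len(ne) - 1) / 4,
                                       (seq_len(n) - 1) / fs)) + 0.5
      se <- epoch_sources(t(d$carr * env), 10, sampling_rate = fs)
      mean(vapply(seq_len(megconn:::n_epochs(se)), function(e) {
        env2 <- hilbert_envelope(fir_bandpass(matrix(se$data[, , e], 2),
                                              "alpha", fs))
        aec_matrix(downsample_envelope(env2, fs, 1))[1, 2]
      }, numeric(1)))
    }, numeric(1)))
  }
  a0 <- measure(0)
  a5 <- measure(0.5)
  a1 <- measure(0.9999)
  expect_lt(abs(a0), 0.12)
  expect_gt(a5, a0 + 0.04)
  expect_gt(a1, a5)
  expect_gt(a1, 0.5)
})

test_that("seed geometry is valid and sensors sit outside the sphere", {
  hm <- default_head_model()
  sm <- default_source_model()
  expect_equal(nrow(sm), 90)
  expect_equal(nrow(hm$sensor_positions), 151)
  expect_setequal(unique(sm$hemisphere), c("L", "R"))
  expect_true(all(table(sm$lobe) > 0))
  d <- sqrt(rowSums(megconn:::seed_positions(sm)^2))
  expect_true(all(d < hm$sphere_radius))
  expect_true(all(sqrt(rowSums(hm$sensor_positions^2)) > hm$sphere_radius))
  # orientations tangential: orthogonal to the radial direction
  ors <- megconn:::seed_orientations(sm, hm)
  rad <- megconn:::seed_positions(sm) / d
  expect_lt(max(abs(rowSums(ors * rad))), 1e-10)
})

test_that("sensor projection is linear and attaches geometry", {
  sm <- tiny_source_model(6)
  hm <- default_head_model(40)
  fs <- 100
  X <- matrix(0, 6, fs * 5)
  X[2, ] <- sin(2 * pi * 7 * (seq_len(fs * 5) - 1) / fs)
  attr(X, "sampling_rate") <- fs
  rec <- project_to_sensors(X, sm, hm, sensor_noise_sd = 0)
  # rank-1 mixing: every channel proportional to the single source
  cc <- suppressWarnings(cor(t(rec$data), X[2, ]))
  live <- which(apply(rec$data, 1, sd) > 1e-9)
  expect_true(all(abs(cc[live]) > 1 - 1e-8))
  # doubling the source doubles the field
  rec2 <- project_to_sensors(X * 2, sm, hm, sensor_noise_sd = 0)
  expect_equal(rec2$data, rec$data * 2, tolerance = 1e-12)
  # two orthogonal sources -> sensor covariance rank exactly 2
  X2 <- matrix(0, 6, fs * 5)
  t <- (seq_len(fs * 5) - 1) / fs
  X2[1, ] <- sin(2 * pi * 5 * t)
  X2[4, ] <- cos(2 * pi * 10 * t)
  attr(X2, "sampling_rate") <- fs
  rec3 <- project_to_sensors(X2, sm, hm, sensor_noise_sd = 0)
  ev <- eigen(tcrossprod(rec3$data), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[2], 1e-6 * ev[1])
  expect_lt(ev[3], 1e-10 * ev[1])
})

test_that("artifact injection is identity at zero amplitudes and truthful", {
  sm <- tiny_source_model(4)
  hm <- default_head_model(30)
  fs <- 150
  set.seed(9)
  X <- matrix(rnorm(4 * fs * 25), 4)
  attr(X, "sampling_rate") <- fs
  rec <- project_to_sensors(X, sm, hm, sensor_noise_sd = 5)
  am0 <- default_artifact_model()
  am0$ocular_amplitude <- 0
  am0$cardiac_amplitude <- 0
  am0$excursion_prob <- 0
  am0$jump_prob <- 0
  expect_identical(inject_artifacts(rec, am0, seed = 2)$data, rec$data)
  am <- default_artifact_model()
  am$jump_prob <- 1
  dirty <- inject_artifacts(rec, am, seed = 2)
  truth <- attr(dirty, "artifacts")
  expect_true(nrow(truth$jumps) >= 1)
  expect_equal(length(truth$ocular_course), ncol(rec$data))
  # a jump appears as a first-difference spike at the injected sample
  j <- truth$jumps[1, ]
  expect_gt(abs(diff(dirty$data[j$channel, (j$sample - 1):j$sample])),
            0.9 * abs(j$amplitude))
})
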