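# AEC pipeline: FIR filtering, symmetric orthogonalization, Hilbert
# envelopes, downsampling, correlation and leakage suppression.

test_that("two-pass FIR matches its own transfer function oracle", {
  fs <- 600
  t <- (seq_len(fs * 20) - 1) / fs
  ctr <- (fs * 5):(fs * 15)
  k <- megconn:::fir_twopass_kernel("alpha", fs)
  H <- function(f) abs(sum(k$kernel * exp(-2i * pi * f / fs *
                                            (seq_along(k$kernel) - 1))))
  # in-band sinusoid: amplitude within 5%, zero phase shift
  x <- matrix(sin(2 * pi * 10 * t), 1)
  y <- fir_bandpass(x, "alpha", fs)
  gain <- sd(y[ctr]) / sd(x[ctr])
  expect_equal(gain, 1, tolerance = 0.05)
  expect_equal(gain, H(10), tolerance = 1e-3)
  expect_gt(cor(y[1, ctr], x[1, ctr]), 0.999)   # zero phase
  # an octave away: > 20 dB down, matching the oracle
  x2 <- matrix(sin(2 * pi * 20 * t), 1)
  y2 <- fir_bandpass(x2, "alpha", fs)
  g2 <- sd(y2[ctr]) / sd(x2[ctr])
  expect_lt(g2, 10^(-20 / 20))
  expect_equal(g2, H(20), tolerance = max(0.05 * H(20), 1e-4))
  expect_equal(fir_bandpass(matrix(0, 2, 1000), "alpha", fs),
               matrix(0, 2, 1000))
  expect_error(fir_bandpass(x, c(100, 400), fs), "Nyquist")
})

test_that("symmetric orthogonalization meets its contracts", {
  set.seed(20)
  # random input: exactly orthogonal rows, non-increasing objective
  X <- matrix(rnorm(6 * 3000), 6)
  Y <- orthogonalize_symmetric(X)
  G <- tcrossprod(Y)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
  expect_true(all(diff(attr(Y, "objective_trace")) <= 1e-12))
  # duplicated rows forced apart to zero-lag correlation 0
  x <- rnorm(2000)
  Xd <- rbind(x, x)
  Yd <- orthogonalize_symmetric(Xd)
  expect_lt(abs(sum(Yd[1, ] * Yd[2, ])), 1e-10)
  # already orthogonal input is a fixed point
  Q <- qr.Q(qr(matrix(rnorm(2000 * 3), ncol = 3)))
  Xo <- t(Q %*% diag(c(2, 3, 1.5)))
  Yo <- orthogonalize_symmetric(Xo)
  expect_equal(Yo[, ], Xo[, ], tolerance = 1e-8)
  # all-zero row is degenerate
  expect_error(orthogonalize_symmetric(rbind(rnorm(100), 0)), "zero")
  expect_error(orthogonalize_symmetric(matrix(rnorm(12), 4, 3)), "samples")
})

test_that("orthogonalization matches a high-precision independent run", {
  set.seed(21)
  X <- matrix(rnorm(4 * 2000), 4)
  Y <- orthogonalize_symmetric(X)
  # independent implementation: full-space polar iteration, tighter tol
  oracle <- function(X, iters = 3000) {
    d <- rep(1, nrow(X))
    O <- NULL
    for (i in seq_len(iters)) {
      s <- svd(X * d)
      O <- s$u %*% t(s$v)
      d <- rowSums(X * O)
    }
    d * O
  }
  Yo <- oracle(X)
  expect_equal(sum((X - Y)^2), sum((X - Yo)^2), tolerance = 1e-6)
  expect_equal(Y[, ], Yo, tolerance = 1e-4)
})

test_that("Hilbert envelope recovers amplitudes and modulators", {
  fs <- 200
  t <- (seq_len(fs * 10) - 1) / fs
  ctr <- round(length(t) * 0.1):round(length(t) * 0.9)
  env <- hilbert_envelope(matrix(3 * sin(2 * pi * 10 * t), 1))
  expect_equal(max(abs(env[ctr] - 3)) / 3, 0, tolerance = 0.02)
  mod <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env2 <- hilbert_envelope(matrix(mod * sin(2 * pi * 20 * t), 1))
  expect_gte(cor(env2[ctr], mod[ctr]), 0.99)
  expect_equal(hilbert_envelope(matrix(0, 2, 100)), matrix(0, 2, 100))
})

test_that("envelope downsampling is the block mean", {
  expect_equal(ncol(downsample_envelope(matrix(1, 2, 6000), 600)), 10)
  expect_equal(downsample_envelope(matrix(7, 3, 500), 100), matrix(7, 3, 5))
  ramp <- matrix(seq_len(1000), 1)
  d <- downsample_envelope(ramp, 100)
  expect_equal(as.numeric(d), 100 * (0:9) + 50.5)   # window-centre means
  expect_error(downsample_envelope(matrix(1, 1, 150), 100), "integer")
})

test_that("AEC equals brute-force Pearson and handles edge cases", {
  set.seed(22)
  env <- matrix(abs(rnorm(5 * 20)) + 0.2, 5)
  A <- aec_matrix(env)
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(A[i, j], pearson(env[i, ], env[j, ]), tolerance = 1e-12)
  }
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 5))
  # identical pair -> 1; anti-phase modulators -> -1
  tt <- seq(0, 9, by = 0.5)
  e2 <- rbind(2 + sin(tt), 2 + sin(tt), 2 - sin(tt))
  A2 <- aec_matrix(e2)
  expect_equal(A2[1, 2], 1)
  expect_equal(A2[1, 3], -1)
  expect_warning(aec_matrix(rbind(rnorm(10), 1)), "constant")
  expect_error(aec_matrix(matrix(1, 2, 2)), "3 samples")
})

test_that("static AEC averages per-epoch matrices", {
  M <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(static_aec(list(M, -M)), matrix(0, 2, 2))
  expect_equal(static_aec(list(M)), M)
  expect_equal(static_aec(list(M, 3 * M)), 2 * M)
})

test_that("orthogonalization suppresses zero-lag leakage in AEC", {
  # instantaneously mixed (leaky) sources with independent envelopes:
  # corrected |AEC| ~ 0 and far below the uncorrected value
  set.seed(23)
  fs <- 600
  n_ep <- 24
  n <- fs * 10 * n_ep
  ne <- ceiling(n / fs * 4) + 1
  lp <- signal::butter(2, 0.25 / 2, "low")
  bp <- signal::butter(4, c(8, 14) / (fs / 2), "pass")
  k <- 4
  carr <- megconn:::unit_sd_cols(megconn:::filter_ba(bp, matrix(rnorm(n * k), n, k)))
  g <- megconn:::unit_sd_cols(megconn:::filter_ba(lp, matrix(rnorm(ne * k), ne, k)))
  env <- abs(megconn:::interp_cols(g, (seq_len(ne) - 1) / 4,
                                   (seq_len(n) - 1) / fs)) + 0.5
  S <- t(carr * env)
  mix <- diag(k) + matrix(0.35, k, k) - 0.35 * diag(k)  # zero-lag leakage
  se <- epoch_sources(mix %*% S, 10, sampling_rate = fs)
  raw <- connectivity_aec(se, "alpha", orthogonalize = FALSE)
  cor_ <- connectivity_aec(se, "alpha", orthogonalize = TRUE)
  off <- upper.tri(raw)
  expect_gt(mean(abs(raw[off])), 3 * mean(abs(cor_[off])))
  # null level of |mean of n_ep 10-sample correlations| is ~ 0.8/sqrt(10*n_ep)
  expect_lt(mean(abs(cor_[off])), 2 * 0.8 / sqrt(10 * n_ep))
})

test_that("orthogonalizing after the envelope would change the result", {
  # regression guard on the pipeline order (filter -> orthogonalize ->
  # envelope): envelopes of orthogonalized series differ from
  # orthogonalized envelopes
  set.seed(24)
  fs <- 200
  X <- matrix(rnorm(3 * fs * 10), 3)
  Xf <- fir_bandpass(X, "alpha", fs)
  a <- hilbert_envelope(orthogonalize_symmetric(Xf))
  b <- orthogonalize_symmetric(hilbert_envelope(Xf))
  expect_gt(max(abs(a - b)), 0.01)
})

test_that("subject-level connectome is symmetric with values in range", {
  set.seed(25)
  cfg <- tiny_config(n_mtbi = 1, n_control = 1, duration = 30)
  coh <- generate_cohort(cfg)
  se <- epoch_sources(cohort_source_signals(coh, 1), 10)
  A <- connectivity_aec(se, "alpha")
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_true(all(abs(A) <= 1))
  expect_equal(attr(A, "n_epochs"), 3)
})
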