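# Shared fixtures: small deterministic objects used across test files.

tiny_source_model <- function(n = 10) default_source_model(n)

# small, fast synthetic config (subset of canonical bands below Nyquist)
tiny_config <- function(n_mtbi = 4, n_control = 4, fs = 200, duration = 30,
                        n_seeds = 10, seed = 101, ...) {
  synthetic_config(
    n_per_group = c(mtbi = n_mtbi, control = n_control),
    sampling_rate = fs, duration = duration, n_seeds = n_seeds,
    band_amplitudes = c(delta = 1, theta = 0.9, alpha = 1.1),
    power_effects = list(), coupling_effects = list(), seed = seed, ...)
}

# deterministic covariate table with group-dependent motion
toy_covars <- function(n1 = 8, n2 = 10, seed = 7) {
  set.seed(seed)
  data.frame(
    group = rep(c("mtbi", "control"), c(n1, n2)),
    age = round(runif(n1 + n2, 7, 17), 1),
    head_motion = abs(rnorm(n1 + n2, rep(c(1.8, 0.6), c(n1, n2)), 0.4))
  )
}

# explicit least-squares ANCOVA oracle via normal equations
ancova_f_oracle <- function(y, covars) {
  g <- as.numeric(covars$group == "mtbi")
  Xf <- cbind(1, g, covars$age, covars$head_motion)
  Xr <- cbind(1, covars$age, covars$head_motion)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  n <- length(y)
  ((rss(Xr) - rss(Xf)) / 1) / (rss(Xf) / (n - 4))
}

# brute-force BH step-up oracle
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  list(p_fdr = adj, significant = adj < q)
}

# exhaustive pair-counting Mann-Whitney U oracle (first factor level)
u_oracle <- function(y, group) {
  group <- as.factor(group)
  a <- y[group == levels(group)[1]]
  b <- y[group == levels(group)[2]]
  sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), 1))
}
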