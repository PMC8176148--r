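# Covariate-adjusted permutation statistics: ANCOVA F, Freedman-Lane
# permutations, BH-FDR and the Wilcoxon rank-sum.

test_that("ANCOVA F matches the explicit least-squares oracle", {
  set.seed(40)
  cov8 <- data.frame(group = rep(c("mtbi", "control"), each = 4),
                     age = c(8, 12, 10, 15, 9, 13, 11, 16),
                     head_motion = c(2.1, 1.2, 0.8, 1.9, 0.5, 0.6, 0.7, 0.4))
  y <- c(3.2, 2.8, 3.9, 3.1, 2.2, 2.0, 2.4, 2.6)
  expect_equal(ancova_f(y, cov8), ancova_f_oracle(y, cov8), tolerance = 1e-10)
  cv <- toy_covars()
  for (i in 1:5) {
    y2 <- rnorm(nrow(cv)) + 0.5 * cv$age + (cv$group == "mtbi")
    expect_equal(ancova_f(y2, cv), ancova_f_oracle(y2, cv), tolerance = 1e-10)
  }
  # y an exact linear function of the covariates alone -> F ~ 0
  y3 <- 1 + 0.2 * cv$age - 0.3 * cv$head_motion
  expect_lt(ancova_f(y3, cv), 1e-16)
})

test_that("without covariate effects F reduces to the squared pooled t", {
  set.seed(41)
  n1 <- 9; n2 <- 11
  cv <- data.frame(group = rep(c("mtbi", "control"), c(n1, n2)),
                   age = rnorm(n1 + n2), head_motion = rnorm(n1 + n2))
  y <- rnorm(n1 + n2) + 0.8 * (cv$group == "mtbi")
  # oracle: direct regression with the two extra (useless) covariates
  expect_equal(ancova_f(y, cv), ancova_f_oracle(y, cv), tolerance = 1e-10)
  # and close to the classical squared t when covariates explain nothing
  tt <- t.test(y[cv$group == "mtbi"], y[cv$group == "control"],
               var.equal = TRUE)$statistic
  expect_equal(ancova_f(y, cv), as.numeric(tt)^2, tolerance = 0.25)
})

test_that("permutation p-values honour the add-one floor and degeneracy", {
  cv <- toy_covars()
  n <- nrow(cv)
  set.seed(42)
  # huge group effect: observed F above every permuted F
  y <- matrix(10 * (cv$group == "mtbi") + rnorm(n, sd = 0.1))
  pr <- permutation_pvalues(y, cv, n_perm = 500, seed = 3)
  expect_equal(pr$p_perm, 1 / 501)
  expect_equal(pr$direction, 1)
  # constant y -> p = 1
  pc <- permutation_pvalues(matrix(rep(1, n)), cv, n_perm = 100, seed = 3)
  expect_equal(pc$p_perm, 1)
  # reproducible bit-for-bit from the seed, never zero
  pr2 <- permutation_pvalues(y, cv, n_perm = 500, seed = 3)
  expect_identical(pr$p_perm, pr2$p_perm)
})

test_that("null permutation p-values are uniform", {
  set.seed(43)
  cv <- toy_covars(10, 10)
  Y <- matrix(rnorm(20 * 300), 20)
  pr <- permutation_pvalues(Y, cv, n_perm = 400, seed = 9)
  ks <- suppressWarnings(stats::ks.test(pr$p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pr$p_perm > 0 & pr$p_perm <= 1))
})

test_that("vectorized permutation F agrees with per-unit recomputation", {
  set.seed(44)
  cv <- toy_covars(6, 7)
  Y <- matrix(rnorm(13 * 4), 13)
  pr <- permutation_pvalues(Y, cv, n_perm = 50, seed = 5)
  F_direct <- apply(Y, 2, ancova_f, covars = cv)
  expect_equal(pr$F_obs, F_direct, tolerance = 1e-10)
})

test_that("BH-FDR equals the brute-force step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  r <- bh_fdr(p)
  o <- bh_oracle(p)
  expect_equal(r$p_fdr, o$p_fdr)
  expect_true(all(r$significant))
  expect_false(any(bh_fdr(rep(1, 10))$significant))
  r1 <- bh_fdr(0.01)
  expect_equal(r1$p_fdr, 0.01)
  expect_true(r1$significant)
  set.seed(45)
  pr <- runif(200)^2
  expect_equal(bh_fdr(pr)$p_fdr, bh_oracle(pr)$p_fdr, tolerance = 1e-12)
  # invariant under reordering of units
  o2 <- sample(200)
  expect_equal(bh_fdr(pr[o2])$p_fdr, bh_oracle(pr)$p_fdr[o2])
})

test_that("Wilcoxon rank-sum matches the pair-counting oracle", {
  set.seed(46)
  y <- c(rnorm(10), rnorm(12, 1))
  g <- rep(c("a", "b"), c(10, 12))
  w <- wilcoxon_ranksum(y, g)
  expect_equal(w[["U"]], u_oracle(y, g))
  # completely separated groups: U = 0 for the lower group
  y2 <- c(1:5, 11:18)
  g2 <- rep(c("a", "b"), c(5, 8))
  expect_equal(wilcoxon_ranksum(y2, g2)[["U"]], 0)
  # identical pooled values: z = 0 after tie correction
  w3 <- wilcoxon_ranksum(rep(3, 10), rep(c("a", "b"), 5))
  expect_equal(w3[["z"]], 0)
  expect_equal(w3[["p"]], 1)
  # ties handled like the oracle
  y4 <- c(1, 2, 2, 3, 3, 3, 4)
  g4 <- c("a", "a", "b", "a", "b", "b", "b")
  expect_equal(wilcoxon_ranksum(y4, g4)[["U"]], u_oracle(y4, g4))
  expect_error(wilcoxon_ranksum(1:3, rep("a", 3)), "two")
})

test_that("connectome contrasts vectorize 90 seeds into 4005 edges", {
  expect_equal(nrow(edge_table(90)), 4005)
  set.seed(47)
  cv <- toy_covars(5, 6)
  conn <- list(delta = array(rnorm(11 * 6 * 6), c(11, 6, 6)))
  for (s in 1:11) {
    m <- conn$delta[s, , ]
    conn$delta[s, , ] <- (m + t(m)) / 2
  }
  maps <- contrast_connectivity(conn, cv, n_perm = 50, seed = 1)
  expect_equal(nrow(maps$delta), 15)
  expect_true(all(maps$delta$p_perm > 0 & maps$delta$p_perm <= 1))
  expect_true(all(maps$delta$significant == (maps$delta$p_fdr < 0.05)))
})

test_that("covariate adjustment controls motion confounding", {
  # motion strongly group-dependent and y driven by motion only: the naive
  # two-sample test sees an effect, the ANCOVA does not
  set.seed(48)
  n1 <- 14; n2 <- 14
  hits_naive <- 0
  hits_ancova <- 0
  for (r in 1:30) {
    cv <- data.frame(group = rep(c("mtbi", "control"), c(n1, n2)),
                     age = runif(n1 + n2, 7, 17),
                     head_motion = abs(rnorm(n1 + n2,
                                             rep(c(2.2, 0.6), c(n1, n2)), 0.3)))
    y <- 2 * cv$head_motion + rnorm(n1 + n2, sd = 0.5)
    p_naive <- t.test(y[cv$group == "mtbi"], y[cv$group == "control"])$p.value
    pr <- permutation_pvalues(matrix(y), cv, n_perm = 200, seed = r)
    hits_naive <- hits_naive + (p_naive < 0.05)
    hits_ancova <- hits_ancova + (pr$p_perm < 0.05)
  }
  expect_gt(hits_naive, 20)     # heavily inflated
  expect_lt(hits_ancova, 7)     # near nominal
})

test_that("null cohorts stay clean after FDR and planted effects are found", {
  set.seed(49)
  cv <- toy_covars(10, 10)
  clean <- 0
  for (r in 1:20) {
    Y <- matrix(rnorm(20 * 30), 20)
    pr <- permutation_pvalues(Y, cv, n_perm = 300, seed = 100 + r)
    clean <- clean + (sum(bh_fdr(pr$p_perm)$significant) == 0)
  }
  expect_gte(clean, 18)
  # planted shift on 10 of 30 units is recovered with the right sign
  Y <- matrix(rnorm(20 * 30), 20)
  Y[cv$group == "mtbi", 1:10] <- Y[cv$group == "mtbi", 1:10] - 3.5
  pr <- permutation_pvalues(Y, cv, n_perm = 500, seed = 7)
  sig <- bh_fdr(pr$p_perm)$significant
  expect_gte(sum(sig[1:10]), 7)
  expect_true(all(pr$direction[1:10][sig[1:10]] == -1))
  expect_lte(sum(sig[11:30]), 2)
})
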