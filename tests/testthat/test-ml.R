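# Nested feature selection and classification: feature plumbing, rRF-FS,
# consensus thresholds, SVM/PLS-DA permutation tests, AUC and the leakage
# canary.

sep_data <- function(n1 = 18, n2 = 18, p_noise = 40, gap = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("control", "mtbi"), c(n1, n2)))
  X <- matrix(rnorm((n1 + n2) * (p_noise + 2)), n1 + n2)
  X[y == "mtbi", 1:2] <- X[y == "mtbi", 1:2] + gap
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(X = X, y = y)
}

test_that("feature building and edge indexing round-trip", {
  expect_equal(nrow(edge_table(90)), 4005)
  for (n in c(5, 12, 90)) {
    ed <- edge_table(n)
    expect_equal(nrow(ed), n * (n - 1) / 2)
    expect_equal(edge_index(ed$i, ed$j, n), ed$index)
    back <- index_edge(ed$index, n)
    expect_equal(unname(back[, 1]), ed$i)
    expect_equal(unname(back[, 2]), ed$j)
    # order-free
    expect_equal(edge_index(ed$j, ed$i, n), ed$index)
  }
  set.seed(50)
  conn <- list(delta = array(0, c(3, 5, 5)))
  for (s in 1:3) {
    m <- matrix(rnorm(25), 5)
    conn$delta[s, , ] <- m + t(m)
  }
  X <- build_features(conn, "delta")
  expect_equal(dim(X), c(3, 10))
  expect_identical(attr(X, "kind"), "connectivity")
  # values match the upper triangle through the index map
  for (e in 1:10) {
    ij <- index_edge(e, 5)
    expect_equal(unname(X[2, e]), conn$delta[2, ij[1], ij[2]])
  }
  bp <- array(rnorm(3 * 6 * 2), c(3, 6, 2),
              dimnames = list(NULL, paste0("s", 1:6), c("delta", "theta")))
  Xp <- build_features(bp, "theta")
  expect_equal(dim(Xp), c(3, 6))
  expect_identical(attr(Xp, "kind"), "power")
})

test_that("PCA separation check distinguishes separable from null labels", {
  d <- sep_data(gap = 4)
  expect_true(pca_separation_check(d$X, d$y))
  set.seed(51)
  expect_false(pca_separation_check(d$X, sample(d$y)))
  Xdup <- d$X
  Xdup[2, ] <- Xdup[1, ]
  expect_error(pca_separation_check(Xdup, d$y), "degenerate")
})

test_that("univariate filter keeps separating features, ~5% of null", {
  d <- sep_data(gap = 4)
  keep <- univariate_filter(d$X, d$y)
  expect_true(all(1:2 %in% keep))
  # constant feature dropped
  Xc <- cbind(d$X, const = 1)
  expect_false(ncol(Xc) %in% univariate_filter(Xc, d$y))
  # null retention rate ~ alpha
  set.seed(52)
  rates <- vapply(1:10, function(r) {
    Xn <- matrix(rnorm(30 * 200), 30)
    length(univariate_filter(Xn, factor(rep(c("a", "b"), 15)))) / 200
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("rRF-FS keeps a planted feature and prunes noise", {
  set.seed(53)
  n <- 30
  y <- factor(rep(c("a", "b"), each = 15))
  X <- matrix(rnorm(n * 101), n)
  X[y == "b", 1] <- X[y == "b", 1] + 4     # one perfectly separating feature
  colnames(X) <- paste0("f", 1:101)
  sel <- rrf_fs(X, y, seed = 2)
  expect_true(1 %in% sel)
  counts <- attr(sel, "survival_counts")
  expect_equal(counts[1], 10)
  # all-noise input: aggressive pruning on average
  Xn <- matrix(rnorm(n * 60), n)
  colnames(Xn) <- paste0("f", 1:60)
  seln <- rrf_fs(Xn, y, seed = 3)
  expect_lt(length(seln), 0.25 * 60)
  # guard clause below 2 features
  X2 <- X[, 1, drop = FALSE]
  expect_equal(as.integer(rrf_fs(X2, y, seed = 1)), 1L)
})

test_that("nested selection respects consensus thresholds and stratification", {
  d <- sep_data()
  sel <- nested_fs(d$X, d$y, k = 10, seed = 4, use_filter = TRUE)
  expect_equal(sel$threshold, 4)
  expect_true(all(sel$consensus_counts <= 10))
  expect_setequal(sel$consensus, which(sel$consensus_counts >= 4))
  expect_true(all(1:2 %in% sel$consensus))
  expect_gte(mean(sel$fold_accuracy), 0.9)
  selp <- nested_fs(d$X, d$y, k = 10, seed = 4, use_filter = FALSE)
  expect_equal(selp$threshold, 2)
  expect_setequal(selp$consensus, which(selp$consensus_counts >= 2))
  # every fold contains both classes
  for (f in 1:10) {
    expect_equal(length(unique(d$y[sel$folds == f])), 2)
  }
  expect_error(nested_fs(d$X[1:6, ], d$y[c(1, 2, 3, 19, 20, 21)], k = 6),
               "fold")
})

test_that("final SVM CV is accurate on separable and chance on null data", {
  d <- sep_data()
  rep1 <- final_svm(d$X[, 1:2], d$y, seed = 5)
  expect_gte(rep1$cv_accuracy_mean, 95)
  expect_true(rep1$training_accuracy >= 95)
  set.seed(55)
  accs <- vapply(1:5, function(r) {
    final_svm(d$X[, 3:6], sample(d$y), seed = r)$cv_accuracy_mean
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
  # identical feature values: majority-class accuracy
  Xc <- matrix(1, length(d$y), 1)
  repc <- final_svm(Xc, d$y, seed = 6)
  expect_equal(repc$cv_accuracy_mean, 50, tolerance = 10)
})

test_that("label permutation test has an add-one floor and null uniformity", {
  d <- sep_data()
  p <- label_permutation_test(d$X[, 1:2], d$y, n_perm = 30, seed = 7)
  expect_equal(as.numeric(p), 1 / 31)
  expect_error(label_permutation_test(d$X, d$y, n_perm = 0), "n_perm")
  # null: permutation p not systematically extreme
  set.seed(56)
  pn <- vapply(1:5, function(r) {
    yy <- sample(d$y)
    as.numeric(label_permutation_test(d$X[, 10:13], yy, n_perm = 60,
                                      seed = r))
  }, numeric(1))
  expect_gt(mean(pn), 0.2)
})

test_that("PLS-DA validation mirrors the SVM permutation contract", {
  d <- sep_data()
  p <- plsda_validate(d$X[, 1:4], d$y, n_perm = 30, seed = 8)
  expect_equal(as.numeric(p), 1 / 31)
  expect_gte(attr(p, "acc_obs"), 90)
  set.seed(57)
  pnull <- plsda_validate(d$X[, 10:13], sample(d$y), n_perm = 40, seed = 9)
  expect_gt(as.numeric(pnull), 0.05)
})

test_that("training ROC-AUC follows score ordering and tie conventions", {
  d <- sep_data()
  rep1 <- final_svm(d$X[, 1:2], d$y, seed = 10)
  expect_equal(training_roc_auc(rep1, d$X[, 1:2], d$y), 1, tolerance = 0.02)
  # random scores ~ 0.5
  set.seed(58)
  fake <- list(model = NULL)
  expect_equal(training_roc_auc(fake, d$X, d$y), 0.5)
  aucs <- replicate(20, {
    sc <- rnorm(length(d$y))
    as.numeric(pROC::auc(pROC::roc(d$y, sc, quiet = TRUE,
                                   direction = "<", levels = levels(d$y))))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.12)
})

test_that("model comparison ranks by CV accuracy with name tie-breaks", {
  r1 <- list(cv_accuracy_mean = 90, cv_accuracy_sd = 5, training_accuracy = 95)
  r2 <- list(cv_accuracy_mean = 97, cv_accuracy_sd = 4, training_accuracy = 100)
  r3 <- list(cv_accuracy_mean = 90, cv_accuracy_sd = 6, training_accuracy = 92)
  cmp <- compare_models(list(bpower = r1, aec = r2, apower = r3))
  expect_equal(cmp$model, c("aec", "apower", "bpower"))
  expect_equal(cmp$rank, 1:3)
})

test_that("the leakage canary does not raise CV accuracy", {
  d <- sep_data(gap = 1.2, p_noise = 20)
  chk <- leakage_canary_check(d$X, d$y, seed = 11)
  expect_true(as.logical(chk))
  expect_lte(attr(chk, "acc_canary"),
             attr(chk, "acc_base") + 100 / length(d$y) + 1e-9)
})

test_that("the full selection pipeline is reproducible from one seed", {
  d <- sep_data()
  s1 <- nested_fs(d$X, d$y, seed = 12)
  s2 <- nested_fs(d$X, d$y, seed = 12)
  expect_identical(s1$consensus, s2$consensus)
  expect_identical(s1$fold_accuracy, s2$fold_accuracy)
})
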