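# Nested feature-selection and classification: univariate rank-sum filter
# (gated by PCA separation, connectivity features only), recursive random-
# forest feature selection (rRF-FS), SVM with consensus features, PLS-DA
# generalizability check, and Ojala-Garriga label permutation tests.

#' Edge table for an n-seed connectome
#'
#' Deterministic upper-triangle ordering: for `i < j`, edges are listed
#' lexicographically (`1-2, 1-3, ..., (n-1)-n`).
#'
#' @param n_seeds Number of seeds.
#' @return data.frame with columns `index`, `i`, `j`.
#' @export
edge_table <- function(n_seeds) {
  i <- rep(seq_len(n_seeds - 1), times = (n_seeds - 1):1)
  j <- unlist(lapply(seq_len(n_seeds - 1), function(a) (a + 1):n_seeds))
  data.frame(index = seq_along(i), i = i, j = j)
}

#' Edge index of a seed pair (and back)
#'
#' @param i,j Seed indices (order-free).
#' @param n_seeds Connectome size.
#' @return `edge_index`: the 1-based index in the [edge_table()] ordering.
#' @export
edge_index <- function(i, j, n_seeds) {
  a <- pmin(i, j); b <- pmax(i, j)
  stopifnot(all(a >= 1), all(b <= n_seeds), all(a != b))
  (a - 1) * n_seeds - a * (a + 1) / 2 + b
}

#' @rdname edge_index
#' @param index Edge index.
#' @return `index_edge`: a 2-column matrix of seed pairs.
#' @export
index_edge <- function(index, n_seeds) {
  ed <- edge_table(n_seeds)
  stopifnot(all(index >= 1), all(index <= nrow(ed)))
  cbind(i = ed$i[index], j = ed$j[index])
}

#' Build a feature matrix from band power or connectivity
#'
#' Regional power gives one feature per seed; connectivity gives the
#' vectorized upper triangle (`n(n-1)/2` features; 4005 for 90 seeds) with
#' the deterministic [edge_table()] ordering, round-trippable through
#' [edge_index()] / [index_edge()].
#'
#' @param source `subjects x seeds x bands` power array, or a named list
#'   (by band) of `subjects x seeds x seeds` connectivity arrays.
#' @param band Canonical band name to extract.
#' @return Object of class `feature_matrix`: matrix `subjects x features`
#'   with attributes `kind` ("power"/"connectivity"), `band`, `annotation`
#'   (data.frame describing each feature).
#' @export
build_features <- function(source, band) {
  if (is.array(source) && length(dim(source)) == 3 && !is.list(source)) {
    bands <- dimnames(source)[[3]]
    stopifnot(band %in% bands)
    X <- source[, , band]
    ann <- data.frame(feature = seq_len(ncol(X)), band = band,
                      kind = "power",
                      seed = colnames(X) %||% paste0("seed_", seq_len(ncol(X))))
    kind <- "power"
  } else {
    stopifnot(is.list(source), band %in% names(source))
    arr <- source[[band]]
    ns <- dim(arr)[2]
    ed <- edge_table(ns)
    X <- matrix(0, dim(arr)[1], nrow(ed))
    for (s in seq_len(dim(arr)[1])) {
      M <- arr[s, , ]
      X[s, ] <- M[cbind(ed$i, ed$j)]
    }
    labs <- dimnames(arr)[[2]] %||% paste0("seed_", seq_len(ns))
    ann <- data.frame(feature = ed$index, band = band, kind = "connectivity",
                      seed_i = labs[ed$i], seed_j = labs[ed$j],
                      i = ed$i, j = ed$j)
    kind <- "connectivity"
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(X, kind = kind, band = band, annotation = ann,
            class = c("feature_matrix", "matrix", "array"))
}

#' PCA group-separation check
#'
#' TRUE when the silhouette of the group labels in the first two principal
#' components exceeds 0.2 — the quantitative stand-in for judging PCA
#' cluster separation visually. Gates the use of the univariate pre-filter
#' (applied to connectivity data only).
#'
#' @param X `subjects x features` matrix.
#' @param labels Two-level grouping.
#' @return Logical; attribute `silhouette` carries the mean width.
#' @export
pca_separation_check <- function(X, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, nrow(X) == length(labels))
  if (anyDuplicated(X)) stop("degenerate input: duplicated subjects",
                             call. = FALSE)
  keep <- apply(X, 2, sd) > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(labels), stats::dist(sc))
  ms <- mean(sil[, "sil_width"])
  structure(ms > 0.2, silhouette = ms)
}

#' Univariate rank-sum feature filter
#'
#' Keeps features with uncorrected rank-sum p < `alpha` between the groups.
#' Intended for use inside outer folds only, on training subjects — it must
#' never see held-out data.
#'
#' @param X `subjects x features` training matrix.
#' @param labels Training labels.
#' @param alpha Retention threshold (default 0.05).
#' @return Integer vector of retained feature indices.
#' @export
univariate_filter <- function(X, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  p <- vapply(seq_len(ncol(X)), function(k) {
    y <- X[, k]
    if (sd(y) == 0) return(1)
    wilcoxon_ranksum(y, labels)[["p"]]
  }, numeric(1))
  which(p < alpha)
}

ranger_fit <- function(X, y, seed) {
  df <- data.frame(y = y, X, check.names = FALSE)
  ranger::ranger(y ~ ., data = df, num.trees = 500,
                 importance = "impurity", seed = seed,
                 respect.unordered.factors = TRUE)
}

#' Recursive random-forest feature selection (rRF-FS)
#'
#' Repeats, over `n_iterations` fresh RF seeds, a recursive elimination:
#' fit a 500-tree random forest, rank features by impurity importance, drop
#' the bottom `drop_fraction`, and recurse until two features remain; the
#' iteration keeps the smallest set whose out-of-bag accuracy is within
#' `oob_tolerance` of the best accuracy seen along the elimination ladder
#' (a parsimony rule in the spirit of the 1-SE rule). A feature is selected
#' if it survives in at least half of the iterations; the repetition damps
#' the run-to-run instability of single-forest importance rankings.
#'
#' @param X `subjects x features` training matrix.
#' @param labels Training labels (two levels).
#' @param n_iterations RF repetitions (default 10).
#' @param drop_fraction Fraction eliminated per step (default 0.2).
#' @param oob_tolerance Allowed OOB accuracy deficit (in accuracy units)
#'   from the ladder's best when picking the smallest set (default 0.02).
#' @param seed RNG seed.
#' @return Integer vector of selected feature indices (input order);
#'   attribute `survival_counts`.
#' @export
rrf_fs <- function(X, labels, n_iterations = 10, drop_fraction = 0.2,
                   oob_tolerance = 0.02, seed = 1) {
  y <- as.factor(labels)
  p <- ncol(X)
  if (p < 2) return(structure(seq_len(p), survival_counts = rep(n_iterations, p)))
  counts <- integer(p)
  for (it in seq_len(n_iterations)) {
    active <- seq_len(p)
    ladder <- list()
    accs <- numeric(0)
    repeat {
      fit <- ranger_fit(X[, active, drop = FALSE], y,
                        seed = seed * 1000 + it * 100 + length(active))
      ladder[[length(ladder) + 1L]] <- active
      accs <- c(accs, 1 - fit$prediction.error)
      if (length(active) <= 2) break
      ndrop <- max(1, floor(length(active) * drop_fraction))
      active <- active[order(fit$variable.importance,
                             decreasing = TRUE)][
        seq_len(length(active) - ndrop)]
    }
    ok <- which(accs >= max(accs) - oob_tolerance)
    best_set <- ladder[[max(ok)]]   # smallest set within tolerance of best
    counts[best_set] <- counts[best_set] + 1L
  }
  structure(which(counts >= n_iterations / 2), survival_counts = counts)
}

# stratified k folds; returns integer fold id per subject
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  y <- as.factor(labels)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(seq_len(k), function(f)
    length(unique(y[fold == f])) < 2, logical(1)))) {
    stop("stratification failed: a fold is missing a class", call. = FALSE)
  }
  fold
}

svm_fold_accuracy <- function(X, y, train, test, cost = 1) {
  Xtr <- X[train, , drop = FALSE]
  keep <- apply(Xtr, 2, sd) > 0
  if (!any(keep)) {
    # uninformative: majority-class prediction
    maj <- names(which.max(table(y[train])))
    return(mean(y[test] == maj))
  }
  fit <- e1071::svm(Xtr[, keep, drop = FALSE], y[train], kernel = "radial",
                    cost = cost, scale = TRUE)
  mean(predict(fit, X[test, keep, drop = FALSE]) == y[test])
}

#' Nested k-fold feature selection
#'
#' For each of `k` outer folds: (optionally) the univariate filter, then
#' rRF-FS, both on the k-1 training folds only; an RBF SVM trained on the
#' selected features is evaluated on the held-out fold. Features selected in
#' at least `consensus_threshold` folds form the consensus list (4 of 10 for
#' connectivity — which uses the pre-filter — and 2 of 10 for power, which
#' does not).
#'
#' @param X `subjects x features` matrix (e.g. a [build_features()] output).
#' @param labels Group labels.
#' @param k Outer folds (default 10), stratified by group.
#' @param consensus_threshold Minimum fold count for the consensus list;
#'   default 4 when `use_filter` else 2.
#' @param use_filter Apply the univariate pre-filter inside folds; default
#'   TRUE when `attr(X, "kind") == "connectivity"`.
#' @param seed RNG seed (folds and RF substreams).
#' @param folds Optional precomputed fold assignment (length n integers in
#'   1..k); overrides the stratified draw.
#' @param fold_hook Optional `function(X, test_idx)` applied to the feature
#'   matrix before each fold is processed (used by the leakage canary).
#' @return Object of class `selection_result`: list with `fold_selected`
#'   (list of per-fold index vectors), `fold_accuracy`, `consensus_counts`,
#'   `consensus` (indices), `threshold`, `folds`.
#' @export
nested_fs <- function(X, labels, k = 10, consensus_threshold = NULL,
                      use_filter = NULL, seed = 1, folds = NULL,
                      fold_hook = NULL) {
  y <- as.factor(labels)
  stopifnot(nlevels(y) == 2, nrow(X) == length(y))
  if (is.null(use_filter)) {
    use_filter <- identical(attr(X, "kind"), "connectivity")
  }
  if (is.null(consensus_threshold)) {
    consensus_threshold <- if (use_filter) 4 else 2
  }
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  counts <- integer(ncol(X))
  fold_selected <- vector("list", k)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    Xf <- if (is.null(fold_hook)) X else fold_hook(X, which(folds == f))
    train <- which(folds != f)
    test <- which(folds == f)
    cand <- seq_len(ncol(Xf))
    if (use_filter) {
      cand <- univariate_filter(Xf[train, , drop = FALSE], y[train])
      if (!length(cand)) cand <- seq_len(ncol(Xf))
    }
    sel <- rrf_fs(Xf[train, cand, drop = FALSE], y[train],
                  seed = seed + f)
    sel <- cand[sel]
    if (!length(sel)) sel <- cand
    fold_selected[[f]] <- sel
    counts[sel] <- counts[sel] + 1L
    fold_acc[f] <- svm_fold_accuracy(Xf[, sel, drop = FALSE], y, train, test)
  }
  structure(list(
    fold_selected = fold_selected, fold_accuracy = fold_acc,
    consensus_counts = counts,
    consensus = which(counts >= consensus_threshold),
    threshold = consensus_threshold, folds = folds, use_filter = use_filter
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$consensus), "consensus features (>=",
      x$threshold, "of", length(x$fold_selected), "folds ); mean held-out",
      "accuracy", round(100 * mean(x$fold_accuracy), 1), "%\n")
  invisible(x)
}

#' Cross-validated SVM on the consensus features
#'
#' Stratified k-fold CV of an RBF SVM (C = 1, features standardized with
#' training-fold statistics only); also fits the full-data model used for
#' the training-set ROC.
#'
#' @param X Feature matrix restricted to the consensus features.
#' @param labels Group labels.
#' @param k Folds (default 10).
#' @param seed RNG seed.
#' @param folds Optional fold assignment override.
#' @param fold_hook Optional per-fold feature-matrix hook (leakage canary).
#' @return Object of class `classifier_report`: list with
#'   `cv_accuracy_mean`, `cv_accuracy_sd` (percent), `fold_accuracy`,
#'   `training_accuracy` (percent), `model`, `folds`.
#' @export
final_svm <- function(X, labels, k = 10, seed = 1, folds = NULL,
                      fold_hook = NULL) {
  y <- as.factor(labels)
  X <- as.matrix(X)
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(max(folds)), function(f) {
    Xf <- if (is.null(fold_hook)) X else fold_hook(X, which(folds == f))
    svm_fold_accuracy(Xf, y, which(folds != f), which(folds == f))
  }, numeric(1))
  keep <- apply(X, 2, sd) > 0
  model <- if (any(keep)) {
    e1071::svm(X[, keep, drop = FALSE], y, kernel = "radial", cost = 1,
               scale = TRUE)
  } else NULL
  train_acc <- if (is.null(model)) {
    max(table(y)) / length(y)
  } else mean(predict(model, X[, keep, drop = FALSE]) == y)
  structure(list(
    cv_accuracy_mean = 100 * mean(acc), cv_accuracy_sd = 100 * sd(acc),
    fold_accuracy = acc, training_accuracy = 100 * train_acc,
    model = model, model_keep = keep, folds = folds
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> CV accuracy %.1f +/- %.1f %%; training %.1f %%\n",
              x$cv_accuracy_mean, x$cv_accuracy_sd, x$training_accuracy))
  invisible(x)
}

#' Label permutation test for a classification pipeline
#'
#' Re-runs the cross-validated accuracy with permuted labels `n_perm` times;
#' `p = (1 + #(acc_perm >= acc_obs)) / (1 + n_perm)`.
#'
#' @param X Feature matrix.
#' @param labels Group labels.
#' @param n_perm Permutations (default 1000).
#' @param k CV folds.
#' @param seed RNG seed.
#' @param cv_fun Pipeline: `function(X, labels, k, seed)` returning a list
#'   with `cv_accuracy_mean`; default [final_svm()].
#' @return p-value; attributes `acc_obs` and `acc_perm`.
#' @export
label_permutation_test <- function(X, labels, n_perm = 1000, k = 10,
                                   seed = 1, cv_fun = final_svm) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  y <- as.factor(labels)
  acc_obs <- cv_fun(X, y, k = k, seed = seed)$cv_accuracy_mean
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  acc_perm <- vapply(seq_len(n_perm), function(b) {
    set.seed(perm_seeds[b])
    yp <- sample(y)
    cv_fun(X, yp, k = k, seed = perm_seeds[b])$cv_accuracy_mean
  }, numeric(1))
  structure((1 + sum(acc_perm >= acc_obs)) / (1 + n_perm),
            acc_obs = acc_obs, acc_perm = acc_perm)
}

plsda_cv <- function(X, labels, k = 10, seed = 1, n_components = 2) {
  y <- as.factor(labels)
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  folds <- stratified_folds(y, k, seed)
  nc <- min(n_components, ncol(X), nrow(X) - 2)
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    keep <- apply(X[tr, , drop = FALSE], 2, sd) > 0
    if (!any(keep)) return(mean(y[!tr] == names(which.max(table(y[tr])))))
    fit <- mixOmics::plsda(X[tr, keep, drop = FALSE], y[tr], ncomp = nc)
    pr <- predict(fit, X[!tr, keep, drop = FALSE])$class$max.dist[, nc]
    mean(pr == as.character(y[!tr]))
  }, numeric(1))
  list(cv_accuracy_mean = 100 * mean(acc), fold_accuracy = acc)
}

#' PLS-DA generalizability check with label permutation
#'
#' Partial least squares discriminant analysis (class = argmax of the
#' one-hot PLS prediction), cross-validated, with the same add-one label
#' permutation p-value as [label_permutation_test()].
#'
#' @param X Feature matrix.
#' @param labels Group labels.
#' @param n_components PLS components (default 2).
#' @param n_perm Permutations (default 1000).
#' @param k CV folds.
#' @param seed RNG seed.
#' @return p-value; attributes `acc_obs`, `acc_perm`.
#' @export
plsda_validate <- function(X, labels, n_components = 2, n_perm = 1000,
                           k = 10, seed = 1) {
  label_permutation_test(
    X, labels, n_perm = n_perm, k = k, seed = seed,
    cv_fun = function(X, labels, k, seed) {
      plsda_cv(X, labels, k = k, seed = seed, n_components = n_components)
    })
}

#' Training-set ROC-AUC of a fitted classifier
#'
#' AUC of the decision scores on the full (training) set. Deliberately
#' optimistic — a comparative metric between models fit to the same
#' subjects, not an estimate of generalization (a value near 1 is expected
#' by construction). All-equal scores give 0.5 by the tie convention.
#'
#' @param report A `classifier_report` from [final_svm()] (or any list with
#'   `model` and `model_keep`).
#' @param X The feature matrix the model was fit to.
#' @param labels Group labels.
#' @return AUC in `[0, 1]`.
#' @export
training_roc_auc <- function(report, X, labels) {
  y <- as.factor(labels)
  if (is.null(report$model)) return(0.5)
  sc <- attr(predict(report$model,
                     as.matrix(X)[, report$model_keep, drop = FALSE],
                     decision.values = TRUE), "decision.values")[, 1]
  if (length(unique(sc)) == 1) return(0.5)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                 quiet = TRUE, direction = "auto",
                                 levels = levels(y))))
}

#' Compare classification models
#'
#' Ranks feature sets by mean CV accuracy (ties broken by name).
#'
#' @param reports Named list of `classifier_report`s (e.g. one per feature
#'   set / band).
#' @return data.frame with columns `model`, `cv_accuracy_mean`,
#'   `cv_accuracy_sd`, `training_accuracy`, `rank`.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  df <- data.frame(
    model = names(reports),
    cv_accuracy_mean = vapply(reports, function(r) r$cv_accuracy_mean, 1),
    cv_accuracy_sd = vapply(reports, function(r) r$cv_accuracy_sd, 1),
    training_accuracy = vapply(reports, function(r) r$training_accuracy, 1),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$cv_accuracy_mean, df$model), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Leakage canary check
#'
#' Appends a canary feature that is label-revealing only on each fold's
#' held-out subjects (training rows carry pure noise, injected per fold via
#' the fold hook). A leak-free pipeline — selection, scaling and fitting
#' confined to training rows — gains nothing from it; a rise in CV accuracy
#' beyond `tolerance` indicates information leakage.
#'
#' @param X Feature matrix.
#' @param labels Group labels.
#' @param k Folds.
#' @param seed RNG seed.
#' @param tolerance Allowed accuracy increase in percentage points
#'   (default: one subject's worth).
#' @return Logical `passed`; attributes `acc_base`, `acc_canary`.
#' @export
leakage_canary_check <- function(X, labels, k = 10, seed = 1,
                                 tolerance = 100 / length(labels)) {
  y <- as.factor(labels)
  X <- as.matrix(X)
  folds <- stratified_folds(y, k, seed)
  base <- final_svm(X, y, k = k, seed = seed, folds = folds)
  set.seed(seed)
  noise <- rnorm(length(y))
  canary_col <- function(test_idx) {
    v <- noise
    v[test_idx] <- as.numeric(y[test_idx] == levels(y)[2]) * 10 - 5
    v
  }
  hook <- function(Xf, test_idx) {
    Xf[, "canary"] <- canary_col(test_idx)
    Xf
  }
  with_canary <- final_svm(cbind(X, canary = noise), y, k = k, seed = seed,
                           folds = folds, fold_hook = hook)
  structure(with_canary$cv_accuracy_mean <= base$cv_accuracy_mean + tolerance,
            acc_base = base$cv_accuracy_mean,
            acc_canary = with_canary$cv_accuracy_mean)
}
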