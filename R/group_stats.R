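# Covariate-adjusted group contrasts: one-way ANCOVA F (group adjusted for
# age and head motion), Freedman-Lane permutation p-values, Benjamini-
# Hochberg FDR, and the post hoc Wilcoxon rank-sum.

check_covars <- function(covars) {
  stopifnot(is.data.frame(covars),
            all(c("group", "age", "head_motion") %in% names(covars)))
  if (anyNA(covars[, c("group", "age", "head_motion")])) {
    stop("missing values in the covariate table", call. = FALSE)
  }
  if (length(unique(covars$group)) != 2) {
    stop("both groups must be present", call. = FALSE)
  }
  invisible(covars)
}

# orthonormal basis of the reduced design [1, age, motion] and the
# residualized, normalized group indicator
ancova_parts <- function(covars) {
  check_covars(covars)
  n <- nrow(covars)
  if (n <= 4) stop("need n > 4 subjects", call. = FALSE)
  Z <- cbind(1, covars$age, covars$head_motion)
  qrz <- qr(Z)
  if (qrz$rank < 3) stop("rank-deficient design", call. = FALSE)
  U <- qr.Q(qrz)                           # n x 3 orthonormal
  g <- as.numeric(covars$group == "mtbi")
  gs <- g - U %*% crossprod(U, g)
  gn2 <- sum(gs^2)
  if (gn2 < 1e-12) stop("rank-deficient design (group collinear with covariates)",
                        call. = FALSE)
  list(U = U, gn = as.numeric(gs) / sqrt(gn2), n = n)
}

#' One-way ANCOVA F statistic for the group factor
#'
#' F for dropping the group term from the full linear model
#' `y ~ group + age + head_motion`:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 4))`.
#'
#' @param y Per-subject response vector.
#' @param covars Covariate table with columns `group` (two levels, "mtbi"
#'   treated as the indicator), `age`, `head_motion`.
#' @return The F statistic (1 and n-4 df).
#' @export
ancova_f <- function(y, covars) {
  p <- ancova_parts(covars)
  stopifnot(length(y) == p$n)
  r <- y - p$U %*% crossprod(p$U, y)       # residual of reduced model
  rss_red <- sum(r^2)
  # perfect reduced fit (numerically): no group information left
  if (rss_red <= 1e-12 * max(sum(scale(y, scale = FALSE)^2),
                             .Machine$double.eps)) {
    return(0)
  }
  ss_g <- sum(p$gn * r)^2
  rss_full <- rss_red - ss_g
  if (rss_full <= 0) return(Inf)
  ss_g / (rss_full / (p$n - 4))
}

# adjusted group effect sign (mtbi minus control, covariate-adjusted)
ancova_direction <- function(Y, covars) {
  p <- ancova_parts(covars)
  R <- Y - p$U %*% crossprod(p$U, Y)
  sign(as.numeric(crossprod(p$gn, R)))
}

#' Freedman-Lane permutation p-values for a feature matrix
#'
#' Residualizes each feature on the covariates, permutes the residual rows
#' (one permutation sequence shared by every feature), adds back the
#' covariate fit and recomputes the ANCOVA F; the p-value uses the add-one
#' convention `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so p is never
#' zero and is reproducible from the seed.
#'
#' @param Y `subjects x units` feature matrix.
#' @param covars Covariate table (see [ancova_f()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param chunk Permutations per matrix block (memory/speed trade-off).
#' @return List with `F_obs`, `p_perm`, `direction` (sign of the adjusted
#'   group difference), `n_perm`, `seed`.
#' @export
permutation_pvalues <- function(Y, covars, n_perm = 10000, seed = 1,
                                chunk = 1000) {
  stopifnot(n_perm >= 1)
  Y <- as.matrix(Y)
  p <- ancova_parts(covars)
  stopifnot(nrow(Y) == p$n)
  n <- p$n
  m <- ncol(Y)
  R <- Y - p$U %*% crossprod(p$U, Y)
  rss0 <- colSums(R^2)
  ss_g_obs <- as.numeric(crossprod(p$gn, R))^2
  rss_full <- rss0 - ss_g_obs
  F_obs <- ifelse(rss_full <= 0, Inf, ss_g_obs / (rss_full / (n - 4)))
  # degenerate (constant) features: F is NaN-free but meaningless; p = 1
  degenerate <- rss0 <= 1e-24
  set.seed(seed)
  count <- numeric(m)
  done <- 0
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    P <- t(replicate(nb, sample.int(n)))        # nb x n permuted indices
    Wg <- matrix(p$gn[P], nb, n)
    A2 <- (Wg %*% R)^2                           # SS_group per perm x unit
    H2 <- 0
    for (k in 1:3) {
      Wu <- matrix(p$U[, k][P], nb, n)
      H2 <- H2 + (Wu %*% R)^2
    }
    rss_red <- matrix(rss0, nb, m, byrow = TRUE) - H2
    denom <- (rss_red - A2) / (n - 4)
    Fp <- ifelse(denom <= 0, Inf, A2 / denom)
    count <- count + colSums(Fp >= matrix(F_obs, nb, m, byrow = TRUE))
    done <- done + nb
  }
  p_perm <- (1 + count) / (1 + n_perm)
  p_perm[degenerate] <- 1
  F_obs[degenerate] <- 0
  list(F_obs = F_obs, p_perm = p_perm,
       direction = ancova_direction(Y, covars),
       n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg FDR adjustment and significance mask
#'
#' Standard step-up adjusted p-values (with monotonicity enforcement) and
#' the mask `adjusted < q`.
#'
#' @param p P-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_fdr` and logical `significant`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p > 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  list(p_fdr = adj, significant = adj < q)
}

#' Wilcoxon rank-sum (Mann-Whitney U) with tie-corrected normal z
#'
#' U counts, for the first group, the pairs in which its value exceeds the
#' other group's (ties count one half). z uses the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param y Pooled values.
#' @param group Two-level grouping vector; the first level (alphabetical,
#'   or factor order) is the U reference group.
#' @return Named numeric `c(U =, z =, p =)` (two-sided).
#' @export
wilcoxon_ranksum <- function(y, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("need two non-empty groups", call. = FALSE)
  }
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  rk <- rank(y)
  U <- sum(rk[group == levels(group)[1]]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(c(U = U, z = 0, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  c(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

#' Build a StatMap data.frame from permutation results
#' @keywords internal
stat_map <- function(unit, perm, q = 0.05) {
  fdr <- bh_fdr(perm$p_perm, q)
  structure(data.frame(
    unit = unit, F = perm$F_obs, p_perm = perm$p_perm,
    p_fdr = fdr$p_fdr, significant = fdr$significant,
    direction = perm$direction, stringsAsFactors = FALSE
  ), class = c("stat_map", "data.frame"))
}

#' Group contrast of regional band power
#'
#' Per band: one ANCOVA per seed (group adjusted for age and head motion),
#' Freedman-Lane permutation p-values, BH-FDR across the seeds within the
#' band.
#'
#' @param band_power `subjects x seeds x bands` array (dimnames on bands),
#'   as from [measure_cohort()].
#' @param covars Covariate table, rows aligned with subjects.
#' @param n_perm Permutations (default 10000).
#' @param seed Master seed; each band uses an offset substream.
#' @param q FDR level.
#' @return Named list of `stat_map` data.frames, one per band.
#' @export
contrast_power <- function(band_power, covars, n_perm = 10000, seed = 1,
                           q = 0.05) {
  stopifnot(length(dim(band_power)) == 3)
  bands <- dimnames(band_power)[[3]]
  out <- list()
  for (bi in seq_along(bands)) {
    Y <- band_power[, , bi]
    perm <- permutation_pvalues(Y, covars, n_perm = n_perm,
                                seed = seed + bi)
    out[[bands[bi]]] <- stat_map(colnames(Y) %||% paste0("seed_", seq_len(ncol(Y))),
                                 perm, q)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group contrast of AEC connectivity
#'
#' Per band: vectorizes the upper triangle of each subject's connectome
#' (n(n-1)/2 edges; 4005 for 90 seeds), runs the permutation ANCOVA on every
#' edge and applies BH-FDR across edges within the band.
#'
#' @param conn Named list (by band) of `subjects x seeds x seeds` arrays.
#' @param covars Covariate table, rows aligned with subjects.
#' @param n_perm Permutations (default 10000).
#' @param seed Master seed; per-band offset substreams.
#' @param q FDR level.
#' @return Named list of `stat_map` data.frames; units are `"i-j"` edge
#'   labels (upper triangle, i < j).
#' @export
contrast_connectivity <- function(conn, covars, n_perm = 10000, seed = 1,
                                  q = 0.05) {
  out <- list()
  for (bi in seq_along(conn)) {
    arr <- conn[[bi]]
    stopifnot(length(dim(arr)) == 3, dim(arr)[2] == dim(arr)[3])
    ns <- dim(arr)[2]
    ed <- edge_table(ns)
    Y <- matrix(0, dim(arr)[1], nrow(ed))
    for (s in seq_len(dim(arr)[1])) {
      M <- arr[s, , ]
      Y[s, ] <- M[cbind(ed$i, ed$j)]
    }
    perm <- permutation_pvalues(Y, covars, n_perm = n_perm,
                                seed = seed + 100 + bi)
    out[[names(conn)[bi] %||% paste0("band", bi)]] <-
      stat_map(paste0(ed$i, "-", ed$j), perm, q)
  }
  out
}
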