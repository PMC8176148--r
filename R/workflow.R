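# Cohort-level measurement: stream subjects through the spectral-power and
# connectivity pipelines without holding all source signals in memory.

#' Measure band power and AEC connectomes across a cohort
#'
#' For each subject: generate (or reconstruct) the source signals, epoch and
#' z-score them, then compute the Welch band-power table and/or the
#' leakage-corrected static AEC connectome per requested band. Subjects are
#' processed one at a time so full-scale cohorts stay within memory.
#'
#' @param cohort A `meg_cohort` from [generate_cohort()], or a list of
#'   `source_epochs` plus a metadata data.frame via `metadata`.
#' @param bands Canonical band names to analyse.
#' @param power,connectivity Which feature spaces to compute.
#' @param orthogonalize Leakage correction for the connectivity arm.
#' @param epoch_length Seconds (default 10).
#' @param metadata Required when `cohort` is a plain list of `source_epochs`.
#' @param zscore Standardize each seed over concatenated epochs before
#'   measuring (default TRUE, the analysis-pipeline convention). Set FALSE
#'   to measure raw generator output (e.g. amplitude-square-law checks —
#'   z-scoring rescales total variance, so planted band-power ratios are
#'   diluted by design under the default).
#' @param verbose Print per-subject progress.
#' @return List with `metadata`, `band_power`
#'   (`subjects x seeds x bands`), `psd` (`subjects x seeds x freqs`,
#'   attribute `freq`), and `conn` (named list per band of
#'   `subjects x seeds x seeds`).
#' @export
measure_cohort <- function(cohort, bands = "delta", power = TRUE,
                           connectivity = TRUE, orthogonalize = TRUE,
                           epoch_length = 10, metadata = NULL,
                           zscore = TRUE, verbose = FALSE) {
  assert_bands(bands)
  if (inherits(cohort, "meg_cohort")) {
    metadata <- cohort$metadata
    get_epochs <- function(i) {
      epoch_sources(cohort_source_signals(cohort, i), epoch_length)
    }
    labels <- cohort$source_model$label
    ns <- cohort$config$n_seeds
  } else {
    stopifnot(is.list(cohort), !is.null(metadata),
              length(cohort) == nrow(metadata))
    get_epochs <- function(i) cohort[[i]]
    labels <- cohort[[1]]$labels
    ns <- n_seeds_of(cohort[[1]])
  }
  n <- nrow(metadata)
  band_power <- NULL
  psd_arr <- NULL
  freq <- NULL
  conn <- NULL
  for (i in seq_len(n)) {
    if (verbose) message("subject ", i, "/", n, " (", metadata$subject_id[i], ")")
    se <- get_epochs(i)
    if (zscore) se <- zscore_sources(se)
    if (power) {
      p <- welch_psd(se)
      if (is.null(psd_arr)) {
        freq <- p$freq
        psd_arr <- array(NA_real_, c(n, ns, length(freq)),
                         dimnames = list(metadata$subject_id, labels, NULL))
        band_power <- array(NA_real_, c(n, ns, length(bands)),
                            dimnames = list(metadata$subject_id, labels, bands))
      }
      psd_arr[i, , ] <- p$psd
      band_power[i, , ] <- bin_bands(p, bands)
    }
    if (connectivity) {
      if (is.null(conn)) {
        conn <- lapply(setNames(bands, bands), function(b) {
          array(NA_real_, c(n, ns, ns),
                dimnames = list(metadata$subject_id, labels, labels))
        })
      }
      for (b in bands) {
        conn[[b]][i, , ] <- connectivity_aec(se, b,
                                             orthogonalize = orthogonalize)
      }
    }
  }
  if (!is.null(psd_arr)) attr(psd_arr, "freq") <- freq
  list(metadata = metadata, band_power = band_power, psd = psd_arr,
       conn = conn)
}

#' Covariate table of a cohort
#'
#' @param metadata A cohort metadata data.frame.
#' @return data.frame with `group`, `age`, `head_motion` (the ANCOVA
#'   nuisance design).
#' @export
covariate_table <- function(metadata) {
  cv <- metadata[, c("group", "age", "head_motion")]
  check_covars(cv)
  cv
}

#' Write a per-band StatMap to CSV
#'
#' @param maps Named list of `stat_map` data.frames (per band).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_stat_maps <- function(maps, dir, prefix = "statmap") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (b in names(maps)) {
    p <- file.path(dir, paste0(prefix, "_", b, ".csv"))
    write.csv(maps[[b]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
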