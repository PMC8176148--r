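# End-to-end orchestration: simulate -> preprocess -> localize -> power /
# connectivity -> stats -> ml, from one YAML config, with content-hash
# stage caching and a JSON run manifest.

#' Read and validate a pipeline configuration
#'
#' @param path YAML file; see `inst/extdata/demo_config.yaml` for the
#'   schema.
#' @return Validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 7, out_dir = "megconn_run",
    cohort = list(n_mtbi = 8, n_control = 8, sampling_rate = 200,
                  duration = 60, n_seeds = 20,
                  bands = c("delta", "theta", "alpha", "beta"),
                  effects = "default"),
    sensor = list(enabled = TRUE, dipole_moment = 1e-8, noise_sd = 30,
                  artifacts = TRUE),
    preprocess = list(f_lo = 1, f_hi = 90, notch = 60, epoch_length = 10,
                      motion_threshold = 10, jump_threshold = 2000),
    analysis = list(bands = "delta", orthogonalize = TRUE),
    stats = list(n_perm = 1000, q = 0.05),
    ml = list(bands = "delta", n_perm = 100, k = 10)
  )
  cfg <- modifyList(defaults, cfg)
  assert_bands(cfg$cohort$bands)
  assert_bands(cfg$analysis$bands)
  assert_bands(cfg$ml$bands)
  if (!all(cfg$analysis$bands %in% cfg$cohort$bands)) {
    stop("analysis bands must be a subset of the simulated bands",
         call. = FALSE)
  }
  nyq <- cfg$cohort$sampling_rate / 2
  for (b in cfg$cohort$bands) {
    if (band_limits(b)[2] >= nyq) {
      stop("band '", b, "' exceeds Nyquist at ", cfg$cohort$sampling_rate,
           " Hz", call. = FALSE)
    }
  }
  if (cfg$preprocess$f_hi >= nyq) {
    stop("preprocess f_hi must be below Nyquist", call. = FALSE)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

synthetic_config_from <- function(cfg) {
  amps <- c(delta = 1.0, theta = 0.9, alpha = 1.1, beta = 0.7,
            lgamma1 = 0.4, lgamma2 = 0.3, hgamma = 0.25)
  amps <- amps[cfg$cohort$bands]
  sm <- default_source_model(cfg$cohort$n_seeds)
  eff <- cfg$cohort$effects
  if (identical(eff, "null")) {
    pe <- list(); ce <- list()
  } else {
    pe <- default_power_effects(sm)
    ce <- Filter(function(e) e$band %in% cfg$cohort$bands,
                 default_coupling_effects(sm))
  }
  synthetic_config(
    n_per_group = c(mtbi = cfg$cohort$n_mtbi, control = cfg$cohort$n_control),
    sampling_rate = cfg$cohort$sampling_rate, duration = cfg$cohort$duration,
    n_seeds = cfg$cohort$n_seeds, band_amplitudes = amps,
    power_effects = pe, coupling_effects = ce, seed = cfg$seed
  )
}

stage_paths <- function(out_dir) {
  list(cache = file.path(out_dir, "cache"),
       manifest = file.path(out_dir, "manifest.json"))
}

load_manifest <- function(paths) {
  if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  } else list(stages = list())
}

save_manifest <- function(man, paths) {
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

# run one cached stage: recompute when the content hash (stage config +
# upstream hashes) changed or the cached output is missing
run_stage <- function(name, hash_input, paths, man, fun, verbose = TRUE) {
  h <- rlang::hash(hash_input)
  rds <- file.path(paths$cache, paste0(name, ".rds"))
  st <- man$stages[[name]]
  if (!is.null(st) && identical(st$hash, h) && file.exists(rds)) {
    if (verbose) message("[", name, "] cached")
    return(list(value = readRDS(rds), man = man, hash = h))
  }
  if (verbose) message("[", name, "] running")
  t0 <- Sys.time()
  value <- fun()
  dir.create(paths$cache, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, rds)
  man$stages[[name]] <- list(hash = h, output = rds,
                             seconds = round(as.numeric(Sys.time() - t0,
                                                        units = "secs"), 2),
                             finished = format(Sys.time()))
  list(value = value, man = man, hash = h)
}

#' Run the end-to-end pipeline
#'
#' Executes (or resumes from cache) the stages simulate, preprocess +
#' localize, power, connectivity, stats and ml, writing CSV/JSON outputs,
#' connectome heatmap PNGs and a JSON run manifest under `out_dir`. Stage
#' caching is keyed by a content hash of the stage configuration and its
#' upstream hashes, so editing one part of the config recomputes only the
#' affected stages.
#'
#' @param config Path to a YAML config or a `pipeline_config`.
#' @param stages Subset of
#'   `c("simulate", "localize", "power", "connectivity", "stats", "ml")`
#'   or `"all"`.
#' @param verbose Log stage progress.
#' @return The run manifest (invisibly) with an attribute `results` holding
#'   the in-memory stage outputs.
#' @export
run_pipeline <- function(config, stages = "all", verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  all_stages <- c("simulate", "localize", "power", "connectivity", "stats",
                  "ml")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  # expand stage dependencies
  if (any(c("stats", "ml") %in% stages)) {
    stages <- union(stages, c("power", "connectivity"))
  }
  if (any(c("power", "connectivity") %in% stages)) {
    stages <- union(stages, "localize")
  }
  stages <- union(stages, "simulate")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(cfg$out_dir)
  man <- load_manifest(paths)
  man$seed <- cfg$seed
  man$package_version <- as.character(utils::packageVersion("megconn"))
  results <- list()

  scfg <- synthetic_config_from(cfg)
  sim <- run_stage("simulate", list(scfg = unclass(scfg)), paths, man,
                   function() {
    cohort <- generate_cohort(scfg)
    write.csv(cohort$metadata[, c("subject_id", "group", "age", "sex",
                                  "head_motion")],
              file.path(cfg$out_dir, "metadata.csv"), row.names = FALSE)
    yaml::write_yaml(rapply(unclass(scfg), function(x) x, how = "replace"),
                     file.path(cfg$out_dir, "config_echo.yaml"))
    cohort
  }, verbose = verbose)
  man <- sim$man
  cohort <- sim$value
  results$cohort <- cohort
  if (!"localize" %in% stages) {
    save_manifest(man, paths)
    return(invisible(structure(man, results = results)))
  }

  loc <- run_stage("localize",
                   list(up = sim$hash, sensor = cfg$sensor,
                        pre = cfg$preprocess), paths, man, function() {
    sm <- cohort$source_model
    n <- nrow(cohort$metadata)
    out <- vector("list", n)
    rej <- list()
    motion <- numeric(n)
    if (cfg$sensor$enabled) {
      hm <- default_head_model()
      pos <- seed_positions(sm)
      lfs <- lapply(seq_len(nrow(pos)), function(i) {
        compute_leadfield(hm, pos[i, ])
      })
    }
    for (i in seq_len(n)) {
      if (verbose) message("  subject ", i, "/", n)
      X <- cohort_source_signals(cohort, i)
      if (cfg$sensor$enabled) {
        set.seed(cohort$metadata$subject_seed[i] + 1L)
        hp <- simulate_head_position(ncol(X), scfg$sampling_rate,
                                     cohort$metadata$head_motion[i],
                                     cfg$preprocess$epoch_length)
        rec <- project_to_sensors(X, sm, hm,
                                  dipole_moment = cfg$sensor$dipole_moment,
                                  sensor_noise_sd = cfg$sensor$noise_sd,
                                  head_position = hp,
                                  subject_id = cohort$metadata$subject_id[i])
        templates <- NULL
        if (isTRUE(cfg$sensor$artifacts)) {
          rec <- inject_artifacts(rec, scfg$artifact_model,
                                  seed = cohort$metadata$subject_seed[i] + 2L,
                                  epoch_length = cfg$preprocess$epoch_length)
          tr <- attr(rec, "artifacts")
          templates <- Filter(Negate(is.null),
                              list(tr$ocular_course, tr$cardiac_course))
        }
        pc <- preproc_config(bandpass = c(cfg$preprocess$f_lo,
                                          cfg$preprocess$f_hi),
                             notch = cfg$preprocess$notch,
                             epoch_length = cfg$preprocess$epoch_length,
                             motion_threshold = cfg$preprocess$motion_threshold,
                             jump_threshold = cfg$preprocess$jump_threshold)
        ep <- preprocess_recording(rec, pc, artifact_templates = templates)
        rej[[i]] <- data.frame(subject_id = cohort$metadata$subject_id[i],
                               ep$flags)
        motion[i] <- attr(ep, "head_motion")
        se <- lcmv_beamformer(ep, sm, leadfields = lfs)
      } else {
        se <- epoch_sources(X, cfg$preprocess$epoch_length)
        motion[i] <- cohort$metadata$head_motion[i]
      }
      out[[i]] <- zscore_sources(se)
    }
    if (length(rej)) {
      write.csv(do.call(rbind, rej),
                file.path(cfg$out_dir, "rejection_report.csv"),
                row.names = FALSE)
    }
    meta <- cohort$metadata
    meta$head_motion_measured <- motion
    list(epochs = out, metadata = meta)
  }, verbose = verbose)
  man <- loc$man
  results$localized <- loc$value

  meta <- loc$value$metadata
  covars <- data.frame(group = meta$group, age = meta$age,
                       head_motion = if (cfg$sensor$enabled)
                         meta$head_motion_measured else meta$head_motion)

  pow <- NULL
  con <- NULL
  if ("power" %in% stages) {
  pow <- run_stage("power", list(up = loc$hash, bands = cfg$analysis$bands),
                   paths, man, function() {
    m <- measure_cohort(loc$value$epochs, bands = cfg$analysis$bands,
                        power = TRUE, connectivity = FALSE, metadata = meta)
    tab <- as.data.frame.table(m$band_power,
                               responseName = "power")
    names(tab) <- c("subject_id", "seed", "band", "power")
    write.csv(tab, file.path(cfg$out_dir, "band_power.csv"),
              row.names = FALSE)
    m[c("band_power", "psd")]
  }, verbose = verbose)
  man <- pow$man
  results$power <- pow$value
  }

  if ("connectivity" %in% stages) {
  con <- run_stage("connectivity",
                   list(up = loc$hash, bands = cfg$analysis$bands,
                        orth = cfg$analysis$orthogonalize),
                   paths, man, function() {
    m <- measure_cohort(loc$value$epochs, bands = cfg$analysis$bands,
                        power = FALSE, connectivity = TRUE,
                        orthogonalize = cfg$analysis$orthogonalize,
                        metadata = meta)
    for (b in names(m$conn)) {
      gm <- apply(m$conn[[b]], c(2, 3), mean)
      ed <- edge_table(nrow(gm))
      write.csv(data.frame(seed_i = ed$i - 1L, seed_j = ed$j - 1L,
                           value = gm[cbind(ed$i, ed$j)]),
                file.path(cfg$out_dir, paste0("aec_edges_", b, ".csv")),
                row.names = FALSE)
      png_path <- file.path(cfg$out_dir, paste0("aec_heatmap_", b, ".png"))
      tryCatch(pheatmap::pheatmap(gm, cluster_rows = FALSE,
                                  cluster_cols = FALSE, filename = png_path,
                                  main = paste("group-mean AEC,", b)),
               error = function(e) NULL)
    }
    m["conn"]
  }, verbose = verbose)
  man <- con$man
  results$conn <- con$value
  }

  if ("stats" %in% stages) {
    stt <- run_stage("stats", list(up_p = pow$hash, up_c = con$hash,
                                   stats = cfg$stats), paths, man,
                     function() {
      pmaps <- contrast_power(pow$value$band_power, covars,
                              n_perm = cfg$stats$n_perm, seed = cfg$seed,
                              q = cfg$stats$q)
      cmaps <- contrast_connectivity(con$value$conn, covars,
                                     n_perm = cfg$stats$n_perm,
                                     seed = cfg$seed, q = cfg$stats$q)
      write_stat_maps(pmaps, cfg$out_dir, "statmap_power")
      write_stat_maps(cmaps, cfg$out_dir, "statmap_aec")
      jsonlite::write_json(list(seed = cfg$seed, n_perm = cfg$stats$n_perm,
                                q = cfg$stats$q),
                           file.path(cfg$out_dir, "stats_manifest.json"),
                           auto_unbox = TRUE)
      list(power = pmaps, connectivity = cmaps)
    }, verbose = verbose)
    man <- stt$man
    results$stats <- stt$value
  }

  if ("ml" %in% stages) {
    ml <- run_stage("ml", list(up_p = pow$hash, up_c = con$hash,
                               ml = cfg$ml), paths, man, function() {
      labels <- factor(meta$group, levels = c("control", "mtbi"))
      reports <- list()
      consensus <- list()
      for (b in cfg$ml$bands) {
        for (kind in c("power", "connectivity")) {
          X <- if (kind == "power") {
            build_features(pow$value$band_power, b)
          } else build_features(con$value$conn, b)
          sel <- nested_fs(X, labels, k = cfg$ml$k, seed = cfg$seed)
          feats <- if (length(sel$consensus)) sel$consensus
                   else order(-sel$consensus_counts)[1:2]
          rep <- final_svm(X[, feats, drop = FALSE], labels, k = cfg$ml$k,
                           seed = cfg$seed)
          rep$permutation_p <- as.numeric(
            label_permutation_test(X[, feats, drop = FALSE], labels,
                                   n_perm = cfg$ml$n_perm, k = cfg$ml$k,
                                   seed = cfg$seed))
          rep$training_roc_auc <- training_roc_auc(
            rep, X[, feats, drop = FALSE], labels)
          nm <- paste(kind, b, sep = "_")
          reports[[nm]] <- rep
          ann <- attr(X, "annotation")[feats, , drop = FALSE]
          ann$consensus_count <- sel$consensus_counts[feats]
          consensus[[nm]] <- ann
        }
      }
      comp <- compare_models(reports)
      write.csv(do.call(rbind, lapply(names(consensus), function(nm) {
        a <- consensus[[nm]]
        lab <- if ("seed_j" %in% names(a)) {
          paste(a$seed_i, a$seed_j, sep = ":")
        } else a$seed
        data.frame(model = nm, band = a$band, kind = a$kind,
                   feature = lab, consensus_count = a$consensus_count)
      })), file.path(cfg$out_dir, "consensus_features.csv"),
      row.names = FALSE)
      jsonlite::write_json(
        list(comparison = comp,
             reports = lapply(reports, function(r) {
               r[c("cv_accuracy_mean", "cv_accuracy_sd",
                   "training_accuracy", "permutation_p",
                   "training_roc_auc")]
             })),
        file.path(cfg$out_dir, "classifier_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(reports = reports, comparison = comp, consensus = consensus)
    }, verbose = verbose)
    man <- ml$man
    results$ml <- ml$value
  }

  save_manifest(man, paths)
  invisible(structure(man, results = results))
}
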