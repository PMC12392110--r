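#' Default pipeline configuration
#'
#' The full nested configuration of every stage, with the analysis
#' constants as named defaults: 125-Hz label rate, 30-s segments, the
#' 0.1-s drop and 0.2-s merge rules, the 0.165-s spike window, 0.2-Hz
#' PSD bins over (0, 30] Hz, 1e4 bootstrap resamples, 100 training
#' epochs with patience 2 and learning-rate division by 10, the 120-s
#' pause threshold, and the 40-min (2,400-s) analysis window recorded
#' from minute 100 to 140 of a session.
#'
#' @return a nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    output_dir = "sleseg-results",
    verbose = FALSE,
    simulate = list(
      groups = list(
        ctrl = list(duration_multiplier = 1, spike_freq_multiplier = 1,
                    rate_multiplier = 1),
        CNB120 = list(duration_multiplier = 0.3,
                      spike_freq_multiplier = 0.8,
                      rate_multiplier = 1.2)),
      animals_per_group = 3,
      slices_per_animal = c(2, 6),
      recording = list(
        duration_s = 2400, sampling_rate_hz = 2000,
        sle_rate_per_min = 12, sle_duration_mean_s = 2,
        sle_duration_cv = 0.5, intra_sle_spike_hz = 10,
        spike_amplitude = 8, spike_amplitude_cv = 0.2, isi_cv = 0.05,
        spike_width_s = 0.08, min_gap_s = 0.1, baseline_noise_sd = 1,
        lowpass_cutoff_hz = 30, interictal_rate_per_min = 2,
        hum_50hz_amplitude = 0)),
    analysis_window = list(apply = FALSE, start_min = 100,
                           end_min = 140),
    detector = list(input_rate_hz = 125, segment_s = 30, n_blocks = 10,
                    kernel_size = 2, channels = 32,
                    padding_mode = "symmetric"),
    train = list(epochs = 100, initial_learning_rate = 1e-3,
                 plateau_patience_epochs = 2, lr_decay_factor = 10,
                 batch_size = 32, val_fraction = 0.2),
    augment = list(enabled = TRUE, hum_amplitude = 0.2,
                   hum_noise_sd = 0.1, burst_s = 5, burst_sd = 1,
                   pointwise_fraction = 0.1, pointwise_sd = 1),
    postprocess = list(binarize_threshold = 0.5, min_duration_s = 0.1,
                       merge_gap_s = 0.2, extremum_neighborhood = 1),
    metrics = list(spike_window_s = 0.165, pause_min_s = 120),
    psd = list(bin_width_hz = 0.2, fmax_hz = 30, n_resamples = 1e4,
               level = 0.95, normalized = TRUE),
    stats = list(metrics = c("fraction", "mean_duration_s",
                             "rate_per_min", "spike_freq_hz"),
                 group_by = "treatment", pairs = NULL))
}

mergeConfig <- function(defaults, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("validation error: unknown configuration key '", full, "'",
           call. = FALSE)
    }
    dval <- defaults[[key]]
    oval <- override[[key]]
    if (is.list(dval) && !is.null(names(dval)) && is.list(oval) &&
        key != "groups" && key != "pairs") {
      defaults[[key]] <- mergeConfig(dval, oval, full)
    } else {
      defaults[[key]] <- oval
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML or JSON configuration file (or takes a list), fills every
#' omitted field with its default from [defaultPipelineConfig()], and
#' rejects unknown keys with an error naming the offending field. An
#' empty file yields the full default configuration.
#'
#' @param config path to a YAML/JSON file, or a named list, or `NULL`
#'   for all defaults.
#' @return the normalized nested configuration list.
#' @export
validateConfig <- function(config = NULL) {
  defaults <- defaultPipelineConfig()
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("validation error: config file not found: ", config,
           call. = FALSE)
    }
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) return(defaults)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE)
    } else {
      yaml::yaml.load(txt)
    }
    if (is.null(config)) return(defaults)
  }
  if (!is.list(config)) {
    stop("validation error: configuration must be a named list",
         call. = FALSE)
  }
  cfg <- mergeConfig(defaults, config)
  for (g in cfg$simulate$groups) {
    bad <- setdiff(names(g), c("duration_multiplier",
                               "spike_freq_multiplier",
                               "rate_multiplier"))
    if (length(bad) > 0) {
      stop("validation error: unknown configuration key '",
           paste0("simulate.groups.", bad[1]), "'", call. = FALSE)
    }
  }
  cfg
}

bindBatches <- function(batches) {
  batches <- Filter(function(b) nrow(b@segments) > 0, batches)
  stopifnot(length(batches) > 0)
  b <- batches[[1]]
  if (length(batches) > 1) {
    b@segments <- do.call(rbind, lapply(batches, function(x) x@segments))
    b@targets <- do.call(rbind, lapply(batches, function(x) x@targets))
    b@provenance <- do.call(rbind,
                            lapply(batches, function(x) x@provenance))
    rownames(b@provenance) <- NULL
  }
  b
}

logStage <- function(con, stage, seed, t0, extra = list()) {
  entry <- c(list(stage = stage, seed = seed,
                  wall_s = round(as.numeric(Sys.time()) - t0, 3),
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             extra)
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' simulate -> train -> predict -> correct -> metrics -> PSD -> stats,
#' writing a results bundle (dataset manifest, trained model archive,
#' corrected event files, slice- and animal-level metric tables, PSD
#' tables with bootstrap bands, statistics tables, and a JSON-lines run
#' log) to the configured output directory. Rule-based stages are
#' exactly reproducible for a fixed config and seed.
#'
#' @param config a configuration accepted by [validateConfig()].
#' @return invisibly, a list with the bundle paths and in-memory tables.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- validateConfig(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "events"), showWarnings = FALSE)
  logCon <- file(file.path(out, "run_log.jsonl"), "w")
  on.exit(close(logCon))
  t0 <- as.numeric(Sys.time())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logStage(logCon, name, cfg$seed, t0)
    res
  }

  cohort <- stage("simulate", {
    groups <- lapply(cfg$simulate$groups,
                     function(g) do.call(treatmentEffect, g))
    base <- do.call(simRecordingConfig,
                    c(cfg$simulate$recording, list(seed = cfg$seed)))
    simulateCohort(simCohortConfig(
      groups = groups,
      animals_per_group = cfg$simulate$animals_per_group,
      slices_per_animal = cfg$simulate$slices_per_animal,
      base = base, seed = cfg$seed))
  })
  utils::write.csv(cohort$manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)

  prepared <- stage("prepare", {
    lapply(names(cohort$recordings), function(id) {
      rec <- cohort$recordings[[id]]
      ds <- downsampleRecording(rec, cfg$detector$input_rate_hz)
      ev125 <- resampleEvents(cohort$events[[id]],
                              cfg$detector$input_rate_hz)
      lab <- eventsToLabels(ev125, length(ds@samples))
      batch <- standardizeBatch(
        segmentRecording(ds, lab, cfg$detector$segment_s))
      list(id = id, ds = ds, batch = batch)
    })
  })
  names(prepared) <- names(cohort$recordings)

  detector <- stage("train", {
    info <- data.frame(
      recording_id = names(cohort$recordings),
      duration_s = vapply(cohort$events, totalWindowS, numeric(1)),
      sle_s = vapply(cohort$events,
                     function(e) sum(eventDurations(e)), numeric(1)),
      treated = cohort$manifest$label != names(cfg$simulate$groups)[1])
    plan <- splitTrainVal(info, cfg$train$val_fraction, cfg$seed)
    trainIds <- names(plan$assignment)[plan$assignment == "train"]
    valIds <- names(plan$assignment)[plan$assignment == "validation"]
    trainBatch <- bindBatches(lapply(prepared[trainIds], `[[`, "batch"))
    valBatch <- bindBatches(lapply(prepared[valIds], `[[`, "batch"))
    trainBatch <- duplicateWithInversion(trainBatch)
    if (isTRUE(cfg$augment$enabled)) {
      spec <- do.call(augmentationSpec,
                      cfg$augment[setdiff(names(cfg$augment), "enabled")])
      trainBatch <- augmentSegments(trainBatch, spec,
                                    seed = splitSeed(cfg$seed, 41L))
    }
    det <- buildDetector(
      do.call(detectorConfig, cfg$detector), seed = cfg$seed)
    pp <- do.call(postprocessConfig, cfg$postprocess)
    trainDetector(det, trainBatch, valBatch,
                  do.call(trainConfig,
                          c(cfg$train[setdiff(names(cfg$train),
                                              "val_fraction")],
                            list(seed = cfg$seed))),
                  postprocess = pp, verbose = isTRUE(cfg$verbose))
  })
  saveDetector(detector, file.path(out, "detector.json"))
  utils::write.csv(detector@history, file.path(out, "history.csv"),
                   row.names = FALSE)

  predicted <- stage("predict", {
    pp <- do.call(postprocessConfig, cfg$postprocess)
    lapply(prepared, function(p) {
      probs <- predictProbabilities(detector, p$ds)
      ev <- correctEvents(probs, p$ds, pp)
      writeEvents(ev, file.path(out, "events",
                                paste0(p$id, ".events.tsv")))
      ev
    })
  })

  metricsTable <- stage("metrics", {
    rows <- lapply(names(prepared), function(id) {
      evAcq <- resampleEvents(predicted[[id]],
                              samplingRate(cohort$recordings[[id]]))
      computeSleMetrics(cohort$recordings[[id]], evAcq,
                        cfg$metrics$spike_window_s)
    })
    do.call(rbind, rows)
  })
  animalTable <- aggregateMetrics(metricsTable, "animal")
  utils::write.csv(metricsTable, file.path(out, "metrics_slice.csv"),
                   row.names = FALSE)
  utils::write.csv(animalTable, file.path(out, "metrics_animal.csv"),
                   row.names = FALSE)

  psdTables <- stage("psd", {
    byGroup <- split(names(cohort$recordings), cohort$manifest$label)
    lapply(byGroup, function(ids) {
      psds <- lapply(cohort$recordings[ids], function(r) {
        binPsd(restrictAndNormalize(computePsd(r), cfg$psd$fmax_hz),
               cfg$psd$bin_width_hz, cfg$psd$fmax_hz, TRUE)
      })
      band <- bootstrapBand(psds, cfg$psd$n_resamples, cfg$psd$level,
                            seed = splitSeed(cfg$seed, 71L))
      bandBounds(band)
    })
  })
  for (g in names(psdTables)) {
    utils::write.csv(psdTables[[g]],
                     file.path(out, paste0("psd_", g, ".csv")),
                     row.names = FALSE)
  }

  statsTables <- stage("stats", {
    res <- list()
    for (metric in cfg$stats$metrics) {
      for (level in c("slice", "animal")) {
        tbl <- if (level == "slice") metricsTable else animalTable
        cmp <- tryCatch(
          compareMetricAcrossGroups(tbl, metric, cfg$stats$group_by,
                                    cfg$stats$pairs),
          error = function(e) NULL)
        if (!is.null(cmp)) {
          pw <- cmp$pairwise
          pw$metric <- metric
          pw$level <- level
          pw$omnibus_H <- cmp$omnibus$statistic
          pw$omnibus_p <- cmp$omnibus$p.value
          res[[paste(metric, level)]] <- pw
        }
      }
    }
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  })
  utils::write.csv(statsTables, file.path(out, "stats.csv"),
                   row.names = FALSE)

  invisible(list(output_dir = out, manifest = cohort$manifest,
                 detector = detector, metrics_slice = metricsTable,
                 metrics_animal = animalTable, psd = psdTables,
                 stats = statsTables))
}
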