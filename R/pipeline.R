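#' Simulate a synthetic dataset to a directory of trial CSVs
#'
#' Generates one session per subject from a \code{\linkS4class{SyntheticConfig}}
#' and writes each trial as a CSV file plus a \code{manifest.csv}
#' (columns \code{filename,subject,task,trial_index}) and sidecar metadata
#' (\code{config.yaml}, \code{metadata.yaml}) sufficient to re-run the stage
#' exactly. Output is byte-identical across runs with the same config.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}} (its seed drives all
#'   randomness).
#' @param outDir output directory, created if absent.
#' @param subjects character vector of subject identifiers.
#' @return The manifest data.frame, invisibly.
#' @seealso \code{\link{runExtract}}, \code{\link{runAnalyze}}
#' @export
runSimulate <- function(config, outDir, subjects = "S01") {
  stopifnot(is(config, "SyntheticConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) {
    stop(sprintf("cannot create output directory: %s", outDir), call. = FALSE)
  }
  sched <- taskSchedule(config)
  rows <- list()
  for (subj in subjects) {
    for (i in seq_along(sched)) {
      tr <- generateTrial(config, sched[i], subj, i)
      fn <- sprintf("%s_T%03d_%s.csv", subj, i, sched[i])
      writeTrialCSV(tr, file.path(outDir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, subject = subj, task = sched[i], trial_index = i)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  writeSyntheticConfig(config, file.path(outDir, "config.yaml"))
  yaml::write_yaml(list(
    stage = "simulate", package_version = as.character(utils::packageVersion("hjortheeg")),
    subjects = subjects, n_trials = nrow(manifest),
    seed = configSeed(config)), file.path(outDir, "metadata.yaml"))
  invisible(manifest)
}

#' Extract Hjorth features from a simulated or recorded session directory
#'
#' Loads every trial named in the directory's manifest, builds the windowed
#' feature table, and writes it as CSV together with a metadata sidecar
#' (window, hop, sampling rate, package version).
#'
#' @param inDir directory holding trial CSVs and a manifest.
#' @param outFile path of the feature CSV to write.
#' @param windowLength window length in samples (default 125); use the trial
#'   length for full-trial mode.
#' @param hop hop in samples (default 25).
#' @param manifest manifest CSV path (default \code{inDir/manifest.csv}).
#' @param samplingRate sampling rate in Hz (default 125).
#' @param nElectrodes required electrode column count (default 16).
#' @return The feature table, invisibly.
#' @export
runExtract <- function(inDir, outFile, windowLength = 125L, hop = 25L,
                       manifest = file.path(inDir, "manifest.csv"),
                       samplingRate = 125, nElectrodes = 16L) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest not found: %s", manifest), call. = FALSE)
  }
  trials <- loadSession(inDir, manifest, samplingRate = samplingRate,
                        nElectrodes = nElectrodes)
  if (!length(trials)) stop("manifest lists no trials", call. = FALSE)
  ft <- buildFeatureTable(trials, windowLength, hop)
  writeFeatureTable(ft, outFile)
  yaml::write_yaml(list(
    stage = "extract", package_version = as.character(utils::packageVersion("hjortheeg")),
    window_length = as.integer(windowLength), hop = as.integer(hop),
    sampling_rate = samplingRate, n_rows = nrow(ft)),
    paste0(outFile, ".meta.yaml"))
  invisible(ft)
}

#' Analyze a feature table: correlation, clustering, task contrast
#'
#' Reads a feature CSV, computes the feature correlation matrix, clusters
#' the rows with \code{\link{clusterFeatures}}, contrasts two tasks with
#' \code{\link{taskContrast}}, and writes a flat key/value report file.
#' Regenerating the report from the same inputs yields identical bytes.
#'
#' @param featureFile feature CSV written by \code{\link{runExtract}}.
#' @param outFile report file path.
#' @param k cluster count (default 2).
#' @param seed integer seed for clustering.
#' @param taskA,taskB tasks to contrast (defaults CRH vs Rest); skipped with
#'   a note in the report if either is absent.
#' @return List with elements \code{correlation}, \code{clusters},
#'   \code{contrast}, invisibly.
#' @export
runAnalyze <- function(featureFile, outFile, k = 2L, seed,
                       taskA = "CRH", taskB = "Rest") {
  if (!file.exists(featureFile)) {
    stop(sprintf("feature file not found: %s", featureFile), call. = FALSE)
  }
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  ft <- readFeatureTable(featureFile)
  cm <- featureCorrelation(ft)
  cl <- clusterFeatures(ft, k = k, seed = seed)
  ctr <- if (all(c(taskA, taskB) %in% ft$task)) {
    taskContrast(ft, taskA, taskB)
  } else NULL

  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  lines <- c(
    "# hjortheeg analysis report",
    sprintf("package_version = %s", utils::packageVersion("hjortheeg")),
    sprintf("n_rows = %d", nrow(ft)),
    sprintf("correlation_method = %s", attr(cm, "method")),
    sprintf("cor_activity_mobility = %s", num(cm["activity", "mobility"])),
    sprintf("cor_activity_complexity = %s", num(cm["activity", "complexity"])),
    sprintf("cor_mobility_complexity = %s", num(cm["mobility", "complexity"])),
    sprintf("cluster_method = %s", cl$method),
    sprintf("cluster_k = %d", cl$k),
    sprintf("cluster_seed = %d", cl$seed),
    sprintf("cluster_rows = %d", length(cl$assignment)),
    sprintf("cluster_rows_dropped = %d", cl$nDropped),
    sprintf("cluster_ari = %s", num(cl$agreement))
  )
  if (is.null(ctr)) {
    lines <- c(lines, sprintf("contrast = skipped (%s or %s absent)",
                              taskA, taskB))
  } else {
    lines <- c(lines, sprintf("contrast_tasks = %s vs %s", taskA, taskB))
    act <- ctr[ctr$feature == "activity", ]
    for (i in seq_len(nrow(act))) {
      lines <- c(lines, sprintf(
        "contrast_activity_E%d = diff %s ratio %s d %s",
        act$electrode[i], num(act$mean_diff[i]), num(act$ratio[i]),
        num(act$cohen_d[i])))
    }
    lines <- c(lines, sprintf(
      "contrast_high_amplitude_b_electrodes = %s",
      paste(sort(unique(ctr$electrode[ctr$high_amplitude_b])), collapse = ",")))
  }
  writeLines(lines, outFile)
  invisible(list(correlation = cm, clusters = cl, contrast = ctr))
}
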