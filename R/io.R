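#' Write a trial to a per-trial CSV file
#'
#' Writes one comma-separated file with a header row naming the electrodes
#' \code{E1..En} and one row per time sample. Values are printed with 17
#' significant digits, so reading the file back reproduces the stored
#' doubles bit-for-bit.
#'
#' @param trial an \code{\linkS4class{EEGTrial}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @seealso \code{\link{readTrialCSV}}
#' @export
writeTrialCSV <- function(trial, path) {
  stopifnot(is(trial, "EEGTrial"))
  dat <- t(trialData(trial)) # samples x electrodes
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(paste0("E", seq_len(ncol(dat))), collapse = ","), con)
  body <- apply(dat, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Read a per-trial CSV file
#'
#' Parses a file written in the package's trial dialect: a header row
#' \code{E1..E16} and one numeric row per sample. Task and subject metadata
#' are not encoded in the file and must be supplied (normally from a session
#' manifest). The reader is strict: it requires exactly 16 columns and
#' rejects non-numeric or missing cells, naming the offending row and
#' column.
#'
#' @param path file to read.
#' @param task task code for the trial.
#' @param subject subject identifier.
#' @param samplingRate sampling rate in Hz (default 125).
#' @param trialIndex 1-based trial index (default 1).
#' @param nElectrodes required column count (default 16, the dataset
#'   layout).
#' @return An \code{\linkS4class{EEGTrial}} with electrodes 1..16 in column
#'   order.
#' @export
readTrialCSV <- function(path, task, subject, samplingRate = 125,
                         trialIndex = 1L, nElectrodes = 16L) {
  if (!file.exists(path)) {
    stop(sprintf("trial file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (ncol(raw) != nElectrodes) {
    stop(sprintf("format error in %s: expected %d electrode columns, found %d",
                 path, nElectrodes, ncol(raw)), call. = FALSE)
  }
  if (nrow(raw) < 2L) {
    stop(sprintf("format error in %s: need at least 2 samples", path),
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf(
        "format error in %s: non-numeric or missing value at row %d, column %d (%s)",
        path, bad[1L], j, names(raw)[j]), call. = FALSE)
    }
    mat[, j] <- v
  }
  EEGTrial(t(mat), samplingRate = samplingRate, task = task,
           subject = subject, trialIndex = trialIndex)
}

#' Load a session of trial CSVs via a manifest
#'
#' The manifest is a data.frame (or path to a manifest CSV) with columns
#' \code{filename}, \code{subject}, \code{task} and optionally
#' \code{trial_index} (defaulting to manifest row order). Filenames are
#' resolved relative to \code{dir}. Trials are returned in manifest order.
#'
#' @param dir directory holding the trial files.
#' @param manifest data.frame or CSV path describing the files.
#' @param samplingRate sampling rate in Hz applied to every trial.
#' @param nElectrodes required column count per file (default 16).
#' @return List of \code{\linkS4class{EEGTrial}} objects.
#' @seealso \code{\link{runSimulate}} writes a conforming manifest.
#' @export
loadSession <- function(dir, manifest, samplingRate = 125,
                        nElectrodes = 16L) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.csv(manifest, colClasses = "character")
  }
  need <- c("filename", "subject", "task")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns filename, subject, task", call. = FALSE)
  }
  if (nrow(manifest) == 0L) return(list())
  idx <- if ("trial_index" %in% names(manifest)) {
    as.integer(manifest$trial_index)
  } else seq_len(nrow(manifest))
  paths <- file.path(dir, manifest$filename)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf("missing trial file(s): %s",
                 paste(manifest$filename[missing], collapse = ", ")),
         call. = FALSE)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    readTrialCSV(paths[i], task = manifest$task[i],
                 subject = manifest$subject[i],
                 samplingRate = samplingRate, trialIndex = idx[i],
                 nElectrodes = nElectrodes)
  })
}
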