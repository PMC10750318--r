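#' Task codes of the motor-execution protocol
#'
#' The eight trial labels used throughout the package: a baseline with eyes
#' open (BEO), closing the left/right hand (CLH, CRH), dorsal and plantar
#' flexion of the left/right foot (DLF, PLF, DRF, PRF), and the inter-task
#' Rest condition.
#'
#' @return Character vector of the eight task codes, in protocol order.
#' @examples
#' taskCodes()
#' @export
taskCodes <- function() {
  c("BEO", "CLH", "CRH", "DLF", "PLF", "DRF", "PRF", "Rest")
}

#' @title EEGTrial: one fixed-duration multichannel EEG segment
#'
#' @description An S4 container for a single trial: a numeric matrix of
#' microvolt samples with electrodes in rows and time samples in columns,
#' together with the sampling rate and task/subject/trial metadata.
#'
#' @slot data numeric matrix, electrodes x samples, in microvolts.
#' @slot samplingRate sampling frequency in Hz.
#' @slot task one of \code{\link{taskCodes}()}.
#' @slot subject subject identifier.
#' @slot trialIndex 1-based index of the trial within its session.
#'
#' @seealso \code{\link{EEGTrial}} (constructor), \code{\link{trialData}},
#'   \code{\link{generateTrial}}, \code{\link{readTrialCSV}}
#' @name EEGTrial-class
#' @rdname EEGTrial-class
#' @exportClass EEGTrial
setClass("EEGTrial",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    task = "character",
    subject = "character",
    trialIndex = "integer"
  )
)

setValidity("EEGTrial", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) {
    msg <- c(msg, "'data' must be a numeric matrix")
  } else {
    if (nrow(d) < 1L) msg <- c(msg, "at least one electrode row is required")
    if (ncol(d) < 2L) msg <- c(msg, "at least two samples per electrode are required")
    if (!all(is.finite(d))) msg <- c(msg, "all samples must be finite")
  }
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "'samplingRate' must be a single positive number")
  }
  if (length(object@task) != 1L || !(object@task %in% taskCodes())) {
    msg <- c(msg, sprintf("'task' must be one of: %s",
                          paste(taskCodes(), collapse = ", ")))
  }
  if (length(object@subject) != 1L || !nzchar(object@subject)) {
    msg <- c(msg, "'subject' must be a single non-empty string")
  }
  if (length(object@trialIndex) != 1L || is.na(object@trialIndex) ||
      object@trialIndex < 1L) {
    msg <- c(msg, "'trialIndex' must be a single positive integer")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGTrial
#'
#' @param data numeric matrix of microvolt samples, electrodes in rows,
#'   time samples in columns. Row names are set to \code{"E1"..} if absent.
#' @param samplingRate sampling frequency in Hz (default 125).
#' @param task task code, one of \code{\link{taskCodes}()}.
#' @param subject subject identifier string.
#' @param trialIndex 1-based trial index within the session.
#' @return A validated \code{\linkS4class{EEGTrial}}.
#' @examples
#' tr <- EEGTrial(matrix(rnorm(32), nrow = 2), samplingRate = 125,
#'                task = "Rest", subject = "S01", trialIndex = 1)
#' nSamples(tr)
#' @export
EEGTrial <- function(data, samplingRate = 125, task, subject,
                     trialIndex = 1L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(rownames(data))) {
    rownames(data) <- paste0("E", seq_len(nrow(data)))
  }
  new("EEGTrial", data = data, samplingRate = as.numeric(samplingRate),
      task = as.character(task), subject = as.character(subject),
      trialIndex = as.integer(trialIndex))
}

#' @title SyntheticConfig: parameters of the synthetic EEG generator
#'
#' @description Ground-truth configuration for \code{\link{generateTrial}}
#' and \code{\link{generateSession}}: the trial geometry (sampling rate,
#' duration, electrode count), the acquisition band limits, a per-task table
#' of electrode noise/burst amplitudes and burst bands, the session task
#' schedule, and the master seed.
#'
#' Each entry of \code{taskSpecs} is a data.frame with one row per electrode
#' and columns \code{noise_sd} (baseline band-limited noise SD, microvolts,
#' > 0), \code{burst_sd} (additional movement-related oscillatory SD,
#' microvolts, >= 0; 0 for Rest-like tasks), and \code{burst_low},
#' \code{burst_high} (burst band edges in Hz, inside the acquisition band).
#'
#' @slot samplingRate samples per second (default 125).
#' @slot trialDuration trial length in seconds (default 4).
#' @slot nElectrodes electrode count (default 16).
#' @slot bandLow,bandHigh acquisition bandpass cutoffs in Hz (defaults 5, 50).
#' @slot taskSpecs named list, task code -> per-electrode spec data.frame.
#' @slot schedule character vector of task codes, one session's trial order.
#' @slot seed master integer seed.
#'
#' @seealso \code{\link{defaultSyntheticConfig}}, \code{\link{generateTrial}}
#' @name SyntheticConfig-class
#' @rdname SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    samplingRate = "numeric",
    trialDuration = "numeric",
    nElectrodes = "integer",
    bandLow = "numeric",
    bandHigh = "numeric",
    taskSpecs = "list",
    schedule = "character",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  ns <- object@samplingRate * object@trialDuration
  if (abs(ns - round(ns)) > 1e-9 || ns < 2) {
    msg <- c(msg, "samplingRate * trialDuration must be an integer >= 2")
  }
  if (!(object@bandLow > 0 && object@bandLow < object@bandHigh &&
        object@bandHigh < object@samplingRate / 2)) {
    msg <- c(msg, "band limits must satisfy 0 < bandLow < bandHigh < samplingRate/2")
  }
  if (object@nElectrodes < 1L) msg <- c(msg, "nElectrodes must be >= 1")
  if (is.null(names(object@taskSpecs)) ||
      !all(names(object@taskSpecs) %in% taskCodes())) {
    msg <- c(msg, "taskSpecs must be named by task codes")
  }
  for (tk in names(object@taskSpecs)) {
    sp <- object@taskSpecs[[tk]]
    if (!is.data.frame(sp) ||
        !all(c("noise_sd", "burst_sd", "burst_low", "burst_high") %in% names(sp))) {
      msg <- c(msg, sprintf(
        "spec for task %s must be a data.frame with columns noise_sd, burst_sd, burst_low, burst_high", tk))
      next
    }
    if (nrow(sp) != object@nElectrodes) {
      msg <- c(msg, sprintf("spec for task %s must have exactly %d electrode rows",
                            tk, object@nElectrodes))
    }
    if (any(sp$noise_sd <= 0)) {
      msg <- c(msg, sprintf("task %s: noise_sd must be > 0 on every electrode", tk))
    }
    if (any(sp$burst_sd < 0)) {
      msg <- c(msg, sprintf("task %s: burst_sd must be >= 0", tk))
    }
    bursty <- sp$burst_sd > 0
    if (any(bursty & (sp$burst_low < object@bandLow |
                      sp$burst_high > object@bandHigh |
                      sp$burst_low >= sp$burst_high))) {
      msg <- c(msg, sprintf("task %s: burst band must lie within [bandLow, bandHigh]", tk))
    }
  }
  if (length(object@schedule) < 1L ||
      !all(object@schedule %in% names(object@taskSpecs))) {
    msg <- c(msg, "schedule entries must all have a task spec")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "a single integer seed is mandatory")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGTrial", function(object) {
  cat(sprintf("EEGTrial: %d electrodes x %d samples @ %g Hz (%.3g s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat(sprintf("  subject %s, task %s, trial %d\n",
              object@subject, object@task, object@trialIndex))
  cat(sprintf("  amplitude range [%.3g, %.3g] uV\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d electrodes, %g Hz, %g s trials, band %g-%g Hz\n",
              object@nElectrodes, object@samplingRate, object@trialDuration,
              object@bandLow, object@bandHigh))
  cat(sprintf("  %d tasks specified, schedule of %d trials, seed %d\n",
              length(object@taskSpecs), length(object@schedule), object@seed))
})
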