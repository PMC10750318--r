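#' @title Accessors for EEGTrial and SyntheticConfig
#'
#' @description Accessor generics for the package's S4 containers. Use these
#' rather than reaching into slots.
#'
#' @param object an \code{\linkS4class{EEGTrial}} or
#'   \code{\linkS4class{SyntheticConfig}}.
#' @return \code{trialData}: the electrodes x samples microvolt matrix;
#'   \code{samplingRate}: sampling frequency in Hz; \code{taskCode}: the task
#'   label; \code{subjectID}: the subject identifier; \code{trialIndex}: the
#'   1-based trial index; \code{nElectrodes} and \code{nSamples}: matrix
#'   dimensions; \code{taskSchedule}: the session's task ordering;
#'   \code{configSeed}: the master seed.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trialData", function(object) standardGeneric("trialData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("taskCode", function(object) standardGeneric("taskCode"))
#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setGeneric("trialIndex", function(object) standardGeneric("trialIndex"))
#' @rdname accessors
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("taskSchedule", function(object) standardGeneric("taskSchedule"))
#' @rdname accessors
#' @export
setGeneric("configSeed", function(object) standardGeneric("configSeed"))

#' @rdname accessors
setMethod("trialData", "EEGTrial", function(object) object@data)
#' @rdname accessors
setMethod("samplingRate", "EEGTrial", function(object) object@samplingRate)
#' @rdname accessors
setMethod("taskCode", "EEGTrial", function(object) object@task)
#' @rdname accessors
setMethod("subjectID", "EEGTrial", function(object) object@subject)
#' @rdname accessors
setMethod("trialIndex", "EEGTrial", function(object) object@trialIndex)
#' @rdname accessors
setMethod("nElectrodes", "EEGTrial", function(object) nrow(object@data))
#' @rdname accessors
setMethod("nSamples", "EEGTrial", function(object) ncol(object@data))

#' @rdname accessors
setMethod("samplingRate", "SyntheticConfig", function(object) object@samplingRate)
#' @rdname accessors
setMethod("nElectrodes", "SyntheticConfig", function(object) object@nElectrodes)
#' @rdname accessors
setMethod("nSamples", "SyntheticConfig",
          function(object) as.integer(round(object@samplingRate * object@trialDuration)))
#' @rdname accessors
setMethod("taskSchedule", "SyntheticConfig", function(object) object@schedule)
#' @rdname accessors
setMethod("configSeed", "SyntheticConfig", function(object) object@seed)

#' Per-electrode generator spec for one task
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param task a task code present in the config.
#' @return data.frame with one row per electrode and columns
#'   \code{noise_sd}, \code{burst_sd}, \code{burst_low}, \code{burst_high}.
#' @export
taskSpec <- function(config, task) {
  stopifnot(is(config, "SyntheticConfig"))
  if (!task %in% names(config@taskSpecs)) {
    stop(sprintf("no generator spec for task '%s'", task), call. = FALSE)
  }
  config@taskSpecs[[task]]
}
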