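#' Hjorth Activity of a signal
#'
#' Activity is the power of the signal: the variance of the amplitude about
#' its mean. The population denominator (1/N) is used, so
#' \code{hjorthActivity(c * x) == c^2 * hjorthActivity(x)} holds exactly.
#'
#' @param x numeric vector of at least 2 finite samples.
#' @return Signal variance in squared input units (microvolts^2 for EEG).
#' @examples
#' hjorthActivity(c(0, 2, 0, 2)) # deviations +/-1 about mean 1 -> 1
#' @seealso \code{\link{hjorthMobility}}, \code{\link{hjorthComplexity}},
#'   \code{\link{hjorthTriple}}
#' @export
hjorthActivity <- function(x) {
  .checkSignal(x, min_len = 2L)
  mean((x - mean(x))^2)
}

#' First difference of a signal
#'
#' The discrete stand-in for the derivative: \code{d[i] = x[i+1] - x[i]}.
#' The result has one element fewer than the input.
#'
#' @param x numeric vector of at least 2 finite samples.
#' @return Numeric vector of length \code{length(x) - 1}.
#' @examples
#' firstDifference(c(1, 2, 4)) # c(1, 2)
#' @export
firstDifference <- function(x) {
  .checkSignal(x, min_len = 2L)
  x[-1L] - x[-length(x)]
}

#' Hjorth Mobility of a signal
#'
#' Mobility is the square root of the ratio of the variance of the first
#' difference of the signal to the variance of the signal itself, a proxy for
#' mean frequency. Both variances use the population denominator over the
#' elements actually present. Mobility is per-sample and dimensionless; for
#' a sampled sinusoid of frequency f at sampling rate fs it equals
#' \code{2 * sin(pi * f / fs)} in the long-signal limit, and it is bounded by
#' 2 (attained by the Nyquist oscillation).
#'
#' @param x numeric vector of at least 3 finite samples with nonzero variance.
#' @return Dimensionless mobility in [0, 2].
#' @examples
#' t <- seq_len(500) - 1
#' x <- sin(2 * pi * 10 * t / 125)
#' hjorthMobility(x) # ~ 2 * sin(pi * 10 / 125) = 0.49738
#' @export
hjorthMobility <- function(x) {
  .checkSignal(x, min_len = 3L)
  a <- mean((x - mean(x))^2)
  if (a == 0) {
    stop("degenerate signal: zero variance, mobility undefined", call. = FALSE)
  }
  d <- x[-1L] - x[-length(x)]
  sqrt(mean((d - mean(d))^2) / a)
}

#' Hjorth Complexity of a signal
#'
#' Complexity is the Mobility of the first difference of the signal divided
#' by the Mobility of the signal: a measure of how much the waveform departs
#' from a pure sinusoid (for which complexity is 1). It is scale-invariant
#' and, by the Cauchy-Schwarz inequality on spectral moments, never less
#' than 1 for a non-degenerate signal (up to floating-point error).
#'
#' @param x numeric vector of at least 4 finite samples; both the signal and
#'   its first difference must have nonzero variance.
#' @return Dimensionless complexity, >= 1 up to numerical tolerance.
#' @examples
#' set.seed(1)
#' hjorthComplexity(rnorm(10000)) # ~ sqrt(3/2) for white noise
#' @export
hjorthComplexity <- function(x) {
  .checkSignal(x, min_len = 4L)
  d <- x[-1L] - x[-length(x)]
  if (mean((x - mean(x))^2) == 0 || mean((d - mean(d))^2) == 0) {
    stop("degenerate signal: zero variance, complexity undefined", call. = FALSE)
  }
  hjorthMobility(d) / hjorthMobility(x)
}

#' All three Hjorth parameters of a signal
#'
#' Computes Activity, Mobility and Complexity in one call. In strict mode
#' (the default for scalar use) a degenerate signal -- zero variance in the
#' signal or its first difference -- is an error. In bulk mode
#' (\code{strict = FALSE}, used by \code{\link{windowedHjorth}} and
#' \code{\link{buildFeatureTable}}) the undefined parameters are returned as
#' \code{NA} with a warning, so a single flat channel cannot abort a
#' dataset-scale run; activity itself is always defined.
#'
#' @param x numeric vector of at least 4 finite samples.
#' @param strict logical; error on degenerate signals (default TRUE) or
#'   return the \code{NA} missing-value sentinel with a warning.
#' @return Named numeric vector \code{c(activity=, mobility=, complexity=)}.
#' @examples
#' hjorthTriple(sin(2 * pi * 10 * (0:499) / 125))
#' hjorthTriple(rep(5, 10), strict = FALSE) # activity 0, rest NA
#' @export
hjorthTriple <- function(x, strict = TRUE) {
  .checkSignal(x, min_len = 4L)
  a <- mean((x - mean(x))^2)
  d <- x[-1L] - x[-length(x)]
  vd <- mean((d - mean(d))^2)
  if (a == 0 || vd == 0) {
    if (strict) {
      stop("degenerate signal: zero variance, mobility/complexity undefined",
           call. = FALSE)
    }
    warning("degenerate signal: returning NA mobility/complexity",
            call. = FALSE)
    m <- if (a == 0) NA_real_ else sqrt(vd / a)
    return(c(activity = a, mobility = m, complexity = NA_real_))
  }
  m <- sqrt(vd / a)
  dd <- d[-1L] - d[-length(d)]
  md <- sqrt(mean((dd - mean(dd))^2) / vd)
  c(activity = a, mobility = m, complexity = md / m)
}

#' Windowed Hjorth parameter series for a trial
#'
#' Slides a window of \code{windowLength} samples along every electrode of a
#' trial in steps of \code{hop} samples and computes the Hjorth triple in
#' each fully contained window; a trailing partial window is discarded.
#' Window starts are reported as 0-based sample offsets. This produces the
#' per-electrode feature series used to inspect how activity, mobility and
#' complexity evolve within a recording. Degenerate windows yield \code{NA}
#' mobility/complexity (bulk mode) with a warning.
#'
#' @param trial an \code{\linkS4class{EEGTrial}}.
#' @param windowLength window length in samples, between 4 and
#'   \code{nSamples(trial)}. Default 125 (1 s at 125 Hz).
#' @param hop step between window starts in samples, >= 1. Default 25.
#' @return data.frame with columns \code{electrode}, \code{window_start},
#'   \code{activity}, \code{mobility}, \code{complexity}, plus attributes
#'   \code{window_length} and \code{hop}.
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 1)
#' tr <- generateTrial(cfg, "CRH", "S01", 1)
#' hs <- windowedHjorth(tr, 125, 125)
#' nrow(hs) # 16 electrodes x 4 windows
#' @export
windowedHjorth <- function(trial, windowLength = 125L, hop = 25L) {
  stopifnot(is(trial, "EEGTrial"))
  windowLength <- as.integer(windowLength)
  hop <- as.integer(hop)
  ns <- nSamples(trial)
  if (windowLength < 4L) {
    stop("windowLength must be at least 4 samples", call. = FALSE)
  }
  if (windowLength > ns) {
    stop(sprintf("windowLength (%d) exceeds trial length (%d samples)",
                 windowLength, ns), call. = FALSE)
  }
  if (hop < 1L) stop("hop must be >= 1", call. = FALSE)
  starts <- seq.int(0L, ns - windowLength, by = hop)
  dat <- trialData(trial)
  ne <- nrow(dat)
  out <- vector("list", ne * length(starts))
  k <- 0L
  for (e in seq_len(ne)) {
    for (s in starts) {
      k <- k + 1L
      h <- hjorthTriple(dat[e, (s + 1L):(s + windowLength)], strict = FALSE)
      out[[k]] <- c(e, s, h)
    }
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("electrode", "window_start", "activity", "mobility",
                  "complexity")
  res$electrode <- as.integer(res$electrode)
  res$window_start <- as.integer(res$window_start)
  attr(res, "window_length") <- windowLength
  attr(res, "hop") <- hop
  res
}

# shared input validation for signal vectors
.checkSignal <- function(x, min_len) {
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  if (length(x) < min_len) {
    stop(sprintf("signal must have at least %d samples, got %d",
                 min_len, length(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}
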