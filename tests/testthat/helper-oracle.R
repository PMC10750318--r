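# Independent direct transcription of the Hjorth definitions, written as
# explicit sums with no code shared with the package implementation.
# Population denominator over the entries present, for both the signal and
# its difference vectors.
hjorthOracle <- function(x) {
  N <- length(x)
  am_x <- sum(x) / N
  var_x <- sum((x - am_x)^2) / N

  d <- numeric(N - 1L)
  for (i in seq_len(N - 1L)) d[i] <- x[i + 1L] - x[i]
  M <- length(d)
  am_d <- sum(d) / M
  var_d <- sum((d - am_d)^2) / M

  dd <- numeric(M - 1L)
  for (i in seq_len(M - 1L)) dd[i] <- d[i + 1L] - d[i]
  K <- length(dd)
  am_dd <- sum(dd) / K
  var_dd <- sum((dd - am_dd)^2) / K

  mob_x <- sqrt(var_d / var_x)
  mob_d <- sqrt(var_dd / var_d)
  c(activity = var_x, mobility = mob_x, complexity = mob_d / mob_x)
}

# periodogram-based fraction of total power outside a band
outOfBandPowerFraction <- function(y, fs, low, high) {
  n <- length(y)
  p <- Mod(stats::fft(y))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f <= fs / 2
  p <- p[keep]
  f <- f[keep]
  inband <- f >= low & f <= high
  sum(p[!inband]) / sum(p)
}

# ratio of mean out-of-band PSD density to mean in-band density
outOfBandDensityRatio <- function(y, fs, low, high) {
  n <- length(y)
  p <- Mod(stats::fft(y))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f <= fs / 2
  p <- p[keep]
  f <- f[keep]
  inband <- f >= low & f <= high
  mean(p[!inband]) / mean(p[inband])
}

sineSignal <- function(f, fs = 125, n = 500, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * f * (seq_len(n) - 1L) / fs + phase)
}

# small 4-electrode config with a short schedule for fast pipeline tests
tinyConfig <- function(seed, schedule = c("BEO", "Rest", "CRH", "Rest",
                                          "CLH", "Rest")) {
  cfg <- defaultSyntheticConfig(seed = seed, nElectrodes = 4L)
  SyntheticConfig(nElectrodes = 4L, taskSpecs = cfg@taskSpecs,
                  schedule = schedule, seed = seed)
}
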