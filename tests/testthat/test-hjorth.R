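test_that("activity matches hand-evaluated variance and handles errors", {
  expect_equal(hjorthActivity(c(5, 5, 5, 5)), 0)
  # mean 1, deviations +/-1, mean square 1
  expect_equal(hjorthActivity(c(0, 2, 0, 2)), 1)
  expect_error(hjorthActivity(c(1)), "at least 2")
  expect_error(hjorthActivity(c(1, NA, 3)), "non-finite")
})

test_that("first difference is the consecutive-sample difference", {
  expect_equal(firstDifference(c(1, 2, 4)), c(1, 2))
  expect_equal(firstDifference(rep(3, 7)), rep(0, 6))
  expect_length(firstDifference(c(2, 9)), 1L)
  expect_error(firstDifference(5), "at least 2")
})

test_that("mobility matches analytic values for canonical signals", {
  # Nyquist oscillation: Var(d) = 4 Var(x) up to an O(1/n) edge effect
  alt <- rep(c(1, -1), 250)
  expect_lt(abs(hjorthMobility(alt) - 2), 1e-2)
  # sampled sinusoid: mobility -> 2 sin(pi f / fs)
  expect_equal(hjorthMobility(sineSignal(10)), 2 * sin(pi * 10 / 125),
               tolerance = 1e-3)
  # iid noise: Var(d) = 2 sigma^2, mobility -> sqrt(2)
  set.seed(11)
  expect_equal(hjorthMobility(rnorm(1e5)), sqrt(2), tolerance = 0.01)
  expect_error(hjorthMobility(rep(4, 10)), "degenerate")
})

test_that("complexity matches analytic values for canonical signals", {
  # a sinusoid's first difference is a sinusoid at the same frequency
  expect_equal(hjorthComplexity(sineSignal(10)), 1, tolerance = 1e-2)
  # iid noise: Var(dd) = 6 sigma^2 => complexity -> sqrt(3/2)
  set.seed(12)
  expect_equal(hjorthComplexity(rnorm(1e5)), sqrt(3 / 2), tolerance = 0.01)
  expect_error(hjorthComplexity(rep(0, 10)), "degenerate")
})

test_that("sinusoid mobility law holds across the acquisition band", {
  for (f in c(5, 10, 20, 40)) {
    expect_equal(hjorthMobility(sineSignal(f)), 2 * sin(pi * f / 125),
                 tolerance = 1e-3, label = sprintf("f = %g Hz", f))
  }
})

test_that("hjorthTriple composes the three parameters and honours modes", {
  set.seed(21)
  x <- rnorm(400)
  tr <- hjorthTriple(x)
  expect_equal(unname(tr), unname(c(hjorthActivity(x), hjorthMobility(x),
                                    hjorthComplexity(x))))
  # sinusoid moments: activity A^2/2, mobility 2 sin(pi f/fs), complexity ~1
  s <- sineSignal(10, amplitude = 3)
  trs <- hjorthTriple(s)
  expect_equal(trs[["activity"]], 9 / 2, tolerance = 1e-3)
  expect_equal(trs[["mobility"]], 2 * sin(pi * 10 / 125), tolerance = 1e-3)
  expect_equal(trs[["complexity"]], 1, tolerance = 1e-2)
  # degenerate contract: strict errors, bulk yields the NA sentinel
  expect_error(hjorthTriple(rep(5, 10)), "degenerate")
  expect_warning(flat <- hjorthTriple(rep(5, 10), strict = FALSE),
                 "degenerate")
  expect_equal(flat[["activity"]], 0)
  expect_true(is.na(flat[["mobility"]]) && is.na(flat[["complexity"]]))
})

test_that("implementation agrees with the independent direct transcription", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 50))
    got <- hjorthTriple(x)
    want <- hjorthOracle(x)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("scale and shift equivariance hold to near machine precision", {
  set.seed(41)
  for (i in 1:50) {
    x <- cumsum(rnorm(sample(50:300, 1)))
    expect_equal(hjorthActivity(3 * x), 9 * hjorthActivity(x),
                 tolerance = 1e-12)
    expect_equal(hjorthMobility(7 * x + 11), hjorthMobility(x),
                 tolerance = 1e-12)
    expect_equal(hjorthComplexity(7 * x + 11), hjorthComplexity(x),
                 tolerance = 1e-12)
  }
})

test_that("mobility and complexity respect their spectral bounds", {
  set.seed(51)
  fixtures <- c(
    lapply(1:40, function(i) rnorm(sample(10:500, 1))),
    lapply(1:40, function(i) cumsum(rnorm(sample(10:500, 1)))),
    lapply(1:20, function(i) sineSignal(runif(1, 1, 60), n = 300) +
                             rnorm(300, sd = 0.2)),
    lapply(1:20, function(i) {
      bandlimitedNoise(512, sd = runif(1, 0.5, 20), low = runif(1, 2, 10),
                       high = runif(1, 20, 55), fs = 125)
    })
  )
  for (x in fixtures) {
    m <- hjorthMobility(x)
    expect_gte(m, 0)
    expect_lte(m, 2)
    expect_gte(hjorthComplexity(x), 1 - 1e-9)
  }
})

test_that("windowed extraction covers exactly the full windows", {
  cfg <- tinyConfig(seed = 3)
  tr <- generateTrial(cfg, "CRH", "S01", 1)
  w <- windowedHjorth(tr, 125, 125)
  expect_equal(nrow(w), 4 * 4) # 4 electrodes x 4 windows
  expect_equal(sort(unique(w$window_start)), c(0L, 125L, 250L, 375L))

  w2 <- windowedHjorth(tr, 125, 25)
  expect_equal(nrow(w2), 4 * 16) # floor((500-125)/25)+1 = 16 windows
  expect_true(all(diff(w2$window_start[w2$electrode == 1]) == 25L))

  # single full-trial window equals the plain triple
  w3 <- windowedHjorth(tr, 500, 1)
  expect_equal(nrow(w3), 4)
  expect_equal(unname(unlist(w3[1, c("activity", "mobility", "complexity")])),
               unname(hjorthTriple(trialData(tr)[1, ])))

  expect_error(windowedHjorth(tr, 501), "exceeds")
  expect_error(windowedHjorth(tr, 125, 0), "hop")
})
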