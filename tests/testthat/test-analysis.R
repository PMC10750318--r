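makeFeatureFixture <- function(n = 200, seed = 1) {
  # synthetic feature table with independent columns, no generator involved
  set.seed(seed)
  data.frame(subject = "S01",
             task = sample(c("Rest", "CRH"), n, replace = TRUE),
             trial = seq_len(n), electrode = rep(1:4, length.out = n),
             window_start = 0L,
             activity = rexp(n, 1 / 100), mobility = runif(n, 0.3, 1.4),
             complexity = 1 + rexp(n, 2))
}

test_that("feature table has one row per trial, electrode and window", {
  cfg <- tinyConfig(seed = 20)
  trs <- lapply(1:2, function(i) generateTrial(cfg, "CRH", "S01", i))
  ft <- buildFeatureTable(trs, 125, 125)
  expect_equal(nrow(ft), 2 * 4 * 4)
  expect_false(any(duplicated(ft[c("subject", "task", "trial", "electrode",
                                   "window_start")])))
  # full-trial mode: one row per (trial, electrode)
  ft1 <- buildFeatureTable(trs, 500, 500)
  expect_equal(nrow(ft1), 2 * 4)
  expect_error(buildFeatureTable(list()), "no trials")
})

test_that("a flat channel yields counted NA-sentinel rows, not a failure", {
  cfg <- tinyConfig(seed = 21)
  tr <- generateTrial(cfg, "CRH", "S01", 1)
  dat <- trialData(tr)
  dat[3, ] <- 2.5 # one dead electrode
  flat <- EEGTrial(dat, task = "CRH", subject = "S01")
  expect_message(ft <- buildFeatureTable(list(flat, tr), 125, 125),
                 "4 degenerate window row")
  bad <- ft[is.na(ft$mobility), ]
  expect_equal(nrow(bad), 4) # 4 windows of the dead electrode, trial 1 only
  expect_true(all(bad$electrode == 3))
  expect_true(all(bad$activity == 0))
})

test_that("feature correlation obeys its matrix contract", {
  ft <- makeFeatureFixture(200)
  cm <- featureCorrelation(ft)
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(attr(cm, "method"), "pearson")
  # duplicated feature -> perfect correlation
  dup <- ft
  dup$complexity <- dup$mobility
  expect_equal(featureCorrelation(dup)["mobility", "complexity"], 1)
})

test_that("independent features decorrelate at large n", {
  ft <- makeFeatureFixture(10000, seed = 33)
  cm <- featureCorrelation(ft)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.05))
})

test_that("correlation rejects undersized and degenerate input", {
  ft <- makeFeatureFixture(10)
  ft$mobility[1:8] <- NA
  expect_error(suppressMessages(featureCorrelation(ft)), "at least 3")
  ft2 <- makeFeatureFixture(10)
  ft2$activity <- 5
  expect_error(featureCorrelation(ft2), "activity")
})

test_that("clustering is deterministic and row-order invariant", {
  ft <- makeFeatureFixture(300, seed = 44)
  cl1 <- clusterFeatures(ft, k = 3, seed = 5)
  cl2 <- clusterFeatures(ft, k = 3, seed = 5)
  expect_identical(cl1$assignment, cl2$assignment)
  expect_identical(cl1$agreement, cl2$agreement)
  # shuffled input rows: canonical ordering restores the same result
  perm <- ft[sample(nrow(ft)), ]
  cl3 <- clusterFeatures(perm, k = 3, seed = 5)
  expect_identical(cl3$assignment, cl1$assignment)
  expect_identical(cl3$agreement, cl1$agreement)
  expect_true(all(cl1$assignment %in% seq_len(3)))
  expect_gte(cl1$agreement, -1)
  expect_lte(cl1$agreement, 1)
})

test_that("clustering edge cases behave as documented", {
  ft <- makeFeatureFixture(12)
  expect_error(clusterFeatures(ft, k = 1, seed = 1), "k must be >= 2")
  expect_error(clusterFeatures(ft, k = 13, seed = 1), "exceeds")
  # k = number of rows: every row its own cluster, agreement finite
  cl <- clusterFeatures(ft, k = 12, seed = 1)
  expect_equal(sort(unique(cl$assignment)), 1:12)
  expect_true(is.finite(cl$agreement))
})

test_that("default Rest vs CRH separates almost perfectly at k = 2", {
  cfg <- defaultSyntheticConfig(seed = 55)
  trs <- c(lapply(1:10, function(i) generateTrial(cfg, "Rest", "S01", i)),
           lapply(11:20, function(i) generateTrial(cfg, "CRH", "S01", i)))
  ft <- buildFeatureTable(trs, 500, 500)
  cl <- clusterFeatures(ft, k = 2, seed = 3)
  expect_gte(cl$agreement, 0.9)
})

test_that("8-task clustering beats the permutation null", {
  cfg <- defaultSyntheticConfig(seed = 66)
  trs <- generateSession(cfg, "S01")
  ft <- buildFeatureTable(trs, 500, 500)
  cl <- clusterFeatures(ft, k = 8, seed = 9)
  set.seed(10)
  null <- replicate(200, {
    mclust::adjustedRandIndex(cl$assignment, sample(ft$task))
  })
  expect_gt(cl$agreement, stats::quantile(null, 0.95))
})

test_that("task contrasts summarize per-electrode effects", {
  cfg <- defaultSyntheticConfig(seed = 77)
  trs <- c(lapply(1:15, function(i) generateTrial(cfg, "Rest", "S01", i)),
           lapply(16:30, function(i) generateTrial(cfg, "CRH", "S01", i)))
  ft <- buildFeatureTable(trs, 500, 500)
  ctr <- taskContrast(ft, "CRH", "Rest")
  act <- ctr[ctr$feature == "activity", ]
  expect_equal(nrow(act), 16)
  expect_true(all(act$mean_diff > 0)) # movement raises power everywhere
  expect_true(all(act$ratio > 1))
  # Rest amplitude is highest on electrodes 14 and 15 under the defaults
  expect_setequal(act$electrode[act$high_amplitude_b], c(14L, 15L))
  # identical tasks: zero differences
  same <- taskContrast(ft, "Rest", "Rest")
  expect_true(all(same$mean_diff == 0))
  expect_error(taskContrast(ft, "CRH", "PLF"), "PLF")
})

test_that("single-observation groups flag the effect size as undefined", {
  cfg <- tinyConfig(seed = 88)
  trs <- list(generateTrial(cfg, "Rest", "S01", 1),
              generateTrial(cfg, "CRH", "S01", 2))
  ft <- buildFeatureTable(trs, 500, 500)
  ctr <- taskContrast(ft, "CRH", "Rest")
  expect_true(all(is.na(ctr$cohen_d)))
  expect_true(all(is.finite(ctr$mean_diff)))
})

test_that("feature tables round-trip through CSV bit for bit", {
  cfg <- tinyConfig(seed = 90)
  trs <- lapply(1:2, function(i) generateTrial(cfg, "CRH", "S01", i))
  ft <- buildFeatureTable(trs, 125, 125)
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  ft2 <- readFeatureTable(f)
  expect_identical(ft2$activity, ft$activity)
  expect_identical(ft2$mobility, ft$mobility)
  expect_identical(ft2$complexity, ft$complexity)
  expect_equal(ft2$task, ft$task)
})
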