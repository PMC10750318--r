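#' Build the long-form Hjorth feature table
#'
#' Runs windowed Hjorth extraction over a list of trials and stacks the
#' results into one long table with one row per (trial, electrode, window).
#' Setting \code{windowLength} to the trial length (with any hop) gives
#' full-trial mode: one row per (trial, electrode). Degenerate windows keep
#' their rows with \code{NA} mobility/complexity; a message reports how many
#' such rows were produced.
#'
#' @param trials non-empty list of \code{\linkS4class{EEGTrial}} objects with
#'   identical sampling rates and sample counts.
#' @param windowLength window length in samples (default 125).
#' @param hop hop between windows in samples (default 25).
#' @return data.frame with columns \code{subject}, \code{task}, \code{trial},
#'   \code{electrode}, \code{window_start}, \code{activity}, \code{mobility},
#'   \code{complexity}; attributes \code{window_length} and \code{hop}.
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 1)
#' trs <- lapply(1:2, function(i) generateTrial(cfg, "Rest", "S01", i))
#' ft <- buildFeatureTable(trs, 125, 125)
#' nrow(ft) # 2 trials x 16 electrodes x 4 windows
#' @export
buildFeatureTable <- function(trials, windowLength = 125L, hop = 25L) {
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  stopifnot(all(vapply(trials, is, logical(1), "EEGTrial")))
  fs <- vapply(trials, samplingRate, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("trials have inconsistent sampling rates", call. = FALSE)
  }
  ns <- vapply(trials, nSamples, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("trials have inconsistent sample counts", call. = FALSE)
  }
  pieces <- withCallingHandlers(
    lapply(trials, function(tr) {
      hs <- windowedHjorth(tr, windowLength, hop)
      data.frame(subject = subjectID(tr), task = taskCode(tr),
                 trial = trialIndex(tr), hs)
    }),
    warning = function(w) {
      if (grepl("degenerate signal", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  n_na <- sum(!stats::complete.cases(out[c("mobility", "complexity")]))
  if (n_na > 0L) {
    message(sprintf("feature table: %d degenerate window row(s) carry NA mobility/complexity",
                    n_na))
  }
  attr(out, "window_length") <- as.integer(windowLength)
  attr(out, "hop") <- as.integer(hop)
  out
}

.featureCols <- c("activity", "mobility", "complexity")

#' Pearson correlation among the three Hjorth features
#'
#' Computes the 3 x 3 Pearson correlation matrix of activity, mobility and
#' complexity over the complete rows of a feature table (rows carrying the
#' NA missing sentinel are dropped, with a message).
#'
#' @param table a feature table from \code{\link{buildFeatureTable}}.
#' @param method correlation method passed to \code{\link[stats]{cor}}
#'   (default \code{"pearson"}); recorded on the result.
#' @return Symmetric 3 x 3 correlation matrix with unit diagonal and a
#'   \code{method} attribute.
#' @export
featureCorrelation <- function(table, method = "pearson") {
  stopifnot(all(.featureCols %in% names(table)))
  x <- table[, .featureCols]
  ok <- stats::complete.cases(x)
  if (sum(!ok) > 0L) {
    message(sprintf("correlation: dropping %d incomplete row(s)", sum(!ok)))
  }
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 3L) {
    stop("need at least 3 complete rows for a correlation", call. = FALSE)
  }
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s — correlation undefined",
                 paste(.featureCols[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  m <- stats::cor(as.matrix(x), method = method)
  attr(m, "method") <- method
  m
}

#' Cluster feature-table rows and score agreement with task labels
#'
#' Rows are put in a canonical order (subject, task, trial, electrode,
#' window start), incomplete rows are dropped (count messaged), the three
#' features are standardized to zero mean and unit variance per column, and
#' k-means with \code{nstart} restarts is run under a fixed seed, so the
#' result is reproducible and independent of input row order. Agreement
#' between the partition and the rows' task labels is scored with the
#' adjusted Rand index.
#'
#' @param table a feature table from \code{\link{buildFeatureTable}}.
#' @param k number of clusters, >= 2 and at most the number of complete rows.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 10).
#' @return Object of class \code{"ClusterResult"}: a list with
#'   \code{assignment} (integer cluster per retained row, values in 1..k),
#'   \code{rows} (canonical-order key of the retained rows), \code{k},
#'   \code{agreement} (ARI vs task labels), \code{seed}, \code{nDropped},
#'   and \code{method}.
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 1)
#' trs <- c(lapply(1:5, function(i) generateTrial(cfg, "Rest", "S01", i)),
#'          lapply(6:10, function(i) generateTrial(cfg, "CRH", "S01", i)))
#' ft <- buildFeatureTable(trs, 500, 500)
#' clusterFeatures(ft, k = 2, seed = 7)$agreement
#' @export
clusterFeatures <- function(table, k, seed, nstart = 10L) {
  stopifnot(all(.featureCols %in% names(table)))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  ord <- order(table$subject, table$task, table$trial, table$electrode,
               table$window_start)
  table <- table[ord, , drop = FALSE]
  ok <- stats::complete.cases(table[, .featureCols])
  if (sum(!ok) > 0L) {
    message(sprintf("clustering: dropping %d incomplete row(s)", sum(!ok)))
  }
  tab <- table[ok, , drop = FALSE]
  if (nrow(tab) < k) {
    stop(sprintf("k = %d exceeds the %d complete rows", k, nrow(tab)),
         call. = FALSE)
  }
  x <- scale(as.matrix(tab[, .featureCols]))
  # a constant column (single repeated row value) would scale to NaN
  x[, attr(x, "scaled:scale") == 0] <- 0
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (k == nrow(x)) {
    # degenerate partition: every row is its own cluster
    km <- list(cluster = seq_len(nrow(x)))
  } else {
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
  }
  structure(list(
    assignment = as.integer(km$cluster),
    rows = tab[, c("subject", "task", "trial", "electrode", "window_start")],
    k = k,
    agreement = mclust::adjustedRandIndex(km$cluster, tab$task),
    seed = as.integer(seed),
    nDropped = sum(!ok),
    method = sprintf("kmeans(nstart=%d) on standardized features", nstart)
  ), class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k = %d over %d rows (%d dropped), seed %d\n",
              x$k, length(x$assignment), x$nDropped, x$seed))
  cat(sprintf("  %s\n  adjusted Rand index vs task labels: %.4f\n",
              x$method, x$agreement))
  invisible(x)
}

#' Per-electrode contrast between two tasks
#'
#' Summarizes, per electrode and Hjorth feature, the difference between two
#' tasks: mean difference (a - b), the ratio of means for activity, and
#' Cohen's d as a standardized effect size (NA when either task has fewer
#' than two observations for that electrode/feature). Electrodes whose mean
#' activity under \code{taskB} ranks in the top two are flagged
#' (\code{high_amplitude_b}) — with \code{taskB = "Rest"} under the default
#' generator these are electrodes 14 and 15.
#'
#' @param table a feature table from \code{\link{buildFeatureTable}}.
#' @param taskA,taskB task codes present in the table.
#' @return data.frame with columns \code{electrode}, \code{feature},
#'   \code{mean_a}, \code{mean_b}, \code{mean_diff}, \code{ratio} (activity
#'   only, NA otherwise), \code{cohen_d}, \code{high_amplitude_b}.
#' @export
taskContrast <- function(table, taskA, taskB) {
  for (tk in c(taskA, taskB)) {
    if (!tk %in% table$task) {
      stop(sprintf("task '%s' not present in the feature table", tk),
           call. = FALSE)
    }
  }
  a <- table[table$task == taskA, , drop = FALSE]
  b <- table[table$task == taskB, , drop = FALSE]
  electrodes <- sort(unique(table$electrode))
  actB <- vapply(electrodes, function(e) {
    mean(b$activity[b$electrode == e], na.rm = TRUE)
  }, numeric(1))
  topB <- electrodes[order(actB, decreasing = TRUE)[seq_len(min(2L, length(electrodes)))]]
  rows <- list()
  for (e in electrodes) {
    for (f in .featureCols) {
      va <- a[[f]][a$electrode == e]
      vb <- b[[f]][b$electrode == e]
      va <- va[!is.na(va)]
      vb <- vb[!is.na(vb)]
      ma <- mean(va)
      mb <- mean(vb)
      d <- if (length(va) >= 2L && length(vb) >= 2L) {
        sp <- sqrt(((length(va) - 1) * stats::var(va) +
                    (length(vb) - 1) * stats::var(vb)) /
                   (length(va) + length(vb) - 2))
        if (sp > 0) (ma - mb) / sp else NA_real_
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, feature = f, mean_a = ma, mean_b = mb,
        mean_diff = ma - mb,
        ratio = if (f == "activity") ma / mb else NA_real_,
        cohen_d = d,
        high_amplitude_b = e %in% topB)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "task_a") <- taskA
  attr(out, "task_b") <- taskB
  out
}

#' Write / read a feature table as CSV
#'
#' The on-disk layout is
#' \code{subject,task,trial,electrode,window_start,activity,mobility,complexity}
#' with features printed at 17 significant digits for bit-exact round trips.
#'
#' @param table feature table from \code{\link{buildFeatureTable}}.
#' @param path file path.
#' @return \code{writeFeatureTable}: the path, invisibly;
#'   \code{readFeatureTable}: the feature table data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  cols <- c("subject", "task", "trial", "electrode", "window_start",
            .featureCols)
  stopifnot(all(cols %in% names(table)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  writeLines(paste(table$subject, table$task, table$trial, table$electrode,
                   table$window_start, fmt(table$activity),
                   fmt(table$mobility), fmt(table$complexity), sep = ","),
             con)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, colClasses = c(
    subject = "character", task = "character", trial = "integer",
    electrode = "integer", window_start = "integer", activity = "numeric",
    mobility = "numeric", complexity = "numeric"))
}
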