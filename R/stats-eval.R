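#' AUC-ROC via the rank-sum identity
#'
#' The probability that a randomly chosen active outscores a randomly chosen
#' inactive, computed as U / (n1 * n0) from the Mann-Whitney U of mid-ranks;
#' tied pairs contribute 1/2. With `higherIsBetter = FALSE` the orientation
#' is flipped so an informative metric still yields AUC > 0.5.
#'
#' @param scores numeric scores, no missing values.
#' @param labels 0/1 (or logical) activity labels; both classes must be
#'   present.
#' @param higherIsBetter orientation flag of the metric.
#' @return AUC in \[0, 1\].
#' @export
aucRoc <- function(scores, labels, higherIsBetter = TRUE) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                       # mid-ranks: ties count 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (higherIsBetter) auc else 1 - auc
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. A constant input vector leaves the
#' correlation undefined; `NA` is returned with a message rather than an
#' error so metric pairs can be tabulated wholesale.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Spearman's rho, or `NA`.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    message("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The probability-mass definition: the sum of hypergeometric probabilities
#' of all tables with the observed margins that are at most as probable as
#' the observed table (the mainstream-software convention).
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise) of non-negative
#'   integer counts; rows = filter pass/fail, columns = active/inactive.
#' @return p-value in (0, 1\].
#' @examples
#' fisherExactTwoTailed(matrix(c(53, 19, 30, 42), 2, byrow = TRUE))
#' @export
fisherExactTwoTailed <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  stopifnot(dim(table) == c(2L, 2L))
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("table is empty")
  fisher.test(table)$p.value
}

#' Top (or bottom) percentile threshold of a calibration score set
#'
#' The cutoff such that the stated top fraction of the calibration scores is
#' at or above it, using the order statistic with lower-value interpolation:
#' the k-th largest score with `k = max(1, floor(n * p / 100))`. This is the
#' stringent reading -- at most p\% of the calibration set passes (never
#' zero). `direction = "bottom"` mirrors the rule at the low end.
#'
#' @param scores numeric calibration scores (>= 1).
#' @param percentile p in (0, 100\].
#' @param direction `"top"` (default) or `"bottom"`.
#' @return the cutoff score.
#' @examples
#' percentileThreshold(1:10, 10)  # 10: only the best decile passes
#' @export
percentileThreshold <- function(scores, percentile, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) >= 1L, !anyNA(scores))
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  n <- length(scores)
  k <- max(1L, floor(n * percentile / 100))
  if (direction == "top") sort(scores, decreasing = TRUE)[k]
  else sort(scores)[k]
}

#' Two-metric quadrant deconvolution
#'
#' Splits the (score A, score B) plane at the two medians and reports, per
#' quadrant, the count, number of actives, active fraction and the
#' within-quadrant Spearman correlation of the two scores. Points exactly on
#' a median boundary belong to the upper/right quadrant.
#'
#' @param scoresA,scoresB equal-length numeric score vectors (A is the
#'   x-axis, B the y-axis).
#' @param labels 0/1 activity labels.
#' @return list with `median_a`, `median_b`, `overall_spearman`, and
#'   `quadrants`, a data.frame with rows `lower_left`, `lower_right`,
#'   `upper_left`, `upper_right`.
#' @export
quadrantAnalysis <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scoresA) == length(scoresB),
            length(scoresA) == length(labels))
  ma <- median(scoresA); mb <- median(scoresB)
  right <- scoresA >= ma; upper <- scoresB >= mb
  quad <- ifelse(upper, ifelse(right, "upper_right", "upper_left"),
                 ifelse(right, "lower_right", "lower_left"))
  qnames <- c("lower_left", "lower_right", "upper_left", "upper_right")
  rows <- lapply(qnames, function(qn) {
    i <- quad == qn
    data.frame(quadrant = qn, n = sum(i), n_active = sum(labels[i]),
               active_fraction = if (any(i)) mean(labels[i]) else NA_real_,
               spearman = if (sum(i) >= 3L &&
                              sd(scoresA[i]) > 0 && sd(scoresB[i]) > 0)
                 cor(scoresA[i], scoresB[i], method = "spearman")
                 else NA_real_)
  })
  list(median_a = ma, median_b = mb,
       overall_spearman = spearmanRho(scoresA, scoresB),
       quadrants = do.call(rbind, rows))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples (both n <= 20, no ties), otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative as in [stats::wilcox.test()].
#' @return p-value.
#' @export
wilcoxonRankSum <- function(x, y, alternative = "two.sided") {
  exact <- length(x) <= 20L && length(y) <= 20L && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value)
}

#' Welch two-sample t-test
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param alternative as in [stats::t.test()].
#' @return list with `p` and `t`.
#' @export
welchTTest <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  fit <- t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(p = fit$p.value, t = unname(fit$statistic))
}

#' Per-metric evaluation of a score table against activity labels
#'
#' @param scores data.frame with `id` and metric columns (see
#'   [readScoreTable()]); the `orientation` attribute, if present, supplies
#'   per-metric orientation flags (default: higher is better).
#' @param labels data.frame with `id` and `active` (0/1).
#' @return data.frame with one row per metric: AUC-ROC and n used.
#' @export
evaluateMetrics <- function(scores, labels) {
  stopifnot("id" %in% names(scores), all(c("id", "active") %in% names(labels)))
  merged <- merge(scores, labels[, c("id", "active")], by = "id")
  orient <- attr(scores, "orientation")
  metrics <- setdiff(names(scores), "id")
  rows <- lapply(metrics, function(m) {
    ok <- !is.na(merged[[m]])
    hib <- if (!is.null(orient) && m %in% names(orient)) orient[[m]] else TRUE
    auc <- if (sum(merged$active[ok]) %in% c(0L, sum(ok))) NA_real_
           else aucRoc(merged[[m]][ok], merged$active[ok], hib)
    data.frame(metric = m, auc = auc, n = sum(ok), higher_is_better = hib)
  })
  do.call(rbind, rows)
}
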