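#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the average-ranked inputs, with a two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom.  Suited
#' to an ordinal score (heavily tied) against a continuous count.
#'
#' @param scores Ordinal values (e.g. TBE scores 0-4).
#' @param counts Continuous values of the same length (e.g. BALFRBC).
#' @return A list with `rho`, `p_value`, and `n`.
#' @examples
#' spearman_tied(c(0, 0, 1, 2, 2), c(10, 20, 30, 40, 50))
#' @export
spearman_tied <- function(scores, counts) {
  if (length(scores) != length(counts))
    stop("scores and counts must have equal length", call. = FALSE)
  if (length(scores) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(scores) || anyNA(counts))
    stop("missing values are not allowed", call. = FALSE)
  if (length(unique(scores)) < 2)
    stop("scores are constant; correlation undefined", call. = FALSE)
  if (length(unique(counts)) < 2)
    stop("counts are constant; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(as.numeric(scores), as.numeric(counts),
                        method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}

#' One-way repeated-measures analysis of variance
#'
#' Tests for an occasion effect with subject as the blocking factor
#' (`aov(value ~ occasion + Error(subject))`).  With two occasions the F
#' statistic equals the square of the paired t statistic on `(1, n - 1)`
#' degrees of freedom and the p-values coincide.
#'
#' @param value Numeric measurements.
#' @param occasion Occasion index for each measurement.
#' @param subject Subject identifier for each measurement.
#' @return A list of class `"paired_comparison"` with `f_stat`, `p_value`,
#'   `df_num`, `df_den`, `group_means` and `group_sds` (per occasion).
#' @examples
#' repeated_measures_anova(c(100, 200, 300, 110, 190, 310),
#'                         occasion = rep(1:2, each = 3),
#'                         subject  = rep(1:3, times = 2))
#' @export
repeated_measures_anova <- function(value, occasion, subject) {
  stopifnot(length(value) == length(occasion),
            length(value) == length(subject))
  occasion <- factor(occasion)
  subject <- factor(subject)
  tab <- table(subject, occasion)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced design: subject/occasion cell(s) ",
         paste(sprintf("(%s, %s)", rownames(tab)[bad[, 1]],
                       colnames(tab)[bad[, 2]]), collapse = ", "),
         " do not have exactly one value", call. = FALSE)
  }
  if (nlevels(subject) < 2) stop("need at least 2 subjects", call. = FALSE)
  d <- data.frame(value = value, occasion = occasion, subject = subject)
  fit <- stats::aov(value ~ occasion + Error(subject), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(s))
  io <- match("occasion", rn)
  ir <- match("Residuals", rn)
  out <- list(f_stat = s[io, "F value"],
              p_value = s[io, "Pr(>F)"],
              df_num = s[io, "Df"],
              df_den = s[ir, "Df"],
              group_means = tapply(value, occasion, mean),
              group_sds = tapply(value, occasion, stats::sd))
  # no within-subject change at all: both sums of squares vanish and the
  # F ratio is 0/0 numerical noise; report the null result exactly
  tol <- 1e-20 * max(1, sum(value^2))
  if (s[io, "Sum Sq"] <= tol && s[ir, "Sum Sq"] <= tol) {
    out$f_stat <- 0
    out$p_value <- 1
  }
  class(out) <- "paired_comparison"
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$p_value))
  invisible(x)
}

#' Pool per-group summaries into one mean and SD
#'
#' Combines per-group `(n, mean, sd)` triples exactly, using the total
#' sum-of-squares decomposition (within-group plus between-group) with an
#' overall `N - 1` denominator — the mean and SD that raw pooled data would
#' give.
#'
#' @param n,mean,sd Equal-length numeric vectors of group sizes (each >= 2),
#'   group means, and group SDs.
#' @return A list with pooled `n`, `mean`, and `sd`.
#' @examples
#' pooled_summary(n = c(9, 9), mean = c(286, 322), sd = c(160, 194))
#' @export
pooled_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 1)
  if (any(n < 2)) stop("every group must have n >= 2", call. = FALSE)
  N <- sum(n)
  m <- sum(n * mean) / N
  ss_within <- sum((n - 1) * sd^2)
  ss_between <- sum(n * (mean - m)^2)
  list(n = N, mean = m, sd = sqrt((ss_within + ss_between) / (N - 1)))
}

#' Per-score BALFRBC summary table
#'
#' One row per observed TBE score with the count, mean, SD, median, minimum
#' and maximum BALFRBC.
#'
#' @param records Cohort data frame; rows without a TBE score are dropped.
#' @return A data frame with columns `tbe_score`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, ordered by score.
#' @export
score_summary_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("tbe_score", "balf_rbc") %in% names(records)))
  records <- records[!is.na(records$tbe_score), , drop = FALSE]
  if (nrow(records) == 0)
    stop("no records with a TBE score", call. = FALSE)
  scores <- sort(unique(records$tbe_score))
  rows <- lapply(scores, function(s) {
    x <- records$balf_rbc[records$tbe_score == s]
    data.frame(tbe_score = s, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               median = stats::median(x), min = min(x), max = max(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval of BALFRBC values shared by every TBE score
#'
#' The overlap of the per-score ranges: its lower end is the largest
#' per-score minimum and its upper end the smallest per-score maximum.  An
#' empty overlap (lower > upper) is flagged.
#'
#' @param rows A per-score summary table ([score_summary_table()]) with at
#'   least 2 rows, or any data frame with `min` and `max` columns.
#' @return A list with `low`, `high`, and logical `empty`.
#' @examples
#' tab <- data.frame(min = c(102, 199, 775, 801, 4176),
#'                   max = c(41105, 158513, 371530, 1520122, 4605268))
#' overlap_interval(tab)  # low 4176, high 41105
#' @export
overlap_interval <- function(rows) {
  stopifnot(is.data.frame(rows), all(c("min", "max") %in% names(rows)),
            nrow(rows) >= 2)
  low <- max(rows$min)
  high <- min(rows$max)
  list(low = low, high = high, empty = low > high)
}

#' Cross-tabulate the TBE call against the thresholded BALFRBC call
#'
#' Dichotomizes both tests — TBE positive iff score >= 1, BALFRBC positive
#' iff the count reaches `threshold` (>= by default; a strict > rule is
#' available) — and returns the 2x2 table with apparent prevalences.
#'
#' @param records Cohort data frame; every row must carry both tests.
#' @param threshold BALFRBC positivity threshold, cells/uL (> 0).
#' @param strict If `TRUE`, a count equal to the threshold is negative
#'   (`>` rule); default `FALSE` uses the `>=` rule.
#' @return A list of class `"eiph_crosstab"`: cell counts `tp` (both
#'   positive), `fn_balf` (TBE+ only), `fp_tbe_absent` (BALFRBC+ only),
#'   `tn` (both negative), `total`, the positivity `threshold`, and the
#'   apparent prevalence of each test as percentage plus
#'   numerator/denominator (`tbe_prevalence_pct`, `balf_prevalence_pct`,
#'   `tbe_positive`, `balf_positive`, `false_negative_balf_pct`).
#' @examples
#' cohort <- simulate_cohort(default_study_params(), cohort_design(seed = 1))
#' cross_tabulate(cohort[cohort$group == "exercised", ], threshold = 992)
#' @export
cross_tabulate <- function(records, threshold, strict = FALSE) {
  stopifnot(is.data.frame(records), threshold > 0)
  miss <- which(is.na(records$tbe_score) | is.na(records$balf_rbc))
  if (length(miss))
    stop("record(s) missing a test result in row(s) ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  tbe_pos <- records$tbe_score >= 1L
  balf_pos <- if (strict) records$balf_rbc > threshold else
    records$balf_rbc >= threshold
  total <- nrow(records)
  out <- list(tp = sum(tbe_pos & balf_pos),
              fn_balf = sum(tbe_pos & !balf_pos),
              fp_tbe_absent = sum(!tbe_pos & balf_pos),
              tn = sum(!tbe_pos & !balf_pos),
              total = total, threshold = threshold,
              tbe_positive = sum(tbe_pos), balf_positive = sum(balf_pos),
              tbe_prevalence_pct = 100 * sum(tbe_pos) / total,
              balf_prevalence_pct = 100 * sum(balf_pos) / total,
              false_negative_balf_pct = 100 * sum(tbe_pos & !balf_pos) / total)
  class(out) <- "eiph_crosstab"
  out
}

#' @export
print.eiph_crosstab <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn_balf, x$tp + x$fn_balf,
                x$fp_tbe_absent, x$tn, x$fp_tbe_absent + x$tn,
                x$tp + x$fp_tbe_absent, x$fn_balf + x$tn, x$total),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("TBE+", "TBE-", "Total"),
                              c("BALFRBC+", "BALFRBC-", "Total")))
  cat(sprintf("BALFRBC positivity threshold: %g cells/uL\n", x$threshold))
  print(m)
  cat(sprintf("Apparent prevalence: TBE %.0f%% (%d/%d), BALFRBC %.0f%% (%d/%d)\n",
              x$tbe_prevalence_pct, x$tbe_positive, x$total,
              x$balf_prevalence_pct, x$balf_positive, x$total))
  cat(sprintf("BALF false negatives (TBE+ but BALFRBC-): %.1f%% (%d/%d)\n",
              x$false_negative_balf_pct, x$fn_balf, x$total))
  invisible(x)
}
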