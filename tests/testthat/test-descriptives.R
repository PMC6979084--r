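test_that("tied-rank correlation matches hand-computable cases", {
  expect_equal(spearman_tied(0:4, c(1, 2, 3, 4, 5))$rho, 1)
  expect_equal(spearman_tied(0:2, c(30, 20, 10))$rho, -1)
  # ranks (1.5, 1.5, 3, 4.5, 4.5) against (1, 2, 3, 4, 5)
  r <- spearman_tied(c(0, 0, 1, 2, 2), c(10, 20, 30, 40, 50))$rho
  expect_equal(r, 9 / sqrt(90), tolerance = 1e-10)
})

test_that("tied-rank correlation equals the average-rank Pearson oracle", {
  counts_sets <- list(c(5, 1, 4, 2), c(1, 2, 2, 9), c(3, 3, 1, 8))
  grid <- expand.grid(s1 = 0:2, s2 = 0:2, s3 = 0:2, s4 = 0:2)
  for (i in seq_len(nrow(grid))) {
    s <- as.numeric(grid[i, ])
    if (length(unique(s)) < 2) next
    for (cnt in counts_sets) {
      if (length(unique(cnt)) < 2) next
      got <- spearman_tied(s, cnt)
      want <- oracle_spearman(s, cnt)
      expect_equal(got$rho, want$rho, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    }
  }
  # longer inputs with heavy ties
  set.seed(42)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    s <- sample(0:3, n, replace = TRUE)
    cnt <- sample(1:6, n, replace = TRUE)
    if (length(unique(s)) < 2 || length(unique(cnt)) < 2) next
    got <- spearman_tied(s, cnt)
    want <- oracle_spearman(s, cnt)
    expect_equal(got$rho, want$rho, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  }
})

test_that("degenerate correlation inputs produce named errors", {
  expect_error(spearman_tied(0:3, 1:3), "equal length")
  expect_error(spearman_tied(c(1, 1, 1), c(1, 2, 3)), "scores")
  expect_error(spearman_tied(c(0, 1, 2), c(7, 7, 7)), "counts")
})

test_that("two-occasion repeated-measures ANOVA equals the paired t-test", {
  out <- repeated_measures_anova(c(100, 200, 300, 110, 190, 310),
                                 occasion = rep(1:2, each = 3),
                                 subject = rep(1:3, 2))
  expect_equal(out$f_stat, 0.25, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * pt(-0.5, 2), tolerance = 1e-10)
  expect_equal(out$df_num, 1)
  expect_equal(out$df_den, 2)

  set.seed(9)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    v1 <- rnorm(n, 100, 20)
    v2 <- v1 + rnorm(n, 2, 10)
    out <- repeated_measures_anova(c(v1, v2), rep(1:2, each = n),
                                   rep(seq_len(n), 2))
    tt <- t.test(v1, v2, paired = TRUE)
    expect_equal(out$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(out$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("no within-subject change gives F = 0, p = 1", {
  v <- c(5, 7, 9)
  out <- repeated_measures_anova(c(v, v), rep(1:2, each = 3), rep(1:3, 2))
  expect_equal(out$f_stat, 0)
  expect_equal(out$p_value, 1)
})

test_that("unbalanced repeated-measures designs are rejected", {
  expect_error(
    repeated_measures_anova(c(1, 2, 3, 4, 5), c(1, 1, 1, 2, 2),
                            c("a", "b", "c", "a", "b")),
    "unbalanced.*\\(c, 2\\)")
})

test_that("pooled summaries reconstruct the raw-data mean and SD", {
  got <- pooled_summary(n = c(9, 9), mean = c(286, 322), sd = c(160, 194))
  expect_equal(got$mean, 304)
  expect_equal(got$sd, sqrt((8 * 160^2 + 8 * 194^2 + 9 * 18^2 * 2) / 17),
               tolerance = 1e-12)
  expect_lt(abs(got$sd - 173.5), 0.1)

  one <- pooled_summary(9, 286, 160)
  expect_equal(one, list(n = 9, mean = 286, sd = 160))

  # exactness against raw data, and group-order invariance
  set.seed(4)
  x <- rnorm(7, 10, 2); y <- rnorm(12, 14, 5)
  a <- pooled_summary(c(7, 12), c(mean(x), mean(y)), c(sd(x), sd(y)))
  b <- pooled_summary(c(12, 7), c(mean(y), mean(x)), c(sd(y), sd(x)))
  expect_equal(a$mean, mean(c(x, y)), tolerance = 1e-12)
  expect_equal(a$sd, sd(c(x, y)), tolerance = 1e-12)
  expect_equal(a, b)
  expect_error(pooled_summary(c(1, 9), c(1, 2), c(0, 1)), "n >= 2")
})

test_that("per-score summary rows match a direct recomputation", {
  set.seed(21)
  rec <- data.frame(tbe_score = sample(0:4, 20, replace = TRUE),
                    balf_rbc = exp(rnorm(20, 8, 2)))
  tab <- score_summary_table(rec)
  expect_equal(sum(tab$n), 20)
  for (i in seq_len(nrow(tab))) {
    x <- rec$balf_rbc[rec$tbe_score == tab$tbe_score[i]]
    expect_equal(tab$mean[i], mean(x))
    expect_equal(tab$median[i], median(x))
    expect_equal(tab$min[i], min(x))
    expect_equal(tab$max[i], max(x))
  }
  expect_true(all(tab$min <= tab$median & tab$median <= tab$max))

  single <- score_summary_table(data.frame(tbe_score = 2, balf_rbc = 500))
  expect_equal(single$n, 1)
  expect_equal(single$mean, 500)
  expect_equal(single$median, 500)
  expect_error(score_summary_table(data.frame(tbe_score = NA_integer_,
                                              balf_rbc = 1)), "no records")
})

test_that("overlap interval is the max-min / min-max of per-score ranges", {
  got <- overlap_interval(table1_summary())
  expect_equal(got$low, 4176)
  expect_equal(got$high, 41105)
  expect_false(got$empty)

  disjoint <- overlap_interval(data.frame(min = c(1, 5), max = c(2, 9)))
  expect_true(disjoint$empty)
  same <- overlap_interval(data.frame(min = c(3, 3), max = c(8, 8)))
  expect_equal(c(same$low, same$high), c(3, 8))
})

test_that("cross-tabulation reproduces the published 2x2 structure", {
  xt <- cross_tabulate(make_table2_cohort(), threshold = 992)
  expect_equal(c(xt$tp, xt$fn_balf, xt$fp_tbe_absent, xt$tn),
               c(59, 1, 39, 3))
  expect_equal(xt$total, 102)
  expect_equal(round(xt$tbe_prevalence_pct), 59)
  expect_equal(round(xt$balf_prevalence_pct), 96)
  expect_equal(xt$false_negative_balf_pct, 100 / 102)
})

test_that("threshold polarity and monotonicity behave as documented", {
  rec <- data.frame(tbe_score = c(0L, 1L, 0L), balf_rbc = c(992, 500, 2000))
  xt <- cross_tabulate(rec, 992)
  expect_equal(xt$balf_positive, 2)  # 992 itself is positive under >=
  xt_strict <- cross_tabulate(rec, 992, strict = TRUE)
  expect_equal(xt_strict$balf_positive, 1)

  xt_hi <- cross_tabulate(rec, 1e9)
  expect_equal(xt_hi$balf_prevalence_pct, 0)

  set.seed(13)
  rec2 <- data.frame(tbe_score = sample(0:4, 60, replace = TRUE),
                     balf_rbc = exp(rnorm(60, 7, 2)))
  prev <- vapply(c(10, 100, 1000, 10000, 1e6),
                 function(th) cross_tabulate(rec2, th)$balf_prevalence_pct,
                 numeric(1))
  expect_true(all(diff(prev) <= 0))
  tot <- cross_tabulate(rec2, 1000)
  expect_equal(tot$tp + tot$fn_balf + tot$fp_tbe_absent + tot$tn, 60)

  expect_error(cross_tabulate(data.frame(tbe_score = NA_integer_,
                                         balf_rbc = 5), 992),
               "missing a test result")
})
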