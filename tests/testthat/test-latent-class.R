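truth <- lca_params(mu_pos = 9, sigma_pos = 1.5, mu_neg = 5.7,
                    sigma_neg = 0.5, se_tbe = 0.6, fpr_tbe = 0.005,
                    prev = 0.9)

one_record <- function(balf_rbc, tbe_score, group = "exercised") {
  data.frame(horse_id = "H1", group = group,
             modality = if (group == "exercised") "treadmill" else "none",
             occasion = 1L,
             tbe_score = if (group == "exercised") tbe_score else NA_integer_,
             balf_rbc = balf_rbc, latent_eiph = NA)
}

# prior log density evaluated from the defining formulas
oracle_log_prior <- function(p, priors = eiph_priors()) {
  dnorm(p$mu_pos, priors$mu_prior_mean, priors$mu_prior_sd, log = TRUE) +
    dnorm(p$mu_neg, priors$mu_prior_mean, priors$mu_prior_sd, log = TRUE) -
    2 * log(diff(priors$sigma_prior_range)) -
    log(diff(priors$se_prior_range)) -
    log(diff(priors$fpr_prior_range)) -
    log(diff(priors$prev_prior_range))
}

test_that("log_joint matches a direct density evaluation", {
  p <- lca_params(mu_pos = 8, sigma_pos = 1.5, mu_neg = 5.5,
                  sigma_neg = 0.5, se_tbe = 0.6, fpr_tbe = 0.005,
                  prev = 0.5)
  rec <- one_record(exp(6), 1L)
  lik <- log(0.5 * dnorm(6, 8, 1.5) * 0.6 +
             0.5 * dnorm(6, 5.5, 0.5) * 0.005)
  expect_equal(log_joint(p, rec), oracle_log_prior(p) + lik,
               tolerance = 1e-12)

  # a TBE-negative record flips the Bernoulli factors
  rec0 <- one_record(exp(6), 0L)
  lik0 <- log(0.5 * dnorm(6, 8, 1.5) * 0.4 +
              0.5 * dnorm(6, 5.5, 0.5) * 0.995)
  expect_equal(log_joint(p, rec0), oracle_log_prior(p) + lik0,
               tolerance = 1e-12)

  # sedentary records contribute the negative component only
  sed <- one_record(exp(5.2), NA, group = "sedentary")
  expect_equal(log_joint(p, sed),
               oracle_log_prior(p) + dnorm(5.2, 5.5, 0.5, log = TRUE),
               tolerance = 1e-12)
})

test_that("log_joint is -Inf outside the prior support", {
  rec <- one_record(exp(6), 1L)
  out <- truth; out$fpr_tbe <- 0.02  # above the informative upper bound
  expect_equal(log_joint(out, rec), -Inf)
  flipped <- truth; flipped$mu_pos <- 4; flipped$mu_neg <- 9
  expect_equal(log_joint(flipped, rec), -Inf)
  expect_gt(log_joint(flipped, rec, enforce_order = FALSE), -Inf)
  big_sigma <- truth; big_sigma$sigma_neg <- 150
  expect_equal(log_joint(big_sigma, rec), -Inf)
})

test_that("prev = 1 collapses the mixture to the positive component", {
  p <- truth; p$prev <- 1
  set.seed(2)
  y <- rnorm(20, 9, 1.5)
  t <- rbinom(20, 1, 0.6)
  rec <- data.frame(horse_id = sprintf("H%d", 1:20), group = "exercised",
                    modality = "treadmill", occasion = 1L,
                    tbe_score = t, balf_rbc = exp(y), latent_eiph = NA)
  lik <- sum(dnorm(y, 9, 1.5, log = TRUE) +
             ifelse(t == 1, log(0.6), log(0.4)))
  expect_equal(log_joint(p, rec), oracle_log_prior(p) + lik,
               tolerance = 1e-10)
})

test_that("log_joint is permutation-invariant and additive over records", {
  set.seed(6)
  co <- simulate_cohort(truth, cohort_design(20, 3, 2, seed = 30))
  shuffled <- co[sample(nrow(co)), ]
  expect_equal(log_joint(truth, co), log_joint(truth, shuffled))
  a <- co[1:10, ]; b <- co[11:nrow(co), ]
  expect_equal(log_joint(truth, co),
               log_joint(truth, a) + log_joint(truth, b) -
                 oracle_log_prior(truth),
               tolerance = 1e-9)
})

test_that("fits are seed-reproducible and draws stay in the prior support", {
  co <- simulate_cohort(truth, cohort_design(60, 5, 2, seed = 14))
  ctl <- quick_control(seed = 5, n_iterations = 1200, n_burn_in = 400)
  f1 <- eiph_lca(co, control = ctl)
  f2 <- eiph_lca(co, control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)

  d <- f1$draws
  expect_true(all(d$sigma_pos > 0 & d$sigma_pos <= 100))
  expect_true(all(d$sigma_neg > 0 & d$sigma_neg <= 100))
  expect_true(all(d$se_tbe >= 0 & d$se_tbe <= 1))
  expect_true(all(d$fpr_tbe >= 0 & d$fpr_tbe <= 0.01))
  expect_true(all(d$prev >= 0 & d$prev <= 1))
  expect_true(all(d$mu_pos >= d$mu_neg))  # identification constraint
  expect_true(all(f1$summary$ci_lower <= f1$summary$median &
                  f1$summary$median <= f1$summary$ci_upper))
})

test_that("a near-degenerate prevalence prior reduces to a plain normal fit", {
  co <- simulate_cohort(truth, cohort_design(200, 0, seed = 77))
  pr <- eiph_priors(prev_prior_range = c(0.999999, 1))
  # the negative component has no data here, so its chains wander and the
  # non-convergence flag must fire rather than stay silent
  expect_warning(
    fit <- eiph_lca(co, priors = pr,
                    control = quick_control(seed = 2, n_iterations = 3000,
                                            n_burn_in = 1000)),
    "non-convergence")
  expect_false(fit$converged)
  y <- log(co$balf_rbc)
  expect_lt(abs(coef(fit)["mu_pos"] - mean(y)), 0.05)
  expect_lt(abs(coef(fit)["sigma_pos"] - sd(y)), 0.05)
})

test_that("MAP is the highest-joint-density retained draw", {
  co <- simulate_cohort(truth, cohort_design(40, 3, 2, seed = 9))
  fit <- eiph_lca(co, control = quick_control(seed = 3, n_iterations = 1000,
                                              n_burn_in = 300))
  i <- which.max(fit$draws$log_joint)
  pn <- c("mu_pos", "sigma_pos", "mu_neg", "sigma_neg", "se_tbe",
          "fpr_tbe", "prev")
  expect_equal(unlist(map_estimate(fit)[pn]), unlist(fit$draws[i, pn]),
               tolerance = 1e-12, ignore_attr = TRUE)
  kde <- map_estimate(fit, method = "kde")
  expect_s3_class(kde, "lca_params")
})

test_that("generating parameters are recovered on a large synthetic cohort", {
  co <- simulate_cohort(truth, cohort_design(1000, 9, 2, seed = 42))
  fit <- eiph_lca(co, control = quick_control(seed = 7, n_iterations = 4000,
                                              n_burn_in = 1000))
  s <- fit$summary
  # one realized cohort: demand near-universal strict coverage, and for
  # every parameter a posterior mean within one interval-width of truth
  covered <- logical(nrow(s))
  for (i in seq_len(nrow(s))) {
    p <- s$parameter[i]
    covered[i] <- truth[[p]] >= s$ci_lower[i] && truth[[p]] <= s$ci_upper[i]
    width <- s$ci_upper[i] - s$ci_lower[i]
    expect_lt(abs(s$mean[i] - truth[[p]]), width)
    # MAP consistent with the posterior bulk
    expect_gte(s$map[i], s$ci_lower[i] - 1e-9)
    expect_lte(s$map[i], s$ci_upper[i] + 1e-9)
  }
  expect_gte(sum(covered), 6)
  expect_true(fit$converged)
})

test_that("posterior mean of the false-positive rate scales with its prior bound", {
  # No TBE positives among EIPH-negatives: the false-positive rate is
  # prior-dominated, so its posterior mean tracks the scaled uniform mean.
  gen <- truth; gen$fpr_tbe <- 0; gen$prev <- 0.96
  co <- simulate_cohort(do.call(lca_params, unclass(gen)),
                        cohort_design(102, 9, 2, seed = 19))
  ps <- prior_sensitivity(co, control = quick_control(
    seed = 11, n_iterations = 3000, n_burn_in = 1000))
  fpr_means <- ps$means$fpr_tbe
  expect_equal(fpr_means, c(0.0045, 0.005, 0.0055), tolerance = 0.08)

  # the no-op perturbation is exactly the base fit
  base <- eiph_lca(co, control = quick_control(
    seed = 11, n_iterations = 3000, n_burn_in = 1000))
  expect_equal(ps$means$fpr_tbe[2], unname(coef(base)["fpr_tbe"]),
               tolerance = 1e-12)
  expect_equal(unname(ps$max_abs_deviation["scale_1"]), 0)
})

test_that("the fit errors without exercised events carrying both tests", {
  sed_only <- simulate_cohort(truth, cohort_design(0, 5, 2, seed = 1))
  expect_error(eiph_lca(sed_only), "exercised")
  expect_error(log_joint(truth, sed_only[0, ]), "empty")
})
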