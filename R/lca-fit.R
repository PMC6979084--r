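#' Unnormalized log posterior of the latent-class model
#'
#' Evaluates the joint log density of the data and priors with the latent
#' EIPH indicators integrated out analytically.  Each exercised record with
#' log count `y` and TBE indicator `t` contributes
#' `log( prev * N(y; mu_pos, sigma_pos) * se^t (1-se)^(1-t)
#'     + (1-prev) * N(y; mu_neg, sigma_neg) * fpr^t (1-fpr)^(1-t) )`;
#' each sedentary record contributes `log N(y; mu_neg, sigma_neg)` with no
#' Bernoulli term, its EIPH probability being fixed at 0 by design.  Prior
#' log densities are added.  Parameters outside the prior support — or, when
#' `enforce_order` is `TRUE`, violating the identification constraint
#' `mu_pos >= mu_neg` — give `-Inf`.
#'
#' @param params An [lca_params()] object (or coercible named list).
#' @param records Cohort data frame; exercised rows need `tbe_score` and
#'   `balf_rbc`, sedentary rows need `balf_rbc`.
#' @param priors An [eiph_priors()] object.
#' @param enforce_order Apply the `mu_pos >= mu_neg` identification
#'   constraint (default `TRUE`).
#' @return A single numeric value (possibly `-Inf`).
#' @export
log_joint <- function(params, records, priors = eiph_priors(),
                      enforce_order = TRUE) {
  if (!inherits(params, "lca_params"))
    params <- do.call(lca_params, as.list(params)[param_names()])
  dat <- prepare_lca_data(records)
  lp <- make_log_posterior(dat, priors, enforce_order)
  unname(lp(unlist(params[param_names()])))
}

# Split a validated cohort into the vectors the likelihood needs.
prepare_lca_data <- function(records) {
  records <- validate_cohort(records)
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  ex <- records[records$group == "exercised", , drop = FALSE]
  if (nrow(ex) > 0 && anyNA(ex$tbe_score))
    stop("exercised record(s) without a TBE score", call. = FALSE)
  sed <- records[records$group == "sedentary", , drop = FALSE]
  list(y_ex = log(ex$balf_rbc),
       t_pos = ex$tbe_score >= 1L,
       y_sed = log(sed$balf_rbc))
}

# Fast closure over the data: theta is the numeric 7-vector in
# param_names() order.  Uniform priors use closed supports so that
# degenerate boundary settings (prev = 1, fpr = 0) evaluate cleanly.
make_log_posterior <- function(dat, priors, enforce_order = TRUE) {
  y_ex <- dat$y_ex
  tpos <- dat$t_pos
  tneg <- !tpos
  y_sed <- dat$y_sed
  mu0 <- priors$mu_prior_mean
  musd <- priors$mu_prior_sd
  sr <- priors$sigma_prior_range
  ser <- priors$se_prior_range
  fr <- priors$fpr_prior_range
  pr_r <- priors$prev_prior_range
  lconst <- -2 * log(diff(sr)) - log(diff(ser)) - log(diff(fr)) -
    log(diff(pr_r))
  n_ex <- length(y_ex)

  function(th) {
    if (th[2] <= sr[1] || th[2] > sr[2] || th[4] <= sr[1] || th[4] > sr[2])
      return(-Inf)
    if (th[5] < ser[1] || th[5] > ser[2]) return(-Inf)
    if (th[6] < fr[1] || th[6] > fr[2]) return(-Inf)
    if (th[7] < pr_r[1] || th[7] > pr_r[2]) return(-Inf)
    if (enforce_order && th[1] < th[3]) return(-Inf)
    lp <- stats::dnorm(th[1], mu0, musd, log = TRUE) +
      stats::dnorm(th[3], mu0, musd, log = TRUE) + lconst
    if (length(y_sed))
      lp <- lp + sum(stats::dnorm(y_sed, th[3], th[4], log = TRUE))
    if (n_ex) {
      la <- stats::dnorm(y_ex, th[1], th[2], log = TRUE) + log(th[7])
      lb <- stats::dnorm(y_ex, th[3], th[4], log = TRUE) + log1p(-th[7])
      la[tpos] <- la[tpos] + log(th[5])
      la[tneg] <- la[tneg] + log1p(-th[5])
      lb[tpos] <- lb[tpos] + log(th[6])
      lb[tneg] <- lb[tneg] + log1p(-th[6])
      m <- pmax(la, lb)
      s <- m + log(exp(la - m) + exp(lb - m))
      s[m == -Inf] <- -Inf
      lp <- lp + sum(s)
    }
    if (is.nan(lp)) -Inf else lp
  }
}

# Data-driven starting point, jittered per chain (uses the current RNG
# stream).  Kept inside the prior support.
lca_init <- function(dat, priors) {
  y_all <- c(dat$y_ex, dat$y_sed)
  mu_neg0 <- if (length(dat$y_sed) >= 2) mean(dat$y_sed) else
    stats::quantile(y_all, 0.1, names = FALSE)
  sigma_neg0 <- if (length(dat$y_sed) >= 2) max(stats::sd(dat$y_sed), 0.2) else 0.5
  mu_pos0 <- max(stats::quantile(dat$y_ex, 0.75, names = FALSE), mu_neg0 + 0.5)
  sigma_pos0 <- max(stats::sd(dat$y_ex), 0.3)
  se0 <- if (length(dat$t_pos)) mean(dat$t_pos) else 0.5
  th <- c(mu_pos0 + stats::rnorm(1, 0, 0.3),
          sigma_pos0 * exp(stats::rnorm(1, 0, 0.2)),
          mu_neg0 + stats::rnorm(1, 0, 0.2),
          sigma_neg0 * exp(stats::rnorm(1, 0, 0.2)),
          se0, diff(priors$fpr_prior_range) / 2 + priors$fpr_prior_range[1],
          0.5)
  # pull the probability-type coordinates strictly inside their ranges
  squeeze <- function(x, r) pmin(pmax(x, r[1] + 0.02 * diff(r)),
                                 r[2] - 0.02 * diff(r))
  th[2] <- squeeze(th[2], priors$sigma_prior_range)
  th[4] <- squeeze(th[4], priors$sigma_prior_range)
  th[5] <- squeeze(th[5] + stats::rnorm(1, 0, 0.05), priors$se_prior_range)
  th[6] <- squeeze(th[6], priors$fpr_prior_range)
  th[7] <- squeeze(th[7] + stats::rnorm(1, 0, 0.05), priors$prev_prior_range)
  if (th[1] < th[3]) th[1] <- th[3] + 0.5
  th
}

# One adaptive random-walk Metropolis-within-Gibbs chain.  Proposal scales
# adapt in batches during burn-in only (Robbins-Monro on the log scale,
# target acceptance 0.44 per coordinate).  Uses the caller's RNG stream.
run_lca_chain <- function(lp, init, control) {
  n_iter <- control$n_iterations
  n_burn <- control$n_burn_in
  n_keep <- n_iter - n_burn
  scales <- control$proposal_scale
  adapt_every <- control$adapt_every
  th <- init
  cur <- lp(th)
  if (!is.finite(cur)) stop("invalid starting point for MCMC", call. = FALSE)
  keep <- matrix(NA_real_, n_keep, 7L)
  keep_lp <- numeric(n_keep)
  acc <- integer(7L)
  batch_acc <- integer(7L)
  batch <- 0L
  for (i in seq_len(n_iter)) {
    for (j in 1:7) {
      prop <- th
      prop[j] <- th[j] + stats::rnorm(1, 0, scales[j])
      new <- lp(prop)
      if (new - cur > log(stats::runif(1))) {
        th <- prop
        cur <- new
        acc[j] <- acc[j] + 1L
        batch_acc[j] <- batch_acc[j] + 1L
      }
    }
    if (i <= n_burn && i %% adapt_every == 0L) {
      batch <- batch + 1L
      gain <- min(0.25, 1 / sqrt(batch))
      rate <- batch_acc / adapt_every
      scales <- scales * exp(gain * (rate - 0.44))
      scales <- pmin(pmax(scales, 1e-8), 50)
      batch_acc[] <- 0L
    }
    if (i > n_burn) {
      keep[i - n_burn, ] <- th
      keep_lp[i - n_burn] <- cur
    }
  }
  colnames(keep) <- param_names()
  list(draws = keep, log_joint = keep_lp,
       acceptance = acc / n_iter, scales = scales)
}

#' Fit the Bayesian latent-class model for EIPH diagnostics
#'
#' Estimates the seven latent-class parameters — the two normal components
#' of log BALFRBC, the TBE sensitivity and false-positive probability, and
#' the exercised prevalence — by MCMC, without assuming either test is a
#' gold standard.  The sampler is an adaptive random-walk
#' Metropolis-within-Gibbs on the marginalized posterior (see
#' [log_joint()]); the mixture is identified by the biologically directed
#' constraint `mu_pos >= mu_neg` (hemorrhage raises counts).  Sedentary
#' lavages inform the EIPH-negative component only, their EIPH probability
#' being fixed at 0.
#'
#' Fits are reproducible: an identical `(records, priors, control)` triple,
#' including `control$seed`, gives identical output.  A split R-hat above
#' 1.1 for any parameter raises a warning and sets `converged = FALSE`.
#'
#' @param records Cohort data frame (see [simulate_cohort()] /
#'   [read_cohort()]); must contain at least one exercised event with both
#'   tests.
#' @param priors An [eiph_priors()] object.
#' @param control An [eiph_mcmc_control()] object.
#' @return An object of class `"eiph_lca"` with components `draws` (data
#'   frame: `chain`, `iteration`, the seven parameters, `log_joint`),
#'   `summary` (per-parameter posterior mean, median, MAP, 2.5 and 97.5
#'   percentiles, split R-hat, effective sample size), `map` (named vector,
#'   highest-posterior retained draw), `acceptance` (per chain x parameter),
#'   `converged`, `rhat_warn_threshold`, plus the `priors`, `control` and
#'   data dimensions used.
#' @seealso [map_estimate()], [prior_sensitivity()], [optimal_threshold()],
#'   [convergence_diagnostics()]
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(default_study_params(), cohort_design(seed = 1))
#' fit <- eiph_lca(cohort, control = eiph_mcmc_control(
#'   n_chains = 2, n_iterations = 2000, n_burn_in = 500, seed = 1))
#' summary(fit)
#' }
#' @export
eiph_lca <- function(records, priors = eiph_priors(),
                     control = eiph_mcmc_control()) {
  stopifnot(inherits(priors, "eiph_priors"),
            inherits(control, "eiph_mcmc_control"))
  dat <- prepare_lca_data(records)
  if (length(dat$y_ex) < 1)
    stop("need at least one exercised event with both tests", call. = FALSE)
  lp <- make_log_posterior(dat, priors, enforce_order = TRUE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + ch - 1L)
    init <- lca_init(dat, priors)
    chains[[ch]] <- run_lca_chain(lp, init, control)
  }

  n_keep <- control$n_iterations - control$n_burn_in
  draws <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    data.frame(chain = ch, iteration = control$n_burn_in + seq_len(n_keep),
               chains[[ch]]$draws, log_joint = chains[[ch]]$log_joint)
  }))

  diag <- if (control$n_chains >= 2)
    convergence_diagnostics(draws) else
    data.frame(parameter = param_names(), rhat = NA_real_, ess = NA_real_)
  i_map <- which.max(draws$log_joint)
  map <- unlist(draws[i_map, param_names()])

  pm <- draws[, param_names(), drop = FALSE]
  summ <- data.frame(
    parameter = param_names(),
    mean = vapply(pm, mean, numeric(1)),
    median = vapply(pm, stats::median, numeric(1)),
    map = unname(map),
    ci_lower = vapply(pm, stats::quantile, numeric(1), probs = 0.025,
                      names = FALSE),
    ci_upper = vapply(pm, stats::quantile, numeric(1), probs = 0.975,
                      names = FALSE),
    rhat = diag$rhat[match(param_names(), diag$parameter)],
    ess = diag$ess[match(param_names(), diag$parameter)],
    row.names = NULL)

  converged <- all(is.na(summ$rhat)) || all(summ$rhat < 1.1, na.rm = TRUE)
  if (!converged)
    warning("possible non-convergence: split R-hat > 1.1 for ",
            paste(summ$parameter[which(summ$rhat >= 1.1)], collapse = ", "),
            call. = FALSE)

  structure(list(draws = draws, summary = summ, map = map,
                 acceptance = t(vapply(chains, `[[`, numeric(7),
                                       "acceptance")),
                 converged = converged, rhat_threshold = 1.05,
                 priors = priors, control = control,
                 n_exercised = length(dat$y_ex),
                 n_sedentary = length(dat$y_sed)),
            class = "eiph_lca")
}
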