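#' @export
print.eiph_lca <- function(x, digits = 3, ...) {
  cat("Bayesian latent-class model for EIPH diagnostic accuracy\n")
  cat(sprintf("  %d exercised events (TBE + BALFRBC), %d sedentary lavages\n",
              x$n_exercised, x$n_sedentary))
  cat(sprintf("  %d chain(s) x %d iterations (%d burn-in)\n",
              x$control$n_chains, x$control$n_iterations,
              x$control$n_burn_in))
  if (!x$converged)
    cat("  WARNING: split R-hat > 1.1 for at least one parameter\n")
  s <- x$summary
  s[, -1] <- lapply(s[, -1], function(v) round(v, digits))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Summarize a fitted latent-class model
#'
#' @param object An [eiph_lca()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.eiph_lca"`: the per-parameter
#'   posterior table plus derived TBE accuracy (sensitivity `se_tbe`,
#'   specificity `1 - fpr_tbe`) with equal-tailed 95% credible intervals,
#'   and convergence information.
#' @export
summary.eiph_lca <- function(object, ...) {
  dr <- object$draws
  spec <- 1 - dr$fpr_tbe
  tbe <- data.frame(
    measure = c("tbe_sensitivity", "tbe_specificity"),
    mean = c(mean(dr$se_tbe), mean(spec)),
    ci_lower = c(stats::quantile(dr$se_tbe, 0.025, names = FALSE),
                 stats::quantile(spec, 0.025, names = FALSE)),
    ci_upper = c(stats::quantile(dr$se_tbe, 0.975, names = FALSE),
                 stats::quantile(spec, 0.975, names = FALSE)))
  structure(list(parameters = object$summary, tbe_accuracy = tbe,
                 converged = object$converged,
                 acceptance = object$acceptance,
                 n_exercised = object$n_exercised,
                 n_sedentary = object$n_sedentary,
                 control = object$control),
            class = "summary.eiph_lca")
}

#' @export
print.summary.eiph_lca <- function(x, digits = 3, ...) {
  cat("Posterior summary (equal-tailed 95% credible intervals)\n")
  p <- x$parameters
  p[, -1] <- lapply(p[, -1], function(v) round(v, digits))
  print(p, row.names = FALSE)
  cat("\nDerived TBE accuracy\n")
  t <- x$tbe_accuracy
  t[, -1] <- lapply(t[, -1], function(v) round(v, digits))
  print(t, row.names = FALSE)
  cat(if (x$converged) "\nAll split R-hat < 1.1\n" else
    "\nWARNING: split R-hat > 1.1 for at least one parameter\n")
  invisible(x)
}

#' Extract parameter estimates from a fitted latent-class model
#'
#' @param object An [eiph_lca()] fit.
#' @param estimate Which posterior point estimate: `"mean"` (default),
#'   `"median"`, or `"map"`.
#' @param ... Unused.
#' @return A named numeric vector of the seven parameters.
#' @export
coef.eiph_lca <- function(object, estimate = c("mean", "median", "map"),
                          ...) {
  estimate <- match.arg(estimate)
  v <- object$summary[[estimate]]
  names(v) <- object$summary$parameter
  v
}

#' Maximum a posteriori parameter estimate
#'
#' By default the retained draw with the highest joint posterior density
#' (the draws already carry their [log_joint()] values).  An alternative
#' marginal definition — the mode of a kernel density estimate of each
#' parameter's posterior, per parameter — is available for comparison; it
#' does not correspond to a single joint draw.
#'
#' @param fit An [eiph_lca()] fit.
#' @param method `"draw"` (default, highest-joint-posterior retained draw)
#'   or `"kde"` (per-parameter kernel density mode).
#' @return An [lca_params()] object.
#' @export
map_estimate <- function(fit, method = c("draw", "kde")) {
  stopifnot(inherits(fit, "eiph_lca"))
  method <- match.arg(method)
  if (method == "draw") {
    v <- fit$map
  } else {
    v <- vapply(param_names(), function(p) {
      d <- stats::density(fit$draws[[p]])
      d$x[which.max(d$y)]
    }, numeric(1))
  }
  do.call(lca_params, as.list(v))
}

#' Posterior probability of EIPH for new events
#'
#' For each new exercised event, the probability of the latent
#' EIPH-positive state given its BALFRBC count (and TBE outcome if
#' present), under plug-in parameters from the fit:
#' `P(D+ | y, t) = prev f_pos(y) b_pos(t) /
#'   (prev f_pos(y) b_pos(t) + (1-prev) f_neg(y) b_neg(t))`.
#'
#' @param object An [eiph_lca()] fit.
#' @param newdata Data frame with `balf_rbc` and optionally `tbe_score`
#'   (`NA` meaning TBE not performed).
#' @param estimate Point estimate to plug in (see [coef.eiph_lca()]).
#' @param ... Unused.
#' @return Numeric vector of posterior EIPH probabilities.
#' @export
predict.eiph_lca <- function(object, newdata,
                             estimate = c("mean", "median", "map"), ...) {
  estimate <- match.arg(estimate)
  p <- coef(object, estimate)
  stopifnot(is.data.frame(newdata), "balf_rbc" %in% names(newdata),
            all(newdata$balf_rbc > 0))
  y <- log(newdata$balf_rbc)
  t <- if ("tbe_score" %in% names(newdata)) newdata$tbe_score else
    rep(NA_integer_, nrow(newdata))
  la <- log(p["prev"]) + stats::dnorm(y, p["mu_pos"], p["sigma_pos"],
                                      log = TRUE)
  lb <- log1p(-p["prev"]) + stats::dnorm(y, p["mu_neg"], p["sigma_neg"],
                                         log = TRUE)
  has_t <- !is.na(t)
  pos <- has_t & t >= 1L
  neg <- has_t & t == 0L
  la[pos] <- la[pos] + log(p["se_tbe"])
  la[neg] <- la[neg] + log1p(-p["se_tbe"])
  lb[pos] <- lb[pos] + log(p["fpr_tbe"])
  lb[neg] <- lb[neg] + log1p(-p["fpr_tbe"])
  unname(1 / (1 + exp(lb - la)))
}

#' Simulate cohorts from a fitted latent-class model
#'
#' Draws synthetic cohorts with [simulate_cohort()] at a point estimate of
#' the fitted parameters, with the fitted study's dimensions.
#'
#' @param object An [eiph_lca()] fit.
#' @param nsim Number of cohorts.
#' @param seed Integer seed for the first cohort; cohort `k` uses
#'   `seed + k - 1`.
#' @param estimate Point estimate to simulate from (see [coef.eiph_lca()]).
#' @param design Optional [cohort_design()] overriding the fitted
#'   dimensions (its `seed` is still replaced as above).
#' @param ... Unused.
#' @return A list of `nsim` cohort data frames.
#' @export
simulate.eiph_lca <- function(object, nsim = 1, seed = 1,
                              estimate = c("mean", "median", "map"),
                              design = NULL, ...) {
  estimate <- match.arg(estimate)
  params <- do.call(lca_params, as.list(coef(object, estimate)))
  if (is.null(design))
    design <- cohort_design(n_exercised = object$n_exercised,
                            n_sedentary_horses = 0, seed = seed)
  lapply(seq_len(nsim), function(k) {
    d <- design
    d$seed <- as.integer(seed + k - 1)
    simulate_cohort(params, d)
  })
}

#' Trace and density plots for a fitted latent-class model
#'
#' @param x An [eiph_lca()] fit.
#' @param parameters Parameters to plot (default: all seven).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.eiph_lca <- function(x, parameters = param_names(), ...) {
  parameters <- match.arg(parameters, param_names(), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(parameters), 2),
                       mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(old))
  chains <- sort(unique(x$draws$chain))
  for (p in parameters) {
    m <- vapply(chains, function(ch) x$draws[[p]][x$draws$chain == ch],
                numeric(sum(x$draws$chain == chains[1])))
    graphics::matplot(m, type = "l", lty = 1, ylab = p,
                      main = paste("trace:", p), ...)
    d <- stats::density(x$draws[[p]])
    graphics::plot(d, main = paste("posterior:", p), xlab = p)
  }
  invisible(x)
}

#' Posterior accuracy of the BALFRBC rule at a fixed threshold
#'
#' Evaluates the model-based sensitivity and specificity of the
#' "BALFRBC >= threshold" rule (see [test_metrics_at()]) at every retained
#' draw, giving posterior means and equal-tailed 95% credible intervals
#' that propagate parameter uncertainty while holding the threshold fixed.
#'
#' @param fit An [eiph_lca()] fit.
#' @param threshold BALFRBC threshold, cells/uL.
#' @return A data frame with rows `balf_sensitivity`, `balf_specificity`
#'   and columns `mean`, `ci_lower`, `ci_upper`.
#' @export
balf_metrics <- function(fit, threshold) {
  stopifnot(inherits(fit, "eiph_lca"), threshold > 0)
  t_log <- log(threshold)
  dr <- fit$draws
  sens <- 1 - stats::pnorm((t_log - dr$mu_pos) / dr$sigma_pos)
  spec <- stats::pnorm((t_log - dr$mu_neg) / dr$sigma_neg)
  data.frame(
    measure = c("balf_sensitivity", "balf_specificity"),
    mean = c(mean(sens), mean(spec)),
    ci_lower = c(stats::quantile(sens, 0.025, names = FALSE),
                 stats::quantile(spec, 0.025, names = FALSE)),
    ci_upper = c(stats::quantile(sens, 0.975, names = FALSE),
                 stats::quantile(spec, 0.975, names = FALSE)))
}
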