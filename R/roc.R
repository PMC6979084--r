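#' Model-based ROC curve from the fitted normal components
#'
#' At a log-scale threshold `t`, the "BALFRBC >= exp(t)" rule has
#' sensitivity `1 - Phi((t - mu_pos)/sigma_pos)` and specificity
#' `Phi((t - mu_neg)/sigma_neg)`.  Precision and F1 are evaluated at an
#' assumed prevalence (see [f1_at()]).
#'
#' @param params An [lca_params()] object (typically [map_estimate()]
#'   output; only the four normal-component fields are used).
#' @param grid Strictly increasing numeric vector of log-scale thresholds;
#'   default 512 points spanning `mu_neg - 5 sigma_neg` to
#'   `mu_pos + 5 sigma_pos`.
#' @param prevalence Assumed prevalence for precision/F1 (default 0.5, the
#'   balanced assumption).
#' @param mean_type F1 variant, `"harmonic"` (default) or `"geometric"`
#'   (see [f1_at()]).
#' @return A data frame of class `"eiph_roc"` with columns
#'   `threshold_log`, `threshold_natural`, `sensitivity`, `specificity`,
#'   `precision`, `f1`.
#' @export
roc_from_normals <- function(params, grid = NULL, prevalence = 0.5,
                             mean_type = c("harmonic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!inherits(params, "lca_params"))
    params <- do.call(lca_params, as.list(params)[param_names()])
  if (is.null(grid))
    grid <- seq(params$mu_neg - 5 * params$sigma_neg,
                params$mu_pos + 5 * params$sigma_pos, length.out = 512)
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  sens <- 1 - stats::pnorm((grid - params$mu_pos) / params$sigma_pos)
  spec <- stats::pnorm((grid - params$mu_neg) / params$sigma_neg)
  f1 <- f1_at(sens, spec, prevalence, mean_type)
  prec <- precision_at(sens, spec, prevalence)
  out <- data.frame(threshold_log = grid, threshold_natural = exp(grid),
                    sensitivity = sens, specificity = spec,
                    precision = prec, f1 = f1)
  class(out) <- c("eiph_roc", "data.frame")
  out
}

#' @export
plot.eiph_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

precision_at <- function(sensitivity, specificity, prevalence) {
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  ifelse(den > 0, num / den, 0)
}

#' F1 score of a test with given sensitivity and specificity
#'
#' Precision (positive predictive value) at the assumed prevalence is
#' `sens * prev / (sens * prev + (1 - spec)(1 - prev))`; the F1 score is
#' the harmonic mean of precision and sensitivity (recall),
#' `2 * precision * sens / (precision + sens)`, and 0 when sensitivity is
#' 0.  A geometric-mean variant (`sqrt(precision * sens)`) is available
#' for comparison.
#'
#' @param sensitivity,specificity Numeric vectors in `[0, 1]`.
#' @param prevalence Assumed prevalence in `[0, 1]` (default 0.5).
#' @param mean_type `"harmonic"` (default) or `"geometric"`.
#' @return Numeric vector of F1 values.
#' @examples
#' f1_at(0.8, 0.9)  # precision 0.8889, F1 0.8421
#' @export
f1_at <- function(sensitivity, specificity, prevalence = 0.5,
                  mean_type = c("harmonic", "geometric")) {
  mean_type <- match.arg(mean_type)
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  prec <- precision_at(sensitivity, specificity, prevalence)
  if (mean_type == "harmonic") {
    ifelse(sensitivity > 0 & prec + sensitivity > 0,
           2 * prec * sensitivity / (prec + sensitivity), 0)
  } else {
    sqrt(prec * sensitivity)
  }
}

#' F1-optimal BALFRBC diagnostic threshold
#'
#' Maximizes the F1 score of the "BALFRBC >= threshold" rule over
#' log-scale thresholds, using a dense grid over
#' `[mu_neg - 5 sigma_neg, mu_pos + 5 sigma_pos]` followed by local
#' refinement with [stats::optimize()] around the best grid point.  For
#' degenerate parameter sets (identical components) F1 increases towards
#' the classify-all-positive limit; the returned boundary solution is then
#' flagged.
#'
#' @param params An [lca_params()] object or an [eiph_lca()] fit (in which
#'   case the MAP estimate is used).
#' @param prevalence Assumed prevalence for precision (default 0.5).
#' @param mean_type F1 variant (see [f1_at()]).
#' @param n_grid Number of initial grid points.
#' @return A list of class `"eiph_threshold"`: `threshold_natural`
#'   (cells/uL), `threshold_log`, `sensitivity`, `specificity`,
#'   `precision`, `f1` at the optimum, `prevalence_assumed`, and logical
#'   `boundary` (optimum at the grid edge).
#' @examples
#' optimal_threshold(default_study_params())
#' @export
optimal_threshold <- function(params, prevalence = 0.5,
                              mean_type = c("harmonic", "geometric"),
                              n_grid = 4096) {
  mean_type <- match.arg(mean_type)
  if (inherits(params, "eiph_lca")) params <- map_estimate(params)
  if (!inherits(params, "lca_params"))
    params <- do.call(lca_params, as.list(params)[param_names()])
  lo <- params$mu_neg - 5 * params$sigma_neg
  hi <- params$mu_pos + 5 * params$sigma_pos
  if (hi <= lo) hi <- lo + 1
  grid <- seq(lo, hi, length.out = n_grid)
  obj <- function(t) {
    f1_at(1 - stats::pnorm((t - params$mu_pos) / params$sigma_pos),
          stats::pnorm((t - params$mu_neg) / params$sigma_neg),
          prevalence, mean_type)
  }
  f1 <- obj(grid)
  i <- which.max(f1)
  boundary <- i == 1L || i == length(grid)
  if (boundary) {
    t_opt <- grid[i]
    f_opt <- f1[i]
    warning("F1 maximized at the search boundary; components may be ",
            "indistinguishable", call. = FALSE)
  } else {
    op <- stats::optimize(obj, lower = grid[i - 1L], upper = grid[i + 1L],
                          maximum = TRUE, tol = 1e-10)
    t_opt <- op$maximum
    f_opt <- op$objective
    if (f1[i] > f_opt) {
      t_opt <- grid[i]
      f_opt <- f1[i]
    }
  }
  sens <- 1 - stats::pnorm((t_opt - params$mu_pos) / params$sigma_pos)
  spec <- stats::pnorm((t_opt - params$mu_neg) / params$sigma_neg)
  structure(list(threshold_natural = exp(t_opt), threshold_log = t_opt,
                 sensitivity = sens, specificity = spec,
                 precision = precision_at(sens, spec, prevalence),
                 f1 = f_opt, prevalence_assumed = prevalence,
                 boundary = boundary),
            class = "eiph_threshold")
}

#' @export
print.eiph_threshold <- function(x, ...) {
  cat(sprintf("F1-optimal BALFRBC threshold: %.0f cells/uL (log %.4f)\n",
              round(x$threshold_natural), x$threshold_log))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, precision %.3f, F1 %.3f",
              x$sensitivity, x$specificity, x$precision, x$f1))
  cat(sprintf(" (assumed prevalence %.2f)\n", x$prevalence_assumed))
  if (x$boundary) cat("  NOTE: boundary solution\n")
  invisible(x)
}

#' Model-based accuracy of the BALFRBC rule at a fixed threshold
#'
#' Sensitivity and specificity of the "BALFRBC >= threshold" rule under
#' the two-normal model, i.e. the [roc_from_normals()] formulas evaluated
#' at `log(threshold)`.
#'
#' @param params An [lca_params()] object.
#' @param threshold_natural BALFRBC threshold, cells/uL (> 0).
#' @return A list with `sensitivity` and `specificity`.
#' @examples
#' test_metrics_at(default_study_params(), 992)
#' @export
test_metrics_at <- function(params, threshold_natural) {
  if (!inherits(params, "lca_params"))
    params <- do.call(lca_params, as.list(params)[param_names()])
  if (length(threshold_natural) != 1 || threshold_natural <= 0)
    stop("threshold_natural must be a single positive count", call. = FALSE)
  t <- log(threshold_natural)
  list(sensitivity = 1 - stats::pnorm((t - params$mu_pos) / params$sigma_pos),
       specificity = stats::pnorm((t - params$mu_neg) / params$sigma_neg))
}
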