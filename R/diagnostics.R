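#' Split-chain potential scale reduction factor (R-hat)
#'
#' The classical between/within variance ratio, computed after splitting
#' each chain in half so that within-chain trends register as
#' between-chain disagreement.  With `m` (split) chains of length `n`,
#' within-variance `W` (mean of chain variances) and between-variance
#' `B = n * var(chain means)`, R-hat is
#' `sqrt( ((n-1)/n * W + B/n) / W )`.
#'
#' @param x A numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors, at least 2 chains of length >= 4.
#' @param split Split each chain in half first (default `TRUE`); `FALSE`
#'   gives the unsplit textbook statistic.
#' @return A single numeric value.
#' @export
split_rhat <- function(x, split = TRUE) {
  x <- as_chain_matrix(x)
  if (split) x <- split_chains(x)
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of the pooled chains
#'
#' Per-chain autocorrelation-sum estimate with Geyer's initial positive
#' sequence truncation: for each chain,
#' `ESS = n / (1 + 2 * sum(rho_k))`, the sum running over lags until the
#' first non-positive paired autocorrelation `rho_{2k} + rho_{2k+1}`;
#' chain estimates are added.
#'
#' @inheritParams split_rhat
#' @return A single numeric value (total across chains).
#' @export
ess_draws <- function(x) {
  x <- as_chain_matrix(x, min_chains = 1)
  sum(apply(x, 2, function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    rho <- stats::acf(v, lag.max = min(n - 1L, 1000L), plot = FALSE,
                      demean = TRUE)$acf[-1]
    s <- 0
    k <- 1L
    while (k <= length(rho)) {
      pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
      if (pair <= 0) break
      s <- s + pair
      k <- k + 2L
    }
    min(n, n / (1 + 2 * s))
  }))
}

#' Per-parameter convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for each latent-class parameter,
#' computed from the retained draws of all chains.
#'
#' @param draws Either an [eiph_lca()] fit or its `draws` data frame
#'   (columns `chain`, the parameters, ...).
#' @return A data frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(draws) {
  if (inherits(draws, "eiph_lca")) draws <- draws$draws
  stopifnot(is.data.frame(draws), "chain" %in% names(draws))
  pars <- intersect(param_names(), names(draws))
  chains <- sort(unique(draws$chain))
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  lens <- table(draws$chain)
  if (length(unique(lens)) != 1)
    stop("chains have unequal retained lengths: ",
         paste(lens, collapse = ", "), call. = FALSE)
  out <- lapply(pars, function(p) {
    m <- vapply(chains, function(ch) draws[[p]][draws$chain == ch],
                numeric(lens[1]))
    data.frame(parameter = p, rhat = split_rhat(m), ess = ess_draws(m))
  })
  do.call(rbind, out)
}

as_chain_matrix <- function(x, min_chains = 2) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1)
      stop("chains have unequal lengths: ", paste(lens, collapse = ", "),
           call. = FALSE)
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < min_chains)
    stop("need at least ", min_chains, " chain(s)", call. = FALSE)
  if (nrow(x) < 4) stop("chains must have length >= 4", call. = FALSE)
  x
}

split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}
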