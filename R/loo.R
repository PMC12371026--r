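## Pareto-smoothed importance-sampling leave-one-out cross-validation
## (PSIS-LOO) from pointwise posterior log-likelihoods.

#' Fit a generalized Pareto distribution to sample tails
#'
#' Zhang & Stephens (2009) empirical-Bayes estimator of the GPD shape k
#' and scale sigma, with the weak shape prior used for Pareto-k
#' regularization in PSIS.
#'
#' @param x positive exceedances (need not be sorted)
#' @return list(k, sigma)
#' @keywords internal
.gpdFit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3; prior_k <- 10
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(theta, function(b) mean(log1p(-b * x)), numeric(1))
  L <- n * (log(-theta / ks) - ks - 1)
  w <- vapply(jj, function(j) 1 / sum(exp(L - L[j])), numeric(1))
  b <- sum(theta * w)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  k <- (n * k + prior_k * 0.5) / (n + prior_k)
  list(k = k, sigma = sigma)
}

## GPD quantile function
.gpdQuantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smoothed importance sampling of one weight vector
#'
#' @param lw raw log importance weights
#' @return list(lw) smoothed, max-normalized log weights; \code{k} the
#'   Pareto shape diagnostic
#' @keywords internal
.psisSmooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exceed <= 0) || stats::sd(exceed) == 0)
    return(list(lw = lw, k = -Inf))
  gpd <- .gpdFit(exceed[exceed > 0])
  if (is.finite(gpd$k)) {
    p <- (rank(lw[tail_idx], ties.method = "first") - 0.5) / M
    sm <- log(exp(cutoff) + .gpdQuantile(p, gpd$k, gpd$sigma))
    lw[tail_idx] <- pmin(sm, 0)
  }
  list(lw = lw, k = gpd$k)
}

#' PSIS-LOO for one fitted model
#'
#' Computes the expected log pointwise predictive density under exact
#' leave-one-out cross-validation, approximated by Pareto-smoothed
#' importance sampling of the posterior draws, and the LOO information
#' criterion LOOIC = -2 elpd_loo with its standard error.
#'
#' @param ll pointwise log-likelihood matrix (draws x observations) or a
#'   \code{\link{BefFit}}
#' @return list: \code{elpd_loo}, \code{looic}, \code{se_looic},
#'   \code{pointwise}, \code{pareto_k} (one per observation)
#' @export
psisLoo <- function(ll) {
  if (is(ll, "BefFit")) ll <- pointwiseLogLik(ll)
  n <- ncol(ll)
  elpd <- numeric(n); k <- numeric(n)
  for (i in seq_len(n)) {
    li <- ll[, i]
    ps <- .psisSmooth(-li)
    lw <- ps$lw - logSumExp(ps$lw)
    elpd[i] <- logSumExp(lw + li)
    k[i] <- ps$k
  }
  list(elpd_loo = sum(elpd), looic = -2 * sum(elpd),
       se_looic = 2 * sqrt(n * stats::var(elpd)),
       pointwise = elpd, pareto_k = k)
}

#' Compare BEF models by LOOIC
#'
#' Ranks fits of the same observations by LOO information criterion
#' (lower is better). Fits must share the response data; high Pareto-k
#' observations (k > 0.7) are surfaced as a warning.
#'
#' @param fits named list of \code{\link{BefFit}} objects
#' @return data.frame ordered by LOOIC: model, ell, looic, se_looic,
#'   elpd_loo, delta_looic, n_high_pareto_k
#' @export
compareModelsLoo <- function(fits) {
  stopifnot(length(fits) >= 1)
  ys <- lapply(fits, function(f) f@design$y)
  if (!all(vapply(ys, function(y) isTRUE(all.equal(y, ys[[1]])), logical(1))))
    stop("models were fitted to different observation sets")
  loos <- lapply(fits, psisLoo)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(
    model = nm,
    ell = vapply(fits, function(f) as.numeric(modelSpec(f)$ell), numeric(1)),
    looic = vapply(loos, `[[`, numeric(1), "looic"),
    se_looic = vapply(loos, `[[`, numeric(1), "se_looic"),
    elpd_loo = vapply(loos, `[[`, numeric(1), "elpd_loo"),
    n_high_pareto_k = vapply(loos, function(l)
      sum(l$pareto_k > 0.7, na.rm = TRUE), numeric(1)),
    row.names = NULL)
  out <- out[order(out$looic), ]
  out$delta_looic <- out$looic - out$looic[1]
  if (any(out$n_high_pareto_k > 0))
    warning("observations with Pareto k > 0.7 present; ",
            "LOO may be unreliable for those points")
  out
}
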