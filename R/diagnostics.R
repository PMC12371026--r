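## Model checking: randomized-quantile residuals from posterior predictive
## draws, and Moran's I spatial autocorrelation with a permutation test.

#' Moran's I with inverse-distance weights and a permutation test
#'
#' Weights are inverse great-circle distances (diagonal zero), row
#' standardized; coincident points receive half the smallest positive
#' distance. Under spatial independence E[I] = -1/(n-1). The p-value is
#' two-sided from \code{n_perm} random permutations of the values.
#'
#' @param z numeric values (e.g. residuals), one per location
#' @param coords matrix/data.frame with columns \code{lon}, \code{lat}
#'   (degrees)
#' @param n_perm number of permutations
#' @param seed integer seed for the permutations
#' @return list: \code{observed}, \code{expected}, \code{p_value},
#'   \code{n_perm}
#' @export
moranTest <- function(z, coords, n_perm = 999, seed = 1L) {
  n <- length(z)
  coords <- as.matrix(coords[, c("lon", "lat")])
  if (nrow(coords) != n) stop("coords must match the values")
  d <- geosphere::distm(coords) / 1000  # km
  diag(d) <- NA
  if (all(d == 0, na.rm = TRUE)) {
    warning("all coordinates identical; Moran's I skipped")
    return(list(observed = NA_real_, expected = -1 / (n - 1),
                p_value = NA_real_, n_perm = 0L))
  }
  dmin <- min(d[d > 0], na.rm = TRUE)
  d[d == 0] <- dmin / 2
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  I_of <- function(v) sum(w * tcrossprod(v)) / sum(v^2)
  obs <- I_of(zc)
  e0 <- -1 / (n - 1)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) I_of(sample(zc)), numeric(1))
  p <- (1 + sum(abs(perm - e0) >= abs(obs - e0))) / (n_perm + 1)
  list(observed = obs, expected = e0, p_value = p, n_perm = n_perm)
}

#' Randomized-quantile residuals and spatial diagnostics for a BEF fit
#'
#' Simulates posterior predictive replicates for every observation,
#' converts each observation to its randomized predictive quantile (the
#' probability integral transform, randomized within ties for the discrete
#' negative-binomial case), tests the quantiles for uniformity
#' (Kolmogorov-Smirnov), and — when coordinates are available — tests the
#' normal-score residuals for spatial autocorrelation with
#' \code{\link{moranTest}}. For a well-specified model the quantiles are
#' uniform and Moran's I is near -1/(n-1).
#'
#' @param fit a \code{\link{BefFit}}
#' @param n_rep number of posterior predictive replicates per observation
#' @param coords optional lon/lat matrix; defaults to the coordinates
#'   stored with the design
#' @param n_perm permutations for Moran's I
#' @param seed integer seed
#' @return list: \code{quantiles} (PIT values), \code{residuals}
#'   (normal scores), \code{ks_p}, \code{moran}
#' @export
residualDiagnostics <- function(fit, n_rep = 400, coords = NULL,
                                n_perm = 999, seed = 1L) {
  stopifnot(is(fit, "BefFit"))
  d <- posteriorDraws(fit)
  des <- fit@design
  spec <- modelSpec(fit)
  n <- length(des$y)
  set.seed(deriveSeed(seed, "ppc"))
  take <- sample(nrow(d), min(n_rep, nrow(d)))
  bcols <- colnames(des$X)
  beta <- d[take, bcols, drop = FALSE]
  a_realm <- d[take, paste0("alpha_realm.", des$realm_levels), drop = FALSE]
  eps <- d[take, paste0("eps_site.", des$site_levels), drop = FALSE]
  a_site <- a_realm[, des$realm_of_site, drop = FALSE] + eps
  eta <- tcrossprod(beta, des$X) + a_site[, des$site, drop = FALSE] +
    matrix(des$offset, length(take), n, byrow = TRUE)
  mu <- exp(eta)
  S <- length(take)
  if (spec$family == "gamma") {
    shape <- d[take, "phi"]
    yrep <- matrix(stats::rgamma(S * n, shape = shape, rate = shape / mu),
                   S, n)
    u <- colMeans(yrep < matrix(des$y, S, n, byrow = TRUE))
    u <- (u * S + stats::runif(n)) / (S + 1)
  } else {
    shape <- d[take, "omega"]
    yrep <- matrix(stats::rnbinom(S * n, size = shape, mu = mu), S, n)
    ymat <- matrix(des$y, S, n, byrow = TRUE)
    lt <- colMeans(yrep < ymat)
    eq <- colMeans(yrep == ymat)
    u <- lt + stats::runif(n) * (eq + 1 / (S + 1))
    u <- pmin(pmax(u, 1 / (2 * (S + 1))), 1 - 1 / (2 * (S + 1)))
  }
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  ks <- stats::ks.test(u, "punif")
  res <- stats::qnorm(u)
  if (is.null(coords)) coords <- des$coords
  moran <- if (is.null(coords)) {
    warning("no coordinates available; Moran's I skipped")
    NULL
  } else moranTest(res, coords, n_perm = n_perm,
                   seed = deriveSeed(seed, "moran"))
  list(quantiles = u, residuals = res, ks_p = ks$p.value, moran = moran)
}
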