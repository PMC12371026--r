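## Adaptive Hamiltonian Monte Carlo for the hierarchical BEF models.
##
## The posterior is sampled on an unconstrained parameterization: fixed
## effects, non-centered standardized random effects (z_realm, z_site),
## and log-transformed scale/shape parameters (with Jacobian terms).
## Warmup follows the windowed scheme used by modern gradient-based
## samplers: an initial step-size-only phase, doubling windows that
## re-estimate a diagonal mass matrix from the accumulated draws (each
## followed by a dual-averaging restart), and a final step-size-only
## phase. Trajectory lengths are set by a fixed integration time with
## +/-30% jitter. Step-size adaptation targets a 0.9 acceptance rate.

## Dual-averaging state (Nesterov primal-dual, as used in NUTS)
.daInit <- function(eps0) {
  list(mu = log(10 * eps0), le = log(eps0), lebar = log(eps0), H = 0, m = 0)
}
.daUpdate <- function(s, accept, target) {
  s$m <- s$m + 1
  s$H <- (1 - 1 / (s$m + 10)) * s$H + (target - accept) / (s$m + 10)
  s$le <- s$mu - sqrt(s$m) / 0.05 * s$H
  w <- s$m^(-0.75)
  s$lebar <- w * s$le + (1 - w) * s$lebar
  s
}

#' One adaptive HMC chain
#'
#' @param logpost_grad function(theta) returning list(lp, grad)
#' @param npar dimension
#' @param warmup,sampling iteration counts
#' @param seed chain seed
#' @param init initial parameter vector
#' @param target dual-averaging acceptance target
#' @param int_time leapfrog integration time (in mass-scaled units)
#' @return list(draws, lp, accept, divergences, step, mass)
#' @keywords internal
.hmcChain <- function(logpost_grad, npar, warmup, sampling, seed, init,
                      target = 0.9, int_time = 1.2) {
  set.seed(seed)
  th <- init
  cur <- logpost_grad(th)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initial values")
  minv <- rep(1, npar)                     # inverse mass = scale estimates
  draws <- matrix(NA_real_, sampling, npar)
  lpv <- numeric(sampling)
  ## warmup window layout
  w1 <- max(20, floor(0.15 * warmup)); w3 <- max(20, floor(0.10 * warmup))
  mass_end <- warmup - w3
  wins <- integer(); bsz <- 25; pos <- w1
  while (pos + bsz < mass_end) { wins <- c(wins, pos + bsz); pos <- pos + bsz
                                 bsz <- 2 * bsz }
  wins <- c(wins, mass_end)
  da <- .daInit(0.1)
  buf <- matrix(NA_real_, mass_end - w1, npar); nbuf <- 0L
  n_div <- 0L; n_acc <- 0
  for (it in seq_len(warmup + sampling)) {
    stp <- exp(da$le)
    L <- max(1, min(64, ceiling(int_time / stp * stats::runif(1, 0.7, 1.3))))
    rho <- stats::rnorm(npar, 0, 1 / sqrt(minv))
    th_p <- th; g_p <- cur
    rho_p <- rho + 0.5 * stp * g_p$grad
    ok <- TRUE
    for (l in seq_len(L)) {
      th_p <- th_p + stp * minv * rho_p
      g_p <- logpost_grad(th_p)
      if (!is.finite(g_p$lp)) { ok <- FALSE; break }
      rho_p <- rho_p + (if (l < L) stp else 0.5 * stp) * g_p$grad
    }
    a <- 0
    if (ok) {
      dH <- (-cur$lp + 0.5 * sum(rho^2 * minv)) -
            (-g_p$lp + 0.5 * sum(rho_p^2 * minv))
      if (is.finite(dH)) a <- min(1, exp(dH)) else ok <- FALSE
    }
    if (!ok && it > warmup) n_div <- n_div + 1L
    if (stats::runif(1) < a) { th <- th_p; cur <- g_p }
    if (it <= warmup) {
      da <- .daUpdate(da, a, target)
      if (it > w1 && it <= mass_end) { nbuf <- nbuf + 1L; buf[nbuf, ] <- th }
      if (it %in% wins) {
        if (nbuf >= 10) {
          bw <- buf[seq_len(nbuf), , drop = FALSE]
          v <- apply(bw, 2, stats::var)
          v <- (nbuf / (nbuf + 5)) * v + (5 / (nbuf + 5)) * 1e-3
          minv <- pmax(v, 1e-10)
        }
        nbuf <- 0L
        da <- .daInit(exp(da$lebar))
      }
      if (it == warmup) da$le <- da$lebar
    } else {
      draws[it - warmup, ] <- th
      lpv[it - warmup] <- cur$lp
      n_acc <- n_acc + a
    }
  }
  list(draws = draws, lp = lpv, accept = n_acc / sampling,
       divergences = n_div, step = exp(da$le), mass = 1 / minv)
}

#' Run several adaptive HMC chains
#' @inheritParams .hmcChain
#' @param chains number of chains
#' @param init_fn function(chain_id) returning an initial vector
#' @return list(draws [all chains stacked], chain, lp, accept, divergences,
#'   step)
#' @keywords internal
.hmcSample <- function(logpost_grad, npar, chains, warmup, sampling, seed,
                       init_fn, target = 0.9, int_time = 1.2) {
  res <- lapply(seq_len(chains), function(cc)
    .hmcChain(logpost_grad, npar, warmup, sampling,
              seed = deriveSeed(seed, paste0("chain", cc)),
              init = init_fn(cc), target = target, int_time = int_time))
  list(draws = do.call(rbind, lapply(res, `[[`, "draws")),
       chain = rep(seq_len(chains), each = sampling),
       lp = unlist(lapply(res, `[[`, "lp")),
       accept = vapply(res, `[[`, numeric(1), "accept"),
       divergences = vapply(res, `[[`, integer(1), "divergences"),
       step = vapply(res, `[[`, numeric(1), "step"))
}

#' Split-Rhat for one parameter
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed over the resulting 2C sequences.
#'
#' @param x draws vector
#' @param chain chain index per draw
#' @return split-Rhat (NA for zero-variance draws)
#' @keywords internal
.splitRhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  mus <- vapply(halves, mean, numeric(1))
  vs <- vapply(halves, stats::var, numeric(1))
  W <- mean(vs)
  B <- n * stats::var(mus)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## rank-normalize draws (fractional ranks -> standard normal)
.rankNormalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Bulk and tail effective sample size for one parameter
#'
#' Bulk ESS is computed on rank-normalized draws; tail ESS is the smaller
#' of the ESS of the 5\% and 95\% quantile exceedance indicators.
#'
#' @keywords internal
.essBulkTail <- function(x, chain) {
  mk <- function(v) coda::mcmc.list(lapply(split(v, chain), coda::mcmc))
  if (stats::sd(x) == 0) return(c(bulk = NA_real_, tail = NA_real_))
  bulk <- unname(coda::effectiveSize(mk(.rankNormalize(x))))
  q <- stats::quantile(x, c(0.05, 0.95))
  lo <- as.numeric(x <= q[1]); hi <- as.numeric(x >= q[2])
  tl <- min(unname(coda::effectiveSize(mk(.rankNormalize(lo)))),
            unname(coda::effectiveSize(mk(.rankNormalize(hi)))))
  c(bulk = bulk, tail = tl)
}
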