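makeModelData <- function(n = 120, n_sites = 12, seed = 1) {
  set.seed(seed)
  site_num <- rep_len(seq_len(n_sites), n)
  realm <- paste0("r", ((site_num - 1) %% 4) + 1)
  data.frame(
    y = rgamma(n, 5, 1), logD = rnorm(n),
    tropical = realm %in% c("r1", "r2"),
    sst = runif(n, 5, 29), visibility = runif(n, 5, 25),
    depth = runif(n, 2, 18), site_id = sprintf("s%02d", site_num),
    realm = realm, abundance = rpois(n, 50) + 1,
    lat = runif(n, -50, 50), lon = runif(n, -180, 180))
}

test_that("design preparation z-scores covariates and builds the interaction", {
  d <- makeModelData(n = 3, n_sites = 3, seed = 2)
  d$sst <- c(1, 2, 3)
  spec <- befModelSpec("productivity")
  des <- prepareDesign(d, spec)
  expect_s3_class(des, "bef_design")
  expect_equal(unname(des$X[, "b_sst"]), c(-1, 0, 1))
  expect_equal(colnames(des$X), c("b0", "b_D", "b_trop", "b_D_trop",
                                  "b_sst", "b_vis", "b_depth"))
  expect_equal(unname(des$X[, "b_D_trop"]),
               unname(des$X[, "b_D"] * des$X[, "b_trop"]))
  expect_equal(mean(des$X[, "b_D"]), 0, tolerance = 1e-12)
  expect_equal(sd(des$X[, "b_D"]), 1, tolerance = 1e-12)
  ## scaling constants stored for inversion
  expect_equal(des$scaling$sst$mean, 2)
  expect_equal(des$scaling$sst$sd, 1)
  expect_equal(des$offset, rep(0, 3))
})

test_that("Boltzmann temperature scaling transforms before z-scoring", {
  d <- makeModelData(n = 60, seed = 3)
  spec_b <- befModelSpec("productivity", temperature_scale = "boltzmann")
  des_b <- prepareDesign(d, spec_b)
  kB <- 8.617333e-5
  inv <- 1 / (kB * (d$sst + 273.15))
  expect_equal(unname(des_b$X[, "b_sst"]), (inv - mean(inv)) / sd(inv),
               tolerance = 1e-12)
  ## the constant arithmetic: 27 C -> 38.66 eV^-1
  expect_equal(1 / (kB * (27 + 273.15)), 38.66, tolerance = 1e-3)
})

test_that("design preparation enforces its contracts", {
  d <- makeModelData(seed = 4)
  spec <- befModelSpec("productivity")
  d2 <- d; d2$realm[3] <- NA
  expect_error(prepareDesign(d2, spec), "must not be missing")
  d3 <- d; d3$visibility <- 10
  expect_error(prepareDesign(d3, spec), "zero-variance covariate: visibility")
  d4 <- d; d4$y[1] <- -1
  expect_error(prepareDesign(d4, spec), "strictly positive")
  ## per-capita response requires abundance, then offsets by its log
  spec_pc <- befModelSpec("percap")
  des_pc <- prepareDesign(d, spec_pc)
  expect_equal(des_pc$offset, log(d$abundance))
  expect_error(prepareDesign(d[, names(d) != "abundance"], spec_pc),
               "abundance")
  ## a site in two realms is malformed
  d5 <- d; d5$realm[d5$site_id == "s01"][1] <- "r2"
  expect_error(prepareDesign(d5, spec), "more than one realm")
})

test_that("family log-likelihoods agree with the d* densities", {
  set.seed(5)
  y <- rgamma(30, 4, 2); eta <- rnorm(30); phi <- 3.2
  expect_equal(fishBEF:::.famLogLik("gamma", y, eta, phi),
               dgamma(y, shape = phi, rate = phi / exp(eta), log = TRUE),
               tolerance = 1e-12)
  yc <- rpois(30, 6); om <- 1.7
  expect_equal(fishBEF:::.famLogLik("negbin", yc, eta, om),
               dnbinom(yc, size = om, mu = exp(eta), log = TRUE),
               tolerance = 1e-12)
})

test_that("the posterior matches an independent Gibbs sampler (rjags)", {
  truth <- gammaTruth()
  dat <- genGlmmExactDataset(truth, n = 250, n_sites = 20, n_realms = 4,
                             family = "gamma", seed = 11)
  spec <- befModelSpec("productivity", chains = 2, warmup = 800,
                       sampling = 800, strict = FALSE, seed = 21)
  fit <- suppressWarnings(fitBefGlmm(prepareDesign(dat, spec), spec))
  s <- summarizePosterior(fit)
  ## oracle: the same model in JAGS
  library(rjags)
  des <- prepareDesign(dat, spec)
  mod_str <- "
  model {
    eta <- X %*% beta
    for (i in 1:n) {
      y[i] ~ dgamma(phi, phi / mu[i])
      log(mu[i]) <- eta[i] + a_site[site[i]]
    }
    for (s in 1:S) {
      a_site[s] <- a_realm[realm[s]] + eps[s]
      eps[s] ~ dnorm(0, 1 / (sigma_site^2))
    }
    for (r in 1:R) { a_realm[r] ~ dnorm(0, 1 / (sigma_realm^2)) }
    beta[1] ~ dnorm(0, 1/25)
    for (k in 2:p) { beta[k] ~ dnorm(0, 1) }
    sigma_site ~ dnorm(0, 1) T(0,)
    sigma_realm ~ dnorm(0, 1) T(0,)
    phi ~ dgamma(0.01, 0.01)
  }"
  jm <- jags.model(textConnection(mod_str),
    data = list(y = des$y, X = unname(des$X), n = length(des$y),
                p = ncol(des$X), site = des$site, S = length(des$site_levels),
                R = length(des$realm_levels), realm = des$realm_of_site),
    n.chains = 2, n.adapt = 400, quiet = TRUE)
  update(jm, 600)
  samp <- coda.samples(jm, c("beta", "phi", "sigma_site"), n.iter = 1000)
  js <- summary(samp)$statistics
  ## slope posteriors agree between the two samplers
  expect_lt(abs(s$median[s$coefficient == "b_D"] - js["beta[2]", "Mean"]),
            3 * js["beta[2]", "SD"])
  expect_lt(abs(s$median[s$coefficient == "b_sst"] - js["beta[5]", "Mean"]),
            3 * js["beta[5]", "SD"])
  expect_lt(abs(s$median[s$coefficient == "phi"] - js["phi", "Mean"]),
            0.15 * js["phi", "Mean"])
  expect_lt(abs(s$median[s$coefficient == "sigma_site"] -
                js["sigma_site", "Mean"]), 3 * js["sigma_site", "SD"])
  ## posterior widths agree too (b_D sd within 30%)
  width <- (s$q95[s$coefficient == "b_D"] - s$q05[s$coefficient == "b_D"]) /
    (2 * qnorm(0.95))
  expect_lt(abs(width - js["beta[2]", "SD"]), 0.3 * js["beta[2]", "SD"])
})

test_that("negative-binomial fits recover their generator", {
  truth <- nbTruth()
  dat <- genGlmmExactDataset(truth, n = 300, n_sites = 30, n_realms = 4,
                             family = "negbin", seed = 7)
  spec <- befModelSpec("abundance", chains = 2, warmup = 700, sampling = 700,
                       strict = FALSE, seed = 3)
  fit <- suppressWarnings(fitBefGlmm(prepareDesign(dat, spec), spec))
  s <- summarizePosterior(fit)
  expect_true(s$q05[s$coefficient == "b_D"] <= 1.5 &&
              1.5 <= s$q95[s$coefficient == "b_D"])
  expect_true(s$q05[s$coefficient == "omega"] <= 2 &&
              2 <= s$q95[s$coefficient == "omega"])
  expect_error(fitBefGlmm(prepareDesign(transform(dat, y = y + 0.5), spec),
                          spec), "counts")
})

test_that("posterior summaries report ordered quantile intervals", {
  set.seed(6)
  draws <- cbind(b_D = rnorm(4000, 1.10, 0.01), b0 = rnorm(4000))
  fit <- fakeBefFit(draws)
  s <- summarizePosterior(fit, c("b_D", "b0"))
  expect_equal(s$median[1], 1.10, tolerance = 3 * 0.01 / sqrt(4000) * 1.5)
  expect_equal(s$q05[1], qnorm(0.05, 1.10, 0.01), tolerance = 1e-3)
  expect_equal(s$q95[1], qnorm(0.95, 1.10, 0.01), tolerance = 1e-3)
  expect_true(all(s$q05 <= s$q25 & s$q25 <= s$median &
                  s$median <= s$q75 & s$q75 <= s$q95))
  const <- fakeBefFit(cbind(b_D = rep(2, 100)))
  sc <- summarizePosterior(const, "b_D")
  expect_equal(sc$q05, sc$q95)
})

test_that("split-Rhat and ESS flag healthy and pathological chains", {
  set.seed(7)
  good <- rnorm(2000)
  chain <- rep(1:2, each = 1000)
  expect_lt(fishBEF:::.splitRhat(good, chain), 1.01)
  bad <- c(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(fishBEF:::.splitRhat(bad, chain), 1.5)
  ess <- fishBEF:::.essBulkTail(good, chain)
  expect_gt(ess[["bulk"]], 1000)
  ## checkConvergence contract
  fit <- fakeBefFit(cbind(b_D = good))
  cc <- checkConvergence(fit, ess_min = 100)
  expect_true(cc$pass)
  fit1 <- fakeBefFit(cbind(b_D = good), chain = rep(1L, 2000))
  expect_error(checkConvergence(fit1), "2 chains")
})
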