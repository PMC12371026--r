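test_that("truncated-normal Kmax draws honour the quantile range", {
  set.seed(1)
  x <- drawKmaxSample(0.2, 0.6, 1e5)
  expect_true(all(x >= 0.2 & x <= 0.6))
  ## symmetric truncation keeps the midpoint mean
  expect_lt(abs(mean(x) - 0.4), 3 * sd(x) / sqrt(1e5) + 1e-4)
  ## sd parameter makes the *untruncated* 90% interval the quantile range;
  ## truncating to the central 90% shrinks the realized variance by the
  ## standard truncated-normal factor 1 - 2a*phi(a)/(2*Phi(a)-1), a = 1.645
  a <- qnorm(0.95)
  shrink <- sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
  expect_equal(sd(x), (0.6 - 0.2) / 3.2897 * shrink, tolerance = 0.005)
  expect_identical(drawKmaxSample(0.3, 0.3, 5), rep(0.3, 5))
  expect_error(drawKmaxSample(0.6, 0.2), ">=")
  set.seed(9); a <- drawKmaxSample(0.1, 0.5, 10)
  set.seed(9); b <- drawKmaxSample(0.1, 0.5, 10)
  expect_identical(a, b)
})

test_that("individual daily production follows the VBGF step", {
  ## closed form: age at 50 cm, one day ahead, allometric difference
  t <- log(2) / 0.5
  L1 <- 100 * (1 - exp(-0.5 * (t + 1 / 365)))
  expect_equal(individualDailyProduction(50, 0.5, 100, 0.01, 3),
               0.01 * (L1^3 - 50^3), tolerance = 1e-12)
  expect_equal(individualDailyProduction(50, 0.5, 100, 0.01, 3), 5.14,
               tolerance = 1e-2)
  ## at (or beyond) the asymptote production is exactly zero
  expect_equal(individualDailyProduction(100, 0.5, 100, 0.01, 3), 0)
  expect_equal(individualDailyProduction(120, 0.5, 100, 0.01, 3), 0)
  ## vanishing growth coefficient -> vanishing production
  expect_lt(individualDailyProduction(50, 1e-8, 100, 0.01, 3), 1e-3)
  ## vectorized over individuals
  out <- individualDailyProduction(c(10, 50), c(0.5, 0.5), 100, 0.01, 3)
  expect_length(out, 2)
  expect_true(all(out >= 0))
})

test_that("a single fish with a degenerate interval gives its exact growth", {
  ss <- toySurveySet(list(a = 10), lmax = 40)
  pr <- toyPredictions("a", q05 = 0.5, q95 = 0.5)
  out <- communityProductivity(ss, pr, n_boot = 7, seed = 1)
  ## census length is the size-class midpoint (bin 10 spans 7.5-10)
  expected <- individualDailyProduction(8.75, 0.5, 40, 0.01, 3)
  expect_equal(out$productivity_median, expected, tolerance = 1e-12)
  expect_equal(out$productivity_q05, out$productivity_q95)
  expect_equal(out$abundance, 1)
  expect_equal(out$percap_median, expected, tolerance = 1e-12)
})

test_that("production is additive: duplicating a fish doubles the total", {
  ss1 <- toySurveySet(list(a = 10), lmax = 40)
  cnt2 <- surveyCounts(ss1); cnt2$count <- cnt2$count * 2
  ss2 <- new("SurveySet", counts = cnt2, surveys = surveyData(ss1),
             species = speciesTraits(ss1))
  pr <- toyPredictions("a", 0.4, 0.4)
  o1 <- communityProductivity(ss1, pr, n_boot = 5, seed = 3)
  o2 <- communityProductivity(ss2, pr, n_boot = 5, seed = 3)
  expect_equal(o2$productivity_median, 2 * o1$productivity_median,
               tolerance = 1e-12)
})

test_that("vectorized totals equal a brute-force per-individual loop", {
  ## 30-individual toy survey over 3 species, shared seed stream
  lengths <- list(a = c(5, 10, 15, 20, 5, 10, 25, 30, 5, 10),
                  b = c(10, 12.5, 15, 20, 25, 30, 35, 40, 10, 15),
                  c = c(2.5, 5, 7.5, 10, 12.5, 15, 20, 25, 30, 35))
  ss <- toySurveySet(lengths, lmax = c(a = 60, b = 80, c = 50),
                     lw_a = 0.012, lw_b = 2.95)
  pr <- toyPredictions(c("a", "b", "c"), q05 = c(0.2, 0.15, 0.3),
                       q95 = c(0.5, 0.4, 0.9))
  n_boot <- 50; seed <- 77
  out <- communityProductivity(ss, pr, n_boot = n_boot, seed = seed)
  ## independent loop implementation, same uniform stream
  cnt <- surveyCounts(ss); cnt <- cnt[cnt$count > 0, ]
  sp <- speciesTraits(ss)
  idx <- rep(seq_len(nrow(cnt)), cnt$count)
  species <- cnt$species_id[idx]
  bins <- sort(unique(c(0, fishBEF:::rlsSizeBins())))
  pos <- findInterval(cnt$size_class_cm[idx], bins)
  len <- (bins[pos] + bins[pmax(pos - 1, 1)]) / 2
  n_ind <- length(idx)
  prd <- as.data.frame(pr)
  pp <- match(species, prd$species_id)
  q05 <- prd$q05[pp]; q95 <- prd$q95[pp]
  m <- (q05 + q95) / 2; s <- (q95 - q05) / 3.2897
  set.seed(fishBEF:::deriveSeed(seed, "prod_sv1"))
  u <- matrix(runif(n_boot * n_ind), nrow = n_boot, byrow = TRUE)
  totals <- numeric(n_boot)
  for (bt in seq_len(n_boot)) {
    tot <- 0
    for (i in seq_len(n_ind)) {
      ki <- qnorm(pnorm(q05[i], m[i], s[i]) +
                  u[bt, i] * (pnorm(q95[i], m[i], s[i]) -
                              pnorm(q05[i], m[i], s[i])), m[i], s[i])
      ki <- min(max(ki, q05[i]), q95[i])
      lmax_i <- sp$lmax_cm[match(species[i], sp$species_id)]
      t_i <- -log(1 - len[i] / lmax_i) / ki
      L1 <- lmax_i * (1 - exp(-ki * (t_i + 1 / 365)))
      tot <- tot + 0.012 * (L1^2.95 - len[i]^2.95)
    }
    totals[bt] <- tot
  }
  expect_equal(out$productivity_median, median(totals), tolerance = 1e-9)
  expect_equal(unname(out$productivity_q05),
               unname(quantile(totals, 0.05)), tolerance = 1e-9)
  expect_equal(unname(out$productivity_q95),
               unname(quantile(totals, 0.95)), tolerance = 1e-9)
  ## per-capita times abundance reconstructs the total
  expect_equal(out$percap_median * out$abundance, out$productivity_median,
               tolerance = 1e-9)
})

test_that("surveys failing preconditions are excluded or rejected", {
  ss <- toySurveySet(list(a = c(10, 20), b = c(15, 25)))
  ## remove block 2 of the survey -> single-block exclusion
  cnt <- surveyCounts(ss)
  one_block <- cnt[cnt$block == 1, ]
  one_block$survey_id <- "sv_single"
  sv2 <- rbind(surveyData(ss),
               within(surveyData(ss), survey_id <- "sv_single"))
  both <- rbind(cnt, one_block)
  ss2 <- new("SurveySet", counts = both, surveys = sv2,
             species = speciesTraits(ss))
  pr <- toyPredictions(c("a", "b"), c(0.2, 0.2), c(0.5, 0.5))
  expect_message(out <- communityProductivity(ss2, pr, n_boot = 3, seed = 1),
                 "single-block")
  expect_equal(attr(out, "excluded"), "sv_single")
  expect_false("sv_single" %in% out$survey_id)
  ## missing prediction is an error naming the species
  pr_a <- toyPredictions("a", 0.2, 0.5)
  expect_error(communityProductivity(ss, pr_a, n_boot = 3, seed = 1), "b")
})

test_that("per-survey seeds make results order-invariant", {
  ss <- toySurveySet(list(a = c(10, 20, 30, 15)))
  cnt <- surveyCounts(ss)
  cnt2 <- cnt; cnt2$survey_id <- "sv2"
  sv <- rbind(surveyData(ss), within(surveyData(ss), survey_id <- "sv2"))
  ss_ab <- new("SurveySet", counts = rbind(cnt, cnt2), surveys = sv,
               species = speciesTraits(ss))
  ss_ba <- new("SurveySet", counts = rbind(cnt2, cnt), surveys = sv,
               species = speciesTraits(ss))
  pr <- toyPredictions("a", 0.2, 0.6)
  oa <- communityProductivity(ss_ab, pr, n_boot = 11, seed = 5)
  ob <- communityProductivity(ss_ba, pr, n_boot = 11, seed = 5)
  oa <- oa[order(oa$survey_id), ]; ob <- ob[order(ob$survey_id), ]
  expect_equal(oa$productivity_median, ob$productivity_median)
})
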