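test_that("configuration validation catches bad parameters", {
  expect_error(synthConfig(n_species = 0), "counts")
  expect_error(synthConfig(trait_distributions = list(
    lmax_meanlog = log(30), lmax_sdlog = 0.7, trophic_min = 2,
    trophic_max = 4.6, depth_meanlog = log(30), depth_sdlog = 0.8,
    water_position_probs = c(benthic = 0.5, demersal = 0.4, pelagic = 0.2))),
    "sum to 1")
  am <- synthConfig()$abundance_model; am$omega <- -1
  expect_error(synthConfig(abundance_model = am), "omega")
  pm <- synthConfig()$productivity_model; pm$phi <- 0
  expect_error(synthConfig(productivity_model = pm), "phi")
})

test_that("species pool generation is seeded and honours distributions", {
  cfg <- smallConfig(seed = 11)
  sp1 <- genSpeciesPool(cfg); sp2 <- genSpeciesPool(cfg)
  expect_identical(sp1, sp2)
  ## degenerate Lmax distribution pins the trait exactly
  td <- cfg$trait_distributions
  td$lmax_meanlog <- log(100); td$lmax_sdlog <- 0
  one <- genSpeciesPool(synthConfig(n_species = 1, trait_distributions = td,
                                    seed = 1))
  expect_equal(one$lmax_cm, 100)
  expect_true(all(sp1$lw_a >= 0.005 & sp1$lw_a <= 0.05))
  expect_true(all(sp1$lw_b >= 2.8 & sp1$lw_b <= 3.2))
  expect_true(all(sp1$trophic_level >= 2 & sp1$trophic_level <= 4.6))
})

test_that("latent growth declines with maximum length", {
  sp <- genSpeciesPool(synthConfig(n_species = 500, seed = 5))
  expect_lt(cor(sp$latent_kmax, sp$lmax_cm, method = "spearman"), 0)
})

test_that("growth records follow the latent model", {
  cfg <- smallConfig(seed = 3)
  sp <- genSpeciesPool(cfg)
  gr <- genGrowthRecords(sp, 4, cfg)
  expect_equal(nrow(gr$records), 4 * nrow(sp))
  expect_true(all(gr$records$aging_method %in% agingMethods()))
  expect_true(all(gr$records$length_type %in% c("TL", "SL", "FL")))
  ## reported L_inf back-converted to TL never exceeds 1.1 x Lmax
  tl <- standardizeLength(gr$records$l_inf_reported, gr$records$length_type,
                          gr$records$species_id, gr$conversions)
  lmax <- sp$lmax_cm[match(gr$records$species_id, sp$species_id)]
  expect_true(all(tl <= 1.1 * lmax + 1e-9))
  expect_error(genGrowthRecords(sp, 0, cfg), ">= 1")
  expect_error(genGrowthRecords(sp[0, ], 3, cfg), "empty")
})

test_that("zero growth noise pins K at the latent mean", {
  cfg <- smallConfig(seed = 3, growth_noise_sd = 0)
  sp <- genSpeciesPool(cfg)
  gr <- genGrowthRecords(sp, 3, cfg)
  expect_equal(gr$records$k, gr$records$latent_k)
})

test_that("log K is centred on the latent model at Monte-Carlo scale", {
  cfg <- synthConfig(n_species = 500, growth_noise_sd = 0.2, seed = 17)
  sp <- genSpeciesPool(cfg)
  gr <- genGrowthRecords(sp, 20, cfg)   # 10000 records
  dev <- log(gr$records$k) - log(gr$records$latent_k)
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se)
})

test_that("negative-binomial counts reduce to Poisson as omega grows", {
  set.seed(8)
  x <- fishBEF:::rNegBin(5000, 10, 1e8)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
  y <- fishBEF:::rNegBin(50000, 10, 2)
  expect_equal(var(y), 10 + 100 / 2, tolerance = 0.05 * 60)
  expect_error(fishBEF:::rNegBin(10, 5, 0), "positive")
})

test_that("survey generation nests sites in realms and is reproducible", {
  cfg <- smallConfig(seed = 7)
  sp <- genSpeciesPool(cfg)
  s1 <- genSurveyDataset(sp, cfg); s2 <- genSurveyDataset(sp, cfg)
  expect_identical(surveyCounts(s1), surveyCounts(s2))
  expect_identical(surveyData(s1), surveyData(s2))
  expect_true(validObject(s1))
  sv <- surveyData(s1)
  expect_equal(nrow(sv), cfg$n_sites * cfg$n_surveys_per_site)
  ## realm implies the tropical flag
  expect_true(all(tapply(sv$tropical, sv$realm,
                         function(x) length(unique(x))) == 1))
  ## every survey has two blocks
  blocks <- tapply(surveyCounts(s1)$block, surveyCounts(s1)$survey_id,
                   function(b) length(unique(b)))
  expect_true(all(blocks == 2))
  ## size classes never exceed the species maximum length
  cnt <- surveyCounts(s1)
  lmax <- sp$lmax_cm[match(cnt$species_id, sp$species_id)]
  expect_true(all(cnt$size_class_cm <= lmax))
  gt <- groundTruth(s1)
  expect_equal(gt$abundance$beta[["b_D"]], 1.5)
})

test_that("single-realm survey configuration is rejected", {
  cfg <- smallConfig(realms = data.frame(realm = "only", tropical = TRUE))
  sp <- genSpeciesPool(cfg)
  expect_error(genSurveyDataset(sp, cfg), ">= 2 realms")
})

test_that("a unit species pool forces monocultures", {
  cfg <- smallConfig(seed = 9, survey_pool_range = c(1, 1))
  sp <- genSpeciesPool(cfg)
  ss <- genSurveyDataset(sp, cfg)
  rich <- tapply(surveyCounts(ss)$species_id, surveyCounts(ss)$survey_id,
                 function(x) length(unique(x)))
  expect_true(all(rich == 1))
})

test_that("exact GLMM simulation matches its stated moments", {
  ## null model: all beta 0 -> mean(y) ~ exp(0) = 1
  tr0 <- list(beta = c(b0 = 0, b_D = 0, b_trop = 0, b_D_trop = 0,
                       b_sst = 0, b_vis = 0, b_depth = 0),
              sigma_site = 0, sigma_realm = 0, phi = 5)
  d0 <- genGlmmExactDataset(tr0, n = 20000, n_sites = 10, seed = 2)
  expect_equal(mean(d0$y), 1, tolerance = 3 * sd(d0$y) / sqrt(20000) / 1 + 0.01)
  ## gamma variance: mu = 2, phi = 8 -> var = mu^2/phi = 0.5
  tr1 <- tr0; tr1$beta[["b0"]] <- log(2); tr1$phi <- 8
  d1 <- genGlmmExactDataset(tr1, n = 50000, n_sites = 10, seed = 3)
  expect_equal(var(d1$y), 0.5, tolerance = 0.05 * 0.5)
  ## sigma_site = 0 collapses site effects within realm
  tr2 <- gammaTruth(); tr2$sigma_site <- 0
  d2 <- genGlmmExactDataset(tr2, n = 200, n_sites = 20, seed = 4)
  eff <- attr(d2, "truth")$eps_site
  expect_true(all(eff == 0))
  ## NB variance identity: mu = 10, omega = 2 -> var = 60
  tr3 <- tr0; tr3$beta[["b0"]] <- log(10); tr3$phi <- NULL; tr3$omega <- 2
  d3 <- genGlmmExactDataset(tr3, n = 50000, n_sites = 10,
                            family = "negbin", seed = 5)
  expect_equal(var(d3$y), 60, tolerance = 0.05 * 60)
  expect_error(genGlmmExactDataset(tr0[names(tr0) != "phi"], 100,
                                   family = "gamma"), "phi")
})

test_that("survey sets round-trip through CSV + JSON serialization", {
  cfg <- smallConfig(seed = 13)
  sp <- genSpeciesPool(cfg)
  ss <- genSurveyDataset(sp, cfg)
  dir <- file.path(tempdir(), "ss_roundtrip")
  writeSurveySet(ss, dir)
  back <- readSurveySet(dir)
  expect_equal(surveyCounts(back), surveyCounts(ss), tolerance = 1e-12)
  expect_equal(surveyData(back)$sst, surveyData(ss)$sst, tolerance = 1e-12)
  expect_equal(groundTruth(back)$abundance$beta[["b_D"]],
               groundTruth(ss)$abundance$beta[["b_D"]])
  expect_true(validObject(back))
})

test_that("survey sets reject malformed structure", {
  ss <- toySurveySet(list(a = c(10, 20)))
  bad <- surveyCounts(ss); bad$count[1] <- -2
  expect_error(new("SurveySet", counts = bad, surveys = surveyData(ss),
                   species = speciesTraits(ss)), "non-negative")
  bad2 <- surveyCounts(ss); bad2$block[1] <- 3
  expect_error(new("SurveySet", counts = bad2, surveys = surveyData(ss),
                   species = speciesTraits(ss)), "labelled 1 or 2")
})
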