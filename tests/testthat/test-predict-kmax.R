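test_that("feature assembly joins traits and applies taxonomic fallback", {
  cfg <- smallConfig(seed = 19)
  sp <- genSpeciesPool(cfg)
  gr <- genGrowthRecords(sp, 4, cfg)
  f <- assembleFeatures(gr$records, sp, gr$conversions)
  expect_equal(nrow(f), nrow(gr$records))
  expect_true(all(c("kmax", "lmax_cm", "trophic_level", "max_depth_m",
                    "water_position", "sst", "aging_method") %in% names(f)))
  expect_true(all(f$fallback_level == "species"))
  expect_true(all(f$kmax > 0))
  ## knock out one species' depth: genus sibling fills in
  sp2 <- sp
  gsel <- sp2$genus[1]
  victims <- which(sp2$genus == gsel)
  stopifnot(length(victims) >= 2)
  sp2$max_depth_m[victims[1]] <- NA
  f2 <- assembleFeatures(gr$records, sp2, gr$conversions)
  hit <- f2$species_id == sp2$species_id[victims[1]]
  expect_true(all(f2$fallback_level[hit] == "genus"))
  expect_equal(unique(f2$max_depth_m[hit]),
               mean(sp2$max_depth_m[victims[-1]]))
  ## knock out the whole genus: family fills in
  sp3 <- sp2
  sp3$max_depth_m[victims] <- NA
  f3 <- assembleFeatures(gr$records, sp3, gr$conversions)
  expect_true(all(f3$fallback_level[hit] == "family"))
  ## unresolvable trait after family fallback
  sp4 <- sp
  fam <- sp4$family[1]
  sp4$max_depth_m[sp4$family == fam] <- NA
  expect_error(assembleFeatures(gr$records, sp4, gr$conversions),
               "unresolved")
})

test_that("tuning is reproducible and respects the hyperparameter space", {
  f <- monotoneFeatures(300, seed = 2)
  m1 <- tuneAndFit(f, grid_size = 4, nrounds = 40, seed = 6)
  m2 <- tuneAndFit(f, grid_size = 4, nrounds = 40, seed = 6)
  expect_equal(predict(m1, f[1:20, ]), predict(m2, f[1:20, ]))
  grids <- rbind(m1$grids$step1, m1$grids$step2)
  expect_true(all(grids$eta > 0 & grids$eta <= 1))
  expect_true(all(grids$gamma > 0 & grids$gamma <= 1))
  expect_true(all(grids$max_depth %in% c(5L, 10L, 15L)))
  expect_true(all(grids$subsample > 0 & grids$subsample <= 1))
  ## step-2 grid concentrates around the step-1 optimum
  best1 <- m1$grids$step1[which.min(m1$grids$step1$loss), ]
  expect_true(all(abs(m1$grids$step2$eta - best1$eta) <= 0.081))
  ## constant target warns but proceeds
  fc <- f; fc$kmax <- 0.5
  expect_warning(tuneAndFit(fc, grid_size = 2, nrounds = 5, seed = 1),
                 "constant")
})

test_that("a trait-driven model beats the intercept-only baseline", {
  f <- monotoneFeatures(600, seed = 3)
  m <- tuneAndFit(f, grid_size = 4, nrounds = 60, seed = 4)
  test <- m$test
  pred <- predict(m, test)
  gamma_dev <- function(obs, fit) 2 * sum((obs - fit) / fit - log(obs / fit))
  expect_lt(gamma_dev(test$kmax, pred),
            gamma_dev(test$kmax, rep(mean(f$kmax), nrow(test))))
})

test_that("holdout metrics match their definitions", {
  f <- monotoneFeatures(50, seed = 5)
  m <- tuneAndFit(f, grid_size = 2, nrounds = 10, seed = 5)
  test <- m$test
  ## perfect predictions
  ev <- evaluateHoldout(m, test, predictions = test$kmax)
  expect_equal(ev$bias, 0)
  expect_equal(ev$r2_loglog, 1)
  ## doubling preserves log-log fit, bias = mean(observed)
  ev2 <- evaluateHoldout(m, test, predictions = 2 * test$kmax)
  expect_equal(ev2$r2_loglog, 1)
  expect_equal(ev2$bias, mean(test$kmax))
  expect_error(evaluateHoldout(m, test[0, ]), "empty")
})

test_that("bootstrap intervals are ordered, reproducible and honest", {
  f <- monotoneFeatures(250, seed = 6)
  ref <- tuneAndFit(f, grid_size = 3, nrounds = 30, seed = 7)
  targets <- f[1:12, ]
  p1 <- bootstrapPredictIntervals(f, targets, n_boot = 12, reference = ref,
                                  nrounds = 30, seed = 8)
  p2 <- bootstrapPredictIntervals(f, targets, n_boot = 12, reference = ref,
                                  nrounds = 30, seed = 8)
  d1 <- as.data.frame(p1)
  expect_identical(d1, as.data.frame(p2))
  expect_true(validObject(p1))
  expect_true(all(d1$q05 <= d1$median & d1$median <= d1$q95))
  expect_true(all(d1$q05 > 0))
  expect_error(bootstrapPredictIntervals(f, targets, n_boot = 1,
                                         reference = ref), ">= 2")
  ## a degenerate (constant) target collapses the interval
  f0 <- f; f0$kmax <- 0.5
  ref0 <- suppressWarnings(tuneAndFit(f0, grid_size = 2, nrounds = 10,
                                      seed = 7))
  p0 <- bootstrapPredictIntervals(f0, f0[1:6, ], n_boot = 8,
                                  reference = ref0, nrounds = 10, seed = 8)
  d0 <- as.data.frame(p0)
  expect_equal(d0$q05, d0$q95, tolerance = 1e-6)
})

test_that("bootstrap intervals cover the latent growth coefficient", {
  n <- 2000
  f <- monotoneFeatures(n, seed = 10, noise_sd = 0.15)
  latent <- exp(log(0.5) - 0.6 * log(f$lmax_cm / 30) +
                0.3 * (f$sst - 20) / 10)
  ref <- tuneAndFit(f, grid_size = 4, nrounds = 60, seed = 11)
  take <- seq(1, n, by = 40)      # 50 targets
  p <- bootstrapPredictIntervals(f, f[take, ], n_boot = 200,
                                 reference = ref, nrounds = 40, seed = 12)
  d <- as.data.frame(p)
  covered <- mean(d$q05 <= latent[take] & latent[take] <= d$q95)
  expect_gte(covered, 0.8)
})

test_that("variable importance aggregates one-hot columns to predictors", {
  g1 <- c(lmax_cm = 0.6, sst = 0.2, "aging_method.otolith_rings" = 0.1,
          "aging_method.unknown" = 0.05, "water_position.pelagic" = 0.05)
  g2 <- c(lmax_cm = 0.7, max_depth_m = 0.3)
  vi <- variableImportance(list(g1, g2))
  expect_equal(sort(vi$predictor), sort(c("lmax_cm", "sst", "max_depth_m",
                                          "trophic_level", "aging_method",
                                          "water_position")))
  expect_equal(vi$predictor[1], "lmax_cm")
  single <- variableImportance(list(c(lmax_cm = 0.42)))
  expect_equal(single$importance_pct[1], 100)
  expect_error(variableImportance(list()), "at least one")
})
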