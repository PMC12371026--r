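## Shared fixtures, all built in code.

smallConfig <- function(seed = 7, ...) {
  synthConfig(n_species = 25, n_sites = 8, n_surveys_per_site = 2,
              seed = seed, ...)
}

gammaTruth <- function(phi = 5) {
  list(beta = c(b0 = 0.5, b_D = 1.10, b_trop = 0.3, b_D_trop = 0.06,
                b_sst = 0.1, b_vis = 0.05, b_depth = -0.05),
       sigma_site = 0.3, sigma_realm = 0.4, phi = phi)
}

nbTruth <- function(omega = 2) {
  list(beta = c(b0 = log(250), b_D = 1.5, b_trop = 0.2, b_D_trop = 0.1,
                b_sst = 0.1, b_vis = 0.05, b_depth = -0.05),
       sigma_site = 0.3, sigma_realm = 0.4, omega = omega)
}

## A tiny two-block survey set built by hand: `lengths_by_species` is a
## named list of size-class vectors (cm), one entry per species.
toySurveySet <- function(lengths_by_species,
                         lmax = NULL, lw_a = 0.01, lw_b = 3) {
  sp_ids <- names(lengths_by_species)
  if (is.null(lmax)) lmax <- vapply(lengths_by_species, max, 1) * 2
  species <- data.frame(
    species_id = sp_ids, genus = "g1", family = "f1",
    lmax_cm = unname(lmax), trophic_level = 3, max_depth_m = 30,
    water_position = "demersal", lw_a = lw_a, lw_b = lw_b,
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(sp_ids, function(s) {
    L <- lengths_by_species[[s]]
    data.frame(survey_id = "sv1",
               block = rep_len(c(1, 2), length(L)),
               species_id = s, size_class_cm = L, count = 1,
               stringsAsFactors = FALSE)
  }))
  for (blk in 1:2)                       # both blocks must exist
    if (!blk %in% rows$block)
      rows <- rbind(rows, within(rows[1, ], { block <- blk; count <- 0 }))
  surveys <- data.frame(
    survey_id = "sv1", site_id = "siteA", realm = "coral_triangle",
    tropical = TRUE, sst = 27, visibility = 12, depth = 8,
    lat = -14.7, lon = 145.4, stringsAsFactors = FALSE)
  new("SurveySet", counts = rows, surveys = surveys, species = species,
      groundTruth = list())
}

toyPredictions <- function(species_ids, q05, q95, n_boot = 100) {
  new("KmaxPredictions", predictions = data.frame(
    species_id = species_ids, sst = NA_real_,
    q05 = q05, median = (q05 + q95) / 2, q95 = q95, n_boot = n_boot,
    stringsAsFactors = FALSE))
}

## Synthetic growth-record features with a strong monotone trait signal,
## for boosting tests: log kmax declines with log Lmax, rises with SST.
monotoneFeatures <- function(n, seed = 1, noise_sd = 0.15) {
  set.seed(seed)
  lmax <- exp(runif(n, log(5), log(200)))
  sst <- runif(n, 5, 29)
  kmax <- exp(log(0.5) - 0.6 * log(lmax / 30) + 0.3 * (sst - 20) / 10 +
              rnorm(n, 0, noise_sd))
  data.frame(
    kmax = kmax, lmax_cm = lmax,
    trophic_level = runif(n, 2, 4.6),
    max_depth_m = exp(runif(n, log(5), log(400))),
    water_position = factor(sample(c("benthic", "demersal", "pelagic"), n,
                                   replace = TRUE),
                            levels = c("benthic", "demersal", "pelagic")),
    sst = sst,
    aging_method = factor(sample(agingMethods(), n, replace = TRUE),
                          levels = agingMethods()),
    species_id = sprintf("sp%04d", seq_len(n)),
    fallback_level = "species", stringsAsFactors = FALSE)
}

## Minimal BefFit carrying externally supplied draws, for summary tests.
fakeBefFit <- function(draws, chain = NULL) {
  if (is.null(chain))
    chain <- rep(1:2, each = nrow(draws) / 2)
  nm <- colnames(draws)
  rh <- setNames(rep(1.0, ncol(draws)), nm)
  new("BefFit", draws = draws, chain = as.integer(chain),
      logLik = matrix(0, nrow(draws), 1),
      spec = list(response = "productivity", family = "gamma", ell = 10),
      design = list(y = 1), scaling = list(),
      diagnostics = list(rhat = rh, ess_bulk = rh * NA, ess_tail = rh * NA,
                         divergences = 0L, accept = 0.9, step = 0.1))
}
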