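## Synthetic-data generators with known ground truth. These emulate the
## three inputs of the analysis — a mined growth-curve database, a species
## trait table, and a global transect survey program (two 250 m^2 blocks
## per survey, sites nested in biogeographic realms) — so every downstream
## stage can be validated against simulation truth.

## Reef-census style size-class bins (cm): fine at small sizes, then
## 12.5 cm steps beyond 50 cm.
rlsSizeBins <- function(max_cm = 300) {
  c(2.5, 5, 7.5, 10, 12.5, 15, 20, 25, 30, 35, 40, 50,
    seq(62.5, max_cm, by = 12.5))
}

## Negative-binomial with mean mu and inverse shape omega:
## Var = mu + mu^2/omega. omega -> Inf recovers Poisson.
rNegBin <- function(n, mu, omega) {
  if (any(omega <= 0)) stop("omega must be positive")
  if (is.infinite(omega)) stats::rpois(n, mu)
  else stats::rnbinom(n, size = omega, mu = mu)
}

#' Configuration for the synthetic generators
#'
#' Assembles and validates all knobs of the synthetic world: community and
#' sampling dimensions, trait distributions, the latent trait-to-growth
#' link, and the generative abundance and productivity models whose
#' coefficients form the recoverable ground truth.
#'
#' @param n_species number of species in the pool
#' @param n_sites number of sites (distributed round-robin over realms)
#' @param n_surveys_per_site surveys per site
#' @param realms data.frame with columns \code{realm} and \code{tropical}
#'   (logical); default two tropical and two temperate realms
#' @param trait_distributions list: \code{lmax_meanlog}, \code{lmax_sdlog}
#'   (log-normal maximum total length, cm), \code{trophic_min},
#'   \code{trophic_max} (uniform trophic level), \code{depth_meanlog},
#'   \code{depth_sdlog} (log-normal maximum depth, m),
#'   \code{water_position_probs} (named probabilities, must sum to 1)
#' @param k_link coefficients of the latent growth link
#'   log Kmax = \code{intercept} - \code{lmax_slope} * log(Lmax/30cm)
#'   + \code{sst_slope} * (SST - 20)/10; the link must be decreasing in
#'   Lmax and increasing in SST
#' @param growth_noise_sd log-scale standard deviation of a published K
#'   around its latent mean
#' @param abundance_model list: \code{beta} (named vector b0, b_D, b_trop,
#'   b_D_trop, b_sst, b_vis, b_depth), \code{omega} (> 0, inverse shape),
#'   \code{sigma_site}, \code{sigma_realm}
#' @param productivity_model list: \code{beta} (same names), \code{phi}
#'   (> 0, gamma shape), \code{sigma_site}, \code{sigma_realm}
#' @param survey_pool_range integer range of the per-site species pool size
#'   (the diversity gradient); degenerate c(1, 1) forces monocultures
#' @param seed integer seed; all generators derive independent sub-streams
#' @return a validated list of class \code{synth_config}
#' @export
synthConfig <- function(n_species = 120,
                        n_sites = 40,
                        n_surveys_per_site = 2,
                        realms = data.frame(
                          realm = c("coral_triangle", "caribbean",
                                    "temperate_australasia", "temperate_atlantic"),
                          tropical = c(TRUE, TRUE, FALSE, FALSE)),
                        trait_distributions = list(
                          lmax_meanlog = log(30), lmax_sdlog = 0.7,
                          trophic_min = 2.0, trophic_max = 4.6,
                          depth_meanlog = log(30), depth_sdlog = 0.8,
                          water_position_probs = c(benthic = 0.4,
                                                   demersal = 0.4,
                                                   pelagic = 0.2)),
                        k_link = c(intercept = log(0.5), lmax_slope = 0.6,
                                   sst_slope = 0.3),
                        growth_noise_sd = 0.2,
                        abundance_model = list(
                          beta = c(b0 = log(250), b_D = 1.5, b_trop = 0.2,
                                   b_D_trop = 0.1, b_sst = 0.1, b_vis = 0.05,
                                   b_depth = -0.05),
                          omega = 2, sigma_site = 0.3, sigma_realm = 0.4),
                        productivity_model = list(
                          beta = c(b0 = log(150), b_D = 1.10, b_trop = 0.2,
                                   b_D_trop = 0.06, b_sst = 0.1, b_vis = 0.05,
                                   b_depth = -0.05),
                          phi = 5, sigma_site = 0.3, sigma_realm = 0.4),
                        survey_pool_range = NULL,
                        seed = 1L) {
  cfg <- list(n_species = n_species, n_sites = n_sites,
              n_surveys_per_site = n_surveys_per_site, realms = realms,
              trait_distributions = trait_distributions, k_link = k_link,
              growth_noise_sd = growth_noise_sd,
              abundance_model = abundance_model,
              productivity_model = productivity_model,
              survey_pool_range = survey_pool_range, seed = as.integer(seed))
  if (any(c(n_species, n_sites, n_surveys_per_site) < 1))
    stop("counts must be >= 1")
  assertColumns(realms, c("realm", "tropical"), "realm table")
  wp <- trait_distributions$water_position_probs
  if (abs(sum(wp) - 1) > 1e-8)
    stop("water-position probabilities must sum to 1")
  if (trait_distributions$lmax_sdlog < 0 || trait_distributions$depth_sdlog < 0 ||
      trait_distributions$trophic_min > trait_distributions$trophic_max)
    stop("invalid trait distribution parameters")
  if (abundance_model$omega <= 0) stop("omega must be positive")
  if (productivity_model$phi <= 0) stop("phi must be positive")
  if (growth_noise_sd < 0) stop("growth_noise_sd must be non-negative")
  if (k_link[["lmax_slope"]] < 0 || k_link[["sst_slope"]] < 0)
    stop("k_link must decrease with Lmax and increase with SST")
  class(cfg) <- "synth_config"
  cfg
}

## latent expected Kmax (yr^-1) from maximum length and SST
.latentKmax <- function(lmax, sst, k_link) {
  exp(k_link[["intercept"]] - k_link[["lmax_slope"]] * log(lmax / 30) +
      k_link[["sst_slope"]] * (sst - 20) / 10)
}

#' Generate a synthetic species pool with traits
#'
#' Draws \code{n_species} species with maximum total length (log-normal),
#' trophic level (uniform), maximum depth (log-normal), water-column
#' position (categorical), and length-weight coefficients (a in
#' [0.005, 0.05], b in [2.8, 3.2]). Species are organized into genera and
#' families (about three species per genus, three genera per family) so the
#' taxonomic fallback of trait imputation can be exercised. The column
#' \code{latent_kmax} records the expected Kmax at the 20 degC reference
#' SST; it decreases with maximum length by construction.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return data.frame of species traits; attribute \code{"ground_truth"}
#'   holds the latent growth-link coefficients
#' @export
genSpeciesPool <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(deriveSeed(cfg$seed, "species_pool"))
  n <- cfg$n_species
  td <- cfg$trait_distributions
  genus <- paste0("g", sprintf("%03d", ceiling(seq_len(n) / 3)))
  family <- paste0("f", sprintf("%03d", ceiling(seq_len(n) / 9)))
  lmax <- stats::rlnorm(n, td$lmax_meanlog, td$lmax_sdlog)
  lmax <- pmin(pmax(lmax, 3), 300)
  sp <- data.frame(
    species_id = paste0("sp", sprintf("%04d", seq_len(n))),
    genus = genus, family = family,
    lmax_cm = lmax,
    trophic_level = stats::runif(n, td$trophic_min, td$trophic_max),
    max_depth_m = stats::rlnorm(n, td$depth_meanlog, td$depth_sdlog),
    water_position = sample(names(td$water_position_probs), n, replace = TRUE,
                            prob = td$water_position_probs),
    lw_a = stats::runif(n, 0.005, 0.05),
    lw_b = stats::runif(n, 2.8, 3.2),
    stringsAsFactors = FALSE)
  sp$latent_kmax <- .latentKmax(sp$lmax_cm, 20, cfg$k_link)
  attr(sp, "ground_truth") <- list(k_link = cfg$k_link, ref_sst = 20)
  sp
}

## aging-method vocabulary used across the package
agingMethods <- function() c("mark_recapture", "otolith_rings", "scale_rings",
                             "other_rings", "length_frequency", "unknown")

#' Generate synthetic published growth records
#'
#' For each species, draws \code{n_per_species} published von Bertalanffy
#' fits: a study location with its SST, a growth coefficient K equal to the
#' species' latent trait-driven mean at that SST times log-normal noise
#' (meanlog 0), an asymptotic length L_inf uniform on [0.7, 1.1] x Lmax,
#' an aging method, and a length-measurement type. Reported L_inf is
#' expressed in the record's own length type using the per-species
#' length-length conversion factors that are returned alongside.
#'
#' @param species trait table from \code{\link{genSpeciesPool}}
#' @param n_per_species number of growth curves per species (>= 1)
#' @param cfg the \code{\link{synthConfig}}
#' @return list with \code{records} (one row per curve: species_id,
#'   l_inf_reported, length_type, k, aging_method, lat, lon, sst, marine,
#'   source, latent_k) and \code{conversions} (species_id, from_type,
#'   slope, intercept mapping SL/FL to TL)
#' @export
genGrowthRecords <- function(species, n_per_species, cfg) {
  if (!nrow(species)) stop("species table is empty")
  if (n_per_species < 1) stop("n_per_species must be >= 1")
  set.seed(deriveSeed(cfg$seed, "growth_records"))
  ns <- nrow(species)
  conv <- data.frame(
    species_id = rep(species$species_id, each = 2),
    from_type = rep(c("SL", "FL"), ns),
    slope = as.numeric(rbind(stats::runif(ns, 1.10, 1.25),
                             stats::runif(ns, 1.02, 1.10))),
    intercept = 0,
    stringsAsFactors = FALSE)
  n <- ns * n_per_species
  idx <- rep(seq_len(ns), each = n_per_species)
  lat <- stats::runif(n, -55, 55)
  sst <- pmax(2, 29 - 0.35 * abs(lat) + stats::rnorm(n, 0, 1.5))
  latent <- .latentKmax(species$lmax_cm[idx], sst, cfg$k_link)
  k <- latent * exp(stats::rnorm(n, 0, cfg$growth_noise_sd))
  l_inf_tl <- species$lmax_cm[idx] * stats::runif(n, 0.7, 1.1)
  length_type <- sample(c("TL", "SL", "FL"), n, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
  ckey <- paste(conv$species_id, conv$from_type)
  pos <- match(paste(species$species_id[idx], length_type), ckey)
  slope <- ifelse(length_type == "TL", 1, conv$slope[pos])
  rec <- data.frame(
    species_id = species$species_id[idx],
    l_inf_reported = l_inf_tl / slope,
    length_type = length_type,
    k = k,
    aging_method = sample(agingMethods(), n, replace = TRUE,
                          prob = c(0.05, 0.5, 0.1, 0.1, 0.2, 0.05)),
    lat = lat,
    lon = stats::runif(n, -180, 180),
    sst = sst,
    marine = TRUE,
    source = sample(c("fishbase", "literature"), n, replace = TRUE,
                    prob = c(0.75, 0.25)),
    latent_k = latent,
    stringsAsFactors = FALSE)
  list(records = rec, conversions = conv)
}

#' Generate a synthetic survey dataset with ground truth
#'
#' Builds \code{n_sites} sites nested in the configured realms (tropical
#' sites at low latitude and warm SST, temperate sites at high latitude and
#' cool SST), gives each site a species pool of varying size and a
#' geometric-series abundance skew — jointly inducing a gradient of
#' richness, evenness, and abundance — and then censuses
#' \code{n_surveys_per_site} two-block surveys per site. Per-species counts
#' come from a negative-binomial model whose expected total follows the
#' configured abundance coefficients driven by the site's latent log
#' diversity; individuals are spread over census size-class bins no larger
#' than the species' maximum length, and split binomially between the two
#' 250 m^2 blocks.
#'
#' @param species trait table from \code{\link{genSpeciesPool}}
#' @param cfg the \code{\link{synthConfig}}
#' @return a \code{\link{SurveySet}} whose \code{groundTruth} records the
#'   abundance/productivity coefficients, dispersion parameters, latent
#'   site effects, and the diversity-gradient driver
#' @export
genSurveyDataset <- function(species, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  realms <- cfg$realms
  if (nrow(realms) < 2)
    stop("survey generation needs >= 2 realms (the diversity x region ",
         "interaction is unidentifiable otherwise)")
  set.seed(deriveSeed(cfg$seed, "surveys"))
  n_sites <- cfg$n_sites
  ridx <- rep_len(seq_len(nrow(realms)), n_sites)
  tropical <- realms$tropical[ridx]
  sites <- data.frame(
    site_id = paste0("site", sprintf("%03d", seq_len(n_sites))),
    realm = realms$realm[ridx],
    tropical = tropical,
    lat = ifelse(tropical, stats::runif(n_sites, -23, 23),
                 sample(c(-1, 1), n_sites, TRUE) * stats::runif(n_sites, 30, 55)),
    lon = stats::runif(n_sites, -180, 180),
    sst = ifelse(tropical, stats::runif(n_sites, 24, 29),
                 stats::runif(n_sites, 8, 18)),
    stringsAsFactors = FALSE)
  am <- cfg$abundance_model
  alpha_realm <- stats::rnorm(nrow(realms), 0, am$sigma_realm)
  eps_site <- stats::rnorm(n_sites, 0, am$sigma_site)

  ## diversity gradient: per-site pool size and geometric abundance skew
  pool_rng <- cfg$survey_pool_range
  if (is.null(pool_rng)) pool_rng <- c(5, min(cfg$n_species, 40))
  pool_size <- if (pool_rng[1] == pool_rng[2]) rep(pool_rng[1], n_sites)
               else sample(pool_rng[1]:pool_rng[2], n_sites, replace = TRUE)
  skew <- stats::runif(n_sites, 0.6, 0.98)
  pools <- lapply(seq_len(n_sites), function(s) {
    sp <- sample(seq_len(nrow(species)), pool_size[s])
    p <- skew[s]^(seq_along(sp) - 1)
    list(idx = sp, p = p / sum(p))
  })
  ## latent log diversity driving expected abundance (rarity-weighted Hill
  ## diversity of the pool composition), z-scored across sites
  latD <- vapply(pools, function(pl) log(hillDiversity(pl$p * 1e6, 10)),
                 numeric(1))
  latD_z <- if (stats::sd(latD) > 0) (latD - mean(latD)) / stats::sd(latD)
            else latD * 0

  bins <- rlsSizeBins()
  b <- am$beta
  survey_rows <- list(); count_rows <- list(); srow <- 0
  for (s in seq_len(n_sites)) {
    for (j in seq_len(cfg$n_surveys_per_site)) {
      srow <- srow + 1
      sid <- sprintf("%s_t%02d", sites$site_id[s], j)
      sst_i <- sites$sst[s] + stats::rnorm(1, 0, 0.3)
      vis_i <- stats::runif(1, 5, 25)
      dep_i <- stats::runif(1, 2, 18)
      eta <- b[["b0"]] + b[["b_D"]] * latD_z[s] +
        b[["b_trop"]] * tropical[s] + b[["b_D_trop"]] * latD_z[s] * tropical[s] +
        b[["b_sst"]] * (sst_i - 18) / 8 + b[["b_vis"]] * (vis_i - 15) / 6 +
        b[["b_depth"]] * (dep_i - 10) / 5 +
        alpha_realm[ridx[s]] + eps_site[s]
      pl <- pools[[s]]
      mu_sp <- exp(eta) * pl$p
      cnt <- rNegBin(length(mu_sp), mu_sp, am$omega)
      keep <- which(cnt > 0)
      if (!length(keep)) { keep <- which.max(mu_sp); cnt[keep] <- 1 }
      for (ksp in keep) {
        spi <- pl$idx[ksp]
        lmax <- species$lmax_cm[spi]
        ok_bins <- bins[bins <= lmax]
        if (!length(ok_bins)) ok_bins <- bins[1]
        w <- stats::dbeta(pmin(ok_bins / lmax, 0.999), 2, 4)
        if (!sum(w)) w <- rep(1, length(ok_bins))
        per_bin <- stats::rmultinom(1, cnt[ksp], w)[, 1]
        nz <- which(per_bin > 0)
        if (!length(nz)) next
        blk1 <- stats::rbinom(length(nz), per_bin[nz], 0.5)
        for (bb in seq_along(nz)) {
          for (blk in 1:2) {
            cc <- if (blk == 1) blk1[bb] else per_bin[nz[bb]] - blk1[bb]
            count_rows[[length(count_rows) + 1]] <- data.frame(
              survey_id = sid, block = blk,
              species_id = species$species_id[spi],
              size_class_cm = ok_bins[nz[bb]], count = cc,
              stringsAsFactors = FALSE)
          }
        }
      }
      survey_rows[[srow]] <- data.frame(
        survey_id = sid, site_id = sites$site_id[s], realm = sites$realm[s],
        tropical = tropical[s], sst = sst_i, visibility = vis_i,
        depth = dep_i, lat = sites$lat[s] + stats::rnorm(1, 0, 0.05),
        lon = sites$lon[s] + stats::rnorm(1, 0, 0.05),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, count_rows)
  ## ensure both blocks appear for every survey (zero rows are legal)
  surveys <- do.call(rbind, survey_rows)
  have2 <- tapply(counts$block, counts$survey_id, function(x) length(unique(x)))
  fix <- names(have2)[have2 < 2]
  if (length(fix)) {
    first <- counts[match(fix, counts$survey_id), ]
    first$block <- 3 - first$block
    first$count <- 0
    counts <- rbind(counts, first)
  }
  truth <- list(
    abundance = cfg$abundance_model, productivity = cfg$productivity_model,
    k_link = cfg$k_link, alpha_realm = alpha_realm, eps_site = eps_site,
    latent_logD = latD, latent_logD_z = latD_z, pool_size = pool_size,
    skew = skew, seed = cfg$seed)
  new("SurveySet", counts = counts, surveys = surveys,
      species = species, groundTruth = truth)
}

#' Simulate a model-ready dataset exactly from the BEF generative model
#'
#' Draws responses exactly from the hierarchical gamma (productivity) or
#' negative-binomial (abundance) model: z-scored continuous covariates, a
#' tropical indicator and its interaction with log diversity, and nested
#' site-within-realm random effects on the log mean. Covariates are z-scored
#' within the generated sample so the supplied coefficients are exact on the
#' analysis scale. Used for parameter-recovery tests.
#'
#' @param truth list with \code{beta} (named b0, b_D, b_trop, b_D_trop,
#'   b_sst, b_vis, b_depth), \code{sigma_site}, \code{sigma_realm}, and
#'   either \code{phi} (gamma) or \code{omega} (negative binomial)
#' @param n number of surveys
#' @param n_sites,n_realms nesting structure (sites split evenly over
#'   realms, surveys evenly over sites); realms alternate tropical/temperate
#' @param family \code{"gamma"} or \code{"negbin"}
#' @param seed integer seed
#' @return data.frame with columns \code{y}, \code{logD}, \code{tropical},
#'   \code{sst}, \code{visibility}, \code{depth}, \code{site_id},
#'   \code{realm}, \code{lat}, \code{lon}; attribute \code{"truth"} echoes
#'   the generator parameters plus the realized random effects
#' @export
genGlmmExactDataset <- function(truth, n = 400, n_sites = 40, n_realms = 4,
                                family = c("gamma", "negbin"), seed = 1L) {
  family <- match.arg(family)
  if (family == "gamma" && (is.null(truth$phi) || truth$phi <= 0))
    stop("gamma simulation needs phi > 0")
  if (family == "negbin" && (is.null(truth$omega) || truth$omega <= 0))
    stop("negative-binomial simulation needs omega > 0")
  set.seed(deriveSeed(seed, paste0("glmm_", family)))
  site <- rep_len(seq_len(n_sites), n)
  realm_of_site <- rep_len(seq_len(n_realms), n_sites)
  tropical_realm <- rep_len(c(TRUE, FALSE), n_realms)
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  logD <- zscore(stats::rnorm(n))
  sst <- zscore(stats::rnorm(n))
  vis <- zscore(stats::rnorm(n))
  dep <- zscore(stats::rnorm(n))
  trop <- as.numeric(tropical_realm[realm_of_site[site]])
  b <- truth$beta
  alpha_realm <- stats::rnorm(n_realms, 0, truth$sigma_realm)
  eps_site <- stats::rnorm(n_sites, 0, truth$sigma_site)
  eta <- b[["b0"]] + b[["b_D"]] * logD + b[["b_trop"]] * trop +
    b[["b_D_trop"]] * logD * trop + b[["b_sst"]] * sst +
    b[["b_vis"]] * vis + b[["b_depth"]] * dep +
    alpha_realm[realm_of_site[site]] + eps_site[site]
  mu <- exp(eta)
  y <- if (family == "gamma") stats::rgamma(n, shape = truth$phi,
                                            rate = truth$phi / mu)
       else rNegBin(n, mu, truth$omega)
  site_lat <- stats::runif(n_sites, -50, 50)
  site_lon <- stats::runif(n_sites, -180, 180)
  out <- data.frame(
    y = y, logD = logD, tropical = trop == 1, sst = sst, visibility = vis,
    depth = dep, site_id = paste0("site", sprintf("%03d", site)),
    realm = paste0("realm", realm_of_site[site]),
    lat = site_lat[site], lon = site_lon[site])
  attr(out, "truth") <- c(truth, list(alpha_realm = alpha_realm,
                                      eps_site = eps_site, family = family,
                                      mu = mu))
  out
}

## Named atomic vectors must become JSON objects, not arrays, so that
## coefficient names survive the round trip.
.namedForJson <- function(x) {
  if (is.list(x)) lapply(x, .namedForJson)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

#' Write a SurveySet and its ground truth to disk
#'
#' CSV tables (long-format counts, survey covariates, species traits) plus
#' a JSON ground-truth sidecar.
#'
#' @param x a \code{\link{SurveySet}}
#' @param dir output directory (created if absent)
#' @return invisibly, the written file paths
#' @export
writeSurveySet <- function(x, dir) {
  stopifnot(is(x, "SurveySet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("survey_counts.csv", "surveys.csv",
                            "species_traits.csv", "ground_truth.json"))
  utils::write.csv(surveyCounts(x), paths[1], row.names = FALSE)
  utils::write.csv(surveyData(x), paths[2], row.names = FALSE)
  utils::write.csv(speciesTraits(x), paths[3], row.names = FALSE)
  jsonlite::write_json(.namedForJson(groundTruth(x)), paths[4],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a SurveySet written by \code{\link{writeSurveySet}}
#' @param dir directory holding the CSV tables and JSON sidecar
#' @return a \code{\link{SurveySet}}
#' @export
readSurveySet <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
        else list()
  new("SurveySet",
      counts = utils::read.csv(file.path(dir, "survey_counts.csv")),
      surveys = utils::read.csv(file.path(dir, "surveys.csv")),
      species = utils::read.csv(file.path(dir, "species_traits.csv")),
      groundTruth = as.list(gt))
}
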