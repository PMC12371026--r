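#' @import methods
NULL

#' SurveySet: a set of underwater visual-census surveys
#'
#' Container for reef-fish community surveys in the standardized
#' two-block transect format (two 250 m^2 blocks, 500 m^2 total; surveys
#' with only one censused block may be present but are excluded from
#' productivity estimation): a
#' long-format count table (per survey, block, species and size class),
#' a survey-level covariate table, a species trait table, and — when the
#' object came from the synthetic generators — the ground-truth parameter
#' list used to simulate it.
#'
#' @slot counts data.frame with columns \code{survey_id}, \code{block},
#'   \code{species_id}, \code{size_class_cm}, \code{count}.
#' @slot surveys data.frame with one row per survey: \code{survey_id},
#'   \code{site_id}, \code{realm}, \code{tropical} (logical), \code{sst}
#'   (deg C), \code{visibility} (m), \code{depth} (m), \code{lat},
#'   \code{lon}.
#' @slot species data.frame with one row per species: \code{species_id},
#'   \code{genus}, \code{family}, \code{lmax_cm}, \code{trophic_level},
#'   \code{max_depth_m}, \code{water_position}, \code{lw_a}, \code{lw_b}.
#' @slot groundTruth list of simulation truth (possibly empty).
#'
#' @exportClass SurveySet
setClass("SurveySet",
  representation(counts = "data.frame", surveys = "data.frame",
                 species = "data.frame", groundTruth = "list"),
  prototype(counts = data.frame(), surveys = data.frame(),
            species = data.frame(), groundTruth = list()))

setValidity("SurveySet", function(object) {
  msg <- character()
  cnt <- object@counts
  sv <- object@surveys
  sp <- object@species
  need_cnt <- c("survey_id", "block", "species_id", "size_class_cm", "count")
  need_sv <- c("survey_id", "site_id", "realm", "tropical", "sst",
               "visibility", "depth", "lat", "lon")
  if (!all(need_cnt %in% names(cnt)))
    msg <- c(msg, "counts table lacks required columns")
  if (!all(need_sv %in% names(sv)))
    msg <- c(msg, "surveys table lacks required columns")
  if (all(need_cnt %in% names(cnt)) && nrow(cnt)) {
    if (any(cnt$count < 0) || any(cnt$count != round(cnt$count)))
      msg <- c(msg, "counts must be non-negative integers")
    if (any(cnt$size_class_cm <= 0))
      msg <- c(msg, "size classes must be positive")
    if (!all(cnt$block %in% 1:2))
      msg <- c(msg, "blocks must be labelled 1 or 2")
    if (!all(unique(cnt$survey_id) %in% sv$survey_id))
      msg <- c(msg, "counts reference surveys absent from the survey table")
    if (nrow(sp) && !all(unique(cnt$species_id) %in% sp$species_id))
      msg <- c(msg, "counts reference species absent from the trait table")
  }
  if (all(need_sv %in% names(sv)) && nrow(sv)) {
    if (anyNA(sv$realm)) msg <- c(msg, "realm labels must not be missing")
    if (!is.logical(sv$tropical)) msg <- c(msg, "tropical must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' KmaxPredictions: bootstrap prediction intervals for Kmax
#'
#' One row per prediction target (species, optionally in an SST context):
#' the median and the 90\% predicted quantile range (5\% / 95\% bootstrap
#' quantiles) of the standardized growth coefficient Kmax (yr^-1).
#'
#' @slot predictions data.frame with columns \code{species_id}, \code{sst},
#'   \code{q05}, \code{median}, \code{q95}, \code{n_boot}.
#'
#' @exportClass KmaxPredictions
setClass("KmaxPredictions",
  representation(predictions = "data.frame"),
  prototype(predictions = data.frame()))

setValidity("KmaxPredictions", function(object) {
  p <- object@predictions
  msg <- character()
  need <- c("species_id", "q05", "median", "q95", "n_boot")
  if (!all(need %in% names(p)))
    return("predictions table lacks required columns")
  if (nrow(p)) {
    if (any(p$q05 <= 0)) msg <- c(msg, "Kmax quantiles must be positive")
    if (any(p$q05 > p$median + 1e-12 | p$median > p$q95 + 1e-12))
      msg <- c(msg, "quantiles must satisfy q05 <= median <= q95")
    if (any(p$n_boot < 1)) msg <- c(msg, "n_boot must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' BefFit: posterior fit of one hierarchical BEF model
#'
#' Holds the MCMC draws of a gamma or negative-binomial mixed model of
#' productivity, per-capita productivity, or abundance against log Hill
#' diversity, with the pointwise log-likelihood needed for PSIS-LOO, the
#' design data, covariate scaling constants, and sampler diagnostics.
#'
#' @slot draws numeric matrix, (chains x sampling iterations) rows by named
#'   parameters (fixed effects on the scaled scale, random-effect values,
#'   variance components, shape).
#' @slot chain integer vector assigning each draw row to its chain.
#' @slot logLik numeric matrix, draws by observations, pointwise
#'   log-likelihood.
#' @slot spec list: response, family, diversity scaling parameter ell,
#'   sampler settings, priors, seed.
#' @slot design list: response vector, model matrix, site/realm indices,
#'   coordinates, offset.
#' @slot scaling list of means/sds used to z-score continuous covariates.
#' @slot diagnostics list: per-parameter split-Rhat and bulk/tail ESS,
#'   divergence count, acceptance rates, step sizes.
#'
#' @exportClass BefFit
setClass("BefFit",
  representation(draws = "matrix", chain = "integer", logLik = "matrix",
                 spec = "list", design = "list", scaling = "list",
                 diagnostics = "list"))

setValidity("BefFit", function(object) {
  msg <- character()
  if (nrow(object@draws) != length(object@chain))
    msg <- c(msg, "chain index length must equal the number of draws")
  if (nrow(object@logLik) && nrow(object@logLik) != nrow(object@draws))
    msg <- c(msg, "logLik rows must equal the number of draws")
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws must have parameter names")
  if (length(msg)) msg else TRUE
})
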