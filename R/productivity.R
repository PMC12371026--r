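## Process-based daily biomass production: one day of simulated somatic
## growth for every censused individual, with Kmax uncertainty propagated
## by truncated-normal draws from the predicted 90% quantile range.

#' Draw Kmax values from a predicted 90\% quantile range
#'
#' Draws from a normal distribution centered on the interval midpoint with
#' sd = (q95 - q05) / 3.2897 — so that the untruncated 90\% interval equals
#' the predicted quantile range — truncated to [q05, q95]. A degenerate
#' interval returns the point value.
#'
#' @param q05,q95 lower/upper 5\%/95\% predicted quantiles (yr^-1)
#' @param n number of draws
#' @return n positive draws in [q05, q95]
#' @export
drawKmaxSample <- function(q05, q95, n = 1) {
  if (q95 < q05) stop("q95 must be >= q05")
  if (q95 == q05) return(rep(q05, n))
  m <- (q05 + q95) / 2
  s <- (q95 - q05) / 3.2897
  rtruncnorm(n, m, s, q05, q95)
}

#' Daily biomass production of one individual
#'
#' Places the individual on its growth trajectory by inverting the VBGF at
#' its current length with asymptote Lmax and coefficient Kmax, advances
#' the trajectory by one day (1/365 yr), and converts the length increment
#' to a biomass increment through the length-weight allometry:
#' expected biomass tomorrow minus observed biomass today. Individuals at
#' or above the asymptote are placed at the capped trajectory position for
#' age inversion (see \code{\link{vbgfInverseAge}}); since their projected
#' length cannot exceed their observed length, they produce zero.
#'
#' @param length current total length (cm); vectorized
#' @param kmax standardized growth coefficient (yr^-1); vectorized
#' @param lmax species maximum total length = trajectory asymptote (cm)
#' @param a,b length-weight coefficients (W = a L^b, grams)
#' @return biomass produced in one day (g), non-negative
#' @examples
#' individualDailyProduction(50, 0.5, 100, 0.01, 3)  # ~5.14 g
#' @export
individualDailyProduction <- function(length, kmax, lmax, a, b) {
  t <- vbgfInverseAge(length, l_inf = lmax, k = kmax)
  L1 <- lmax * (1 - exp(-kmax * (as.numeric(t) + 1 / 365)))
  pmax(0, a * (L1^b - length^b))
}

## Expand a survey's count rows into one row per individual
.individualsOf <- function(counts, species) {
  idx <- rep(seq_len(nrow(counts)), counts$count)
  ind <- counts[idx, c("species_id", "size_class_cm", "block")]
  sp <- match(ind$species_id, species$species_id)
  if (anyNA(sp))
    stop("individuals belong to species missing from the trait table: ",
         paste(unique(ind$species_id[is.na(sp)]), collapse = ", "))
  ind$lmax <- species$lmax_cm[sp]
  ind$lw_a <- species$lw_a[sp]
  ind$lw_b <- species$lw_b[sp]
  ## census length = size-class midpoint: bins are upper edges, the midpoint
  ## sits halfway to the previous bin edge
  bins <- sort(unique(c(0, rlsSizeBins())))
  pos <- findInterval(ind$size_class_cm, bins)
  ind$length <- (bins[pos] + bins[pmax(pos - 1, 1)]) / 2
  ind$length[pos == 1] <- bins[1] / 2
  ind
}

#' Community biomass productivity of the surveys in a SurveySet
#'
#' For every survey: expands counts into individuals (length = size-class
#' midpoint), and over \code{n_boot} bootstrap simulations draws an
#' independent Kmax for each individual from its species' truncated-normal
#' predictive distribution, sums one day of individual growth over both
#' 250 m^2 blocks, and reports the median and 5\%/95\% quantiles of total
#' productivity (g 500 m^-2 day^-1), per-capita productivity
#' (total/abundance, per bootstrap), total abundance, and standing biomass.
#' Surveys with a single block are excluded with a logged reason; the
#' per-survey random stream is derived from (seed, survey_id) so results do
#' not depend on survey order.
#'
#' @param x a \code{\link{SurveySet}}
#' @param preds a \code{\link{KmaxPredictions}} covering every species
#'   present in the counts
#' @param n_boot number of bootstrap simulations (>= 1)
#' @param seed global seed
#' @return data.frame with one row per retained survey: \code{survey_id},
#'   \code{abundance}, \code{richness}, \code{biomass_g},
#'   \code{productivity_median}, \code{productivity_q05},
#'   \code{productivity_q95}, \code{percap_median}, \code{percap_q05},
#'   \code{percap_q95}; attribute \code{"excluded"} lists dropped surveys
#' @export
communityProductivity <- function(x, preds, n_boot = 1000, seed = 1L) {
  stopifnot(is(x, "SurveySet"), is(preds, "KmaxPredictions"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  counts <- surveyCounts(x)
  species <- speciesTraits(x)
  pr <- as.data.frame(preds)
  blocks <- tapply(counts$block, counts$survey_id, function(b) length(unique(b)))
  excluded <- names(blocks)[blocks < 2]
  ids <- setdiff(unique(counts$survey_id), excluded)
  if (length(excluded))
    message(length(excluded), " single-block survey(s) excluded: ",
            paste(excluded, collapse = ", "))
  miss <- setdiff(unique(counts$species_id[counts$survey_id %in% ids]),
                  pr$species_id)
  if (length(miss))
    stop("no Kmax prediction for species: ", paste(miss, collapse = ", "))
  out <- lapply(ids, function(sid) {
    sub <- counts[counts$survey_id == sid & counts$count > 0, , drop = FALSE]
    ind <- .individualsOf(sub, species)
    n_ind <- nrow(ind)
    ppos <- match(ind$species_id, pr$species_id)
    q05 <- pr$q05[ppos]; q95 <- pr$q95[ppos]
    m <- (q05 + q95) / 2
    s <- (q95 - q05) / 3.2897
    set.seed(deriveSeed(seed, paste0("prod_", sid)))
    ## one uniform per (bootstrap, individual), individuals fastest
    u <- matrix(stats::runif(n_boot * n_ind), nrow = n_boot, byrow = TRUE)
    plo <- stats::pnorm(q05, m, s); phi95 <- stats::pnorm(q95, m, s)
    deg <- s <= 0
    totals <- numeric(n_boot); percap <- numeric(n_boot)
    for (bt in seq_len(n_boot)) {
      kdraw <- stats::qnorm(plo + u[bt, ] * (phi95 - plo), m, s)
      kdraw <- pmin(pmax(kdraw, q05), q95)
      if (any(deg)) kdraw[deg] <- q05[deg]
      dm <- individualDailyProduction(ind$length, kdraw, ind$lmax,
                                      ind$lw_a, ind$lw_b)
      totals[bt] <- sum(dm)
      percap[bt] <- totals[bt] / n_ind
    }
    qs <- stats::quantile(totals, c(0.05, 0.5, 0.95), names = FALSE)
    qp <- stats::quantile(percap, c(0.05, 0.5, 0.95), names = FALSE)
    data.frame(
      survey_id = sid, abundance = n_ind,
      richness = length(unique(ind$species_id)),
      biomass_g = sum(lengthToMass(ind$length, ind$lw_a, ind$lw_b)),
      productivity_q05 = qs[1], productivity_median = qs[2],
      productivity_q95 = qs[3],
      percap_q05 = qp[1], percap_median = qp[2], percap_q95 = qp[3],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "excluded") <- excluded
  res
}
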