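## Hill diversity across the evenness-rarity continuum.

#' Hill diversity of one community
#'
#' Computes the Hill diversity
#' \deqn{D = \left(\sum_i p_i (1/p_i)^{\ell}\right)^{1/\ell}}
#' where \eqn{p_i} are species relative abundances. The scaling parameter
#' \eqn{\ell} moves emphasis along the evenness-rarity continuum:
#' \eqn{\ell = -1} is the inverse Simpson index, \eqn{\ell = 0} (taken as
#' the limit) is exponentiated Shannon entropy, \eqn{\ell = 1} is species
#' richness, and large \eqn{\ell} (here 10) emphasizes rarity and hence
#' total abundance. Hill order q relates as q = 1 - \eqn{\ell}.
#'
#' Evaluation is in log space (log-sum-exp of \eqn{(1-\ell)\log p_i}) so
#' that strongly rarity-weighted orders (\eqn{\ell = 10} raises rare-species
#' \eqn{p_i^{-9}}) do not overflow.
#'
#' @param counts non-negative species abundances (zeros are dropped);
#'   at least one must be positive
#' @param ell scaling parameter (vectorized)
#' @param eps half-width of the window around 0 inside which the Shannon
#'   limit is used
#' @return Hill diversity in effective species, one value per \code{ell}
#' @examples
#' hillDiversity(c(8, 1, 1), c(-1, 0, 1, 10))
#' @export
hillDiversity <- function(counts, ell, eps = 1e-8) {
  if (any(counts < 0)) stop("abundances must be non-negative")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("community has no individuals")
  p <- counts / sum(counts)
  lp <- log(p)
  vapply(ell, function(l) {
    if (abs(l) <= eps) {
      exp(-sum(p * lp))
    } else {
      exp(logSumExp((1 - l) * lp) / l)
    }
  }, numeric(1))
}

## Default ell values: inverse Simpson, Shannon limit, richness, abundance
.ell_default <- c(simpson = -1, shannon = 0, richness = 1, abundance = 10)

#' Pool a survey's counts across blocks into one abundance vector
#' @keywords internal
.pooledAbundance <- function(counts, survey_id) {
  sub <- counts[counts$survey_id == survey_id, , drop = FALSE]
  tapply(sub$count, sub$species_id, sum)
}

#' Log Hill diversity matrix for a set of surveys
#'
#' Computes Hill diversity at each \code{ell} for every survey (species
#' counts pooled across the two blocks) and returns the natural-log values
#' used as model inputs.
#'
#' @param x a \code{\link{SurveySet}} or a long-format count data.frame with
#'   columns \code{survey_id}, \code{species_id}, \code{count}
#' @param ell numeric vector of scaling parameters
#' @return matrix of log Hill diversity, rows named by survey id, columns
#'   \code{D_simpson}, \code{D_shannon}, \code{D_richness},
#'   \code{D_abundance} for the default \code{ell} (otherwise
#'   \code{D_ell<value>})
#' @export
diversityMatrix <- function(x, ell = .ell_default) {
  counts <- if (is(x, "SurveySet")) surveyCounts(x) else x
  assertColumns(counts, c("survey_id", "species_id", "count"), "count table")
  if (!nrow(counts)) stop("no surveys supplied")
  ids <- unique(counts$survey_id)
  m <- t(vapply(ids, function(sid) {
    v <- .pooledAbundance(counts, sid)
    log(hillDiversity(v, ell))
  }, numeric(length(ell))))
  colnames(m) <- if (!is.null(names(ell)) && all(nzchar(names(ell))))
    paste0("D_", names(ell)) else paste0("D_ell", ell)
  rownames(m) <- as.character(ids)
  m
}

#' PCA of the Hill diversity metrics
#'
#' Principal component analysis of the (log) diversity matrix on the
#' correlation scale (columns centered and unit-scaled). Constant columns
#' are dropped with a warning. Loadings are sign-fixed so that PC1 loadings
#' are non-negative when all pairwise correlations are positive.
#'
#' @param m matrix as returned by \code{\link{diversityMatrix}}
#' @return list with \code{loadings} (variables x PCs),
#'   \code{var_explained} (percent per axis, sums to 100), and
#'   \code{scores}
#' @export
pcaDiversity <- function(m) {
  if (nrow(m) < 2) stop("PCA needs at least 2 surveys")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (!ncol(m)) stop("no varying diversity columns left")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  cors <- stats::cor(m)
  if (all(cors >= 0) && sum(load[, 1]) < 0) {
    load[, 1] <- -load[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  list(loadings = load, var_explained = ve, scores = pc$x)
}
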