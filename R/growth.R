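## Growth-curve primitives: the von Bertalanffy growth function (VBGF),
## length standardization, and the maximum-size-referenced growth
## coefficient Kmax.

#' Convert a length measurement to total length
#'
#' Published growth curves report asymptotic length as total length (TL),
#' standard length (SL), or fork length (FL). Species-specific linear
#' conversion factors map SL/FL onto TL; TL input is returned unchanged.
#'
#' @param value length in cm (vectorized)
#' @param from_type one of \code{"TL"}, \code{"SL"}, \code{"FL"}
#'   (vectorized, recycled against \code{value})
#' @param species_id species identifier (vectorized)
#' @param conversions data.frame with columns \code{species_id},
#'   \code{from_type}, \code{slope}, \code{intercept}; one row per
#'   (species, type) pair. Not consulted for TL input.
#' @return total length in cm
#' @examples
#' conv <- data.frame(species_id = "sp1", from_type = "SL",
#'                    slope = 1.2, intercept = 0)
#' standardizeLength(40, "SL", "sp1", conv)  # 48
#' standardizeLength(50, "TL", "sp1", conv)  # identity
#' @export
standardizeLength <- function(value, from_type, species_id, conversions) {
  n <- max(length(value), length(from_type), length(species_id))
  value <- rep_len(value, n)
  from_type <- rep_len(as.character(from_type), n)
  species_id <- rep_len(as.character(species_id), n)
  bad <- !from_type %in% c("TL", "SL", "FL")
  if (any(bad))
    stop("unknown length type: ", paste(unique(from_type[bad]), collapse = ", "))
  out <- value
  idx <- which(from_type != "TL")
  if (length(idx)) {
    if (missing(conversions) || is.null(conversions))
      stop("missing length-length conversion table for non-TL input")
    assertColumns(conversions, c("species_id", "from_type", "slope", "intercept"),
                  "conversion table")
    key <- paste(species_id[idx], from_type[idx])
    ckey <- paste(conversions$species_id, conversions$from_type)
    pos <- match(key, ckey)
    if (anyNA(pos)) {
      miss <- unique(key[is.na(pos)])
      stop("no length-length conversion factor for: ",
           paste(miss, collapse = "; "))
    }
    out[idx] <- conversions$slope[pos] * value[idx] + conversions$intercept[pos]
  }
  out
}

#' Von Bertalanffy length at age
#'
#' L(t) = L_inf (1 - exp(-K (t - t0))). Monotone increasing in t and
#' bounded above by \code{l_inf}.
#'
#' @param t age in years (>= 0, vectorized)
#' @param l_inf asymptotic total length (cm)
#' @param k growth coefficient (yr^-1)
#' @param t0 theoretical age at length zero (yr); fixed at 0 by default
#'   because published parameter pairs are standardized on trajectory shape
#' @return length in cm
#' @examples
#' vbgfLength(1, l_inf = 100, k = 0.5)  # 39.347
#' @export
vbgfLength <- function(t, l_inf, k, t0 = 0) {
  if (any(t < 0)) stop("age must be non-negative")
  if (any(l_inf <= 0) || any(k <= 0)) stop("l_inf and k must be positive")
  l_inf * (1 - exp(-k * (t - t0)))
}

#' Age at which a VBGF trajectory reaches a given length
#'
#' Inverse of \code{\link{vbgfLength}}: t = t0 - log(1 - L/L_inf)/K.
#' Lengths at or above the asymptote cannot be inverted; they are capped at
#' \code{cap} x L_inf (censused size classes can exceed literature maximum
#' sizes) and flagged via the \code{"capped"} attribute.
#'
#' @param L length in cm, 0 <= L (vectorized)
#' @param l_inf,k,t0 VBGF parameters as in \code{\link{vbgfLength}}
#' @param cap fraction of \code{l_inf} at which over-asymptote lengths are
#'   capped (default 0.99)
#' @return age in years, with logical attribute \code{"capped"}
#' @export
vbgfInverseAge <- function(L, l_inf, k, t0 = 0, cap = 0.99) {
  if (any(L < 0)) stop("length must be non-negative")
  capped <- L >= l_inf
  L2 <- ifelse(capped, cap * l_inf, L)
  t <- t0 - log(1 - L2 / l_inf) / k
  attr(t, "capped") <- capped
  t
}

## age at 95% of asymptotic length for a VBGF trajectory
.t95 <- function(k, t0 = 0) t0 - log(0.05) / k

#' Standardize a published growth curve to the species maximum size
#'
#' Kmax re-expresses a published (L_inf, K) trajectory as the growth
#' coefficient the same trajectory implies when its asymptote is set to the
#' species' maximum recorded total length. It is found as the K' minimizing
#' the squared distance between the rescaled curve Lmax(1 - e^(-K' t)) and
#' the observed curve L_inf(1 - e^(-K t)) over 100 equally spaced ages on
#' [0, t95], where t95 is the age at 95\% of L_inf. When L_inf = Lmax the
#' curves coincide and Kmax = K exactly.
#'
#' @param l_inf,k published VBGF parameters (total length cm, yr^-1)
#' @param lmax species maximum recorded total length (cm)
#' @param n_grid number of ages used in the least-squares match
#' @return Kmax (yr^-1)
#' @examples
#' computeKmax(l_inf = 80, k = 0.4, lmax = 100)  # ~0.31
#' computeKmax(l_inf = 60, k = 0.5, lmax = 60)   # exactly 0.5
#' @export
computeKmax <- function(l_inf, k, lmax, n_grid = 100) {
  if (length(l_inf) > 1 || length(k) > 1 || length(lmax) > 1)
    return(mapply(computeKmax, l_inf, k, lmax, MoreArgs = list(n_grid = n_grid)))
  if (lmax <= 0) stop("lmax must be positive")
  if (l_inf <= 0 || k <= 0) stop("l_inf and k must be positive")
  if (abs(l_inf - lmax) < 1e-12) return(k)
  ages <- seq(0, .t95(k), length.out = n_grid)
  obs <- l_inf * (1 - exp(-k * ages))
  sse <- function(kp) sum((lmax * (1 - exp(-kp * ages)) - obs)^2)
  ## bracket generously: the optimum scales roughly like k * l_inf/lmax
  upper <- max(2, 10 * k)
  opt <- stats::optimize(sse, interval = c(1e-6, upper), tol = 1e-10)
  if (!is.finite(opt$objective))
    stop(sprintf("Kmax optimization failed for l_inf=%g, k=%g, lmax=%g",
                 l_inf, k, lmax))
  opt$minimum
}

#' Filter a growth-record table to usable, unique marine records
#'
#' Drops (1) non-marine records, (2) records without a geographic location,
#' and (3) exact duplicates (same species, L_inf, K, and source). The number
#' of rows removed for each reason is attached as the \code{"dropped"}
#' attribute and reported via \code{message()}.
#'
#' @param records data.frame with at least \code{species_id}, \code{l_inf},
#'   \code{k}, \code{marine}, \code{lat}, \code{lon}; a \code{source}
#'   column is used for duplicate detection when present.
#' @return the filtered data.frame, attribute \code{"dropped"} holding the
#'   per-reason counts
#' @export
filterGrowthRecords <- function(records) {
  linf_col <- intersect(c("l_inf", "l_inf_reported"), names(records))[1]
  if (is.na(linf_col))
    stop("growth-record table needs an l_inf or l_inf_reported column")
  assertColumns(records, c("species_id", "k", "marine", "lat", "lon"),
                "growth-record table")
  n0 <- nrow(records)
  keep <- records$marine %in% TRUE
  n_marine <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  located <- !(is.na(records$lat) | is.na(records$lon))
  n_loc <- sum(!located)
  records <- records[located, , drop = FALSE]
  src <- if ("source" %in% names(records)) records$source else ""
  key <- paste(records$species_id, records[[linf_col]], records$k, src,
               sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  dropped <- c(non_marine = n_marine, unlocated = n_loc, duplicate = n_dup)
  message(sprintf("filtered growth records: %d -> %d (%s)", n0, nrow(records),
                  paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  if (!nrow(records)) warning("no growth records left after filtering")
  attr(records, "dropped") <- dropped
  records
}

#' Length-weight allometry
#'
#' W = a L^b with L in cm total length and W in grams.
#'
#' @param L total length (cm)
#' @param a,b species length-weight coefficients
#' @return mass in grams
#' @examples
#' lengthToMass(50, 0.01, 3)  # 1250 g
#' @export
lengthToMass <- function(L, a, b) {
  if (any(L <= 0) || any(a <= 0) || any(b <= 0))
    stop("length and allometric coefficients must be positive")
  a * L^b
}
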