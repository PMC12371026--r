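## Internal numerical helpers.

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x)))
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible 32-bit sub-seed from a parent seed and a label
#'
#' Streams for independent generators (species pool, growth records, surveys,
#' per-survey bootstraps) are split off one global seed so that modules stay
#' reproducible independently of each other.
#'
#' @param seed integer parent seed
#' @param label character tag naming the stream
#' @return an integer seed in [0, 2^31 - 1]
#' @keywords internal
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 2654435761) %% 2147483647)
}

#' Draw from a truncated normal by inverse-CDF
#'
#' Exact inverse-CDF sampling of Normal(mean, sd) truncated to [lo, hi].
#'
#' @param n number of draws
#' @param mean,sd normal parameters
#' @param lo,hi truncation bounds
#' @return numeric vector of n draws in [lo, hi]
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (any(hi < lo)) stop("truncation bounds reversed")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(q, lo), hi)
}

## Quantile labels used throughout posterior/bootstrap summaries
.qprobs <- c(0.05, 0.25, 0.5, 0.75, 0.95)

#' Assert that columns are present in a data.frame
#' @keywords internal
assertColumns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
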