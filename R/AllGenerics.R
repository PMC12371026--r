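#' @rdname SurveySet-class
#' @param x a \code{SurveySet}
#' @export
setGeneric("surveyCounts", function(x) standardGeneric("surveyCounts"))

#' @rdname SurveySet-class
#' @export
setGeneric("surveyData", function(x) standardGeneric("surveyData"))

#' @rdname SurveySet-class
#' @export
setGeneric("speciesTraits", function(x) standardGeneric("speciesTraits"))

#' @rdname SurveySet-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname BefFit-class
#' @param x a \code{BefFit}
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname BefFit-class
#' @export
setGeneric("pointwiseLogLik", function(x) standardGeneric("pointwiseLogLik"))

#' @rdname BefFit-class
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))

setMethod("surveyCounts", "SurveySet", function(x) x@counts)
setMethod("surveyData", "SurveySet", function(x) x@surveys)
setMethod("speciesTraits", "SurveySet", function(x) x@species)
setMethod("groundTruth", "SurveySet", function(x) x@groundTruth)

setMethod("posteriorDraws", "BefFit", function(x) x@draws)
setMethod("pointwiseLogLik", "BefFit", function(x) x@logLik)
setMethod("modelSpec", "BefFit", function(x) x@spec)

#' @rdname KmaxPredictions-class
#' @param x a \code{KmaxPredictions}
#' @param ... unused
#' @export
setMethod("as.data.frame", "KmaxPredictions",
          function(x, ...) x@predictions)

#' @export
setMethod("show", "SurveySet", function(object) {
  cat("SurveySet with", nrow(object@surveys), "surveys,",
      length(unique(object@surveys$site_id)), "sites,",
      nrow(object@species), "species\n")
  if (nrow(object@surveys)) {
    tab <- table(object@surveys$realm)
    cat("  realms:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
    cat("  individuals counted:", sum(object@counts$count), "\n")
  }
  if (length(object@groundTruth))
    cat("  carries simulation ground truth\n")
})

#' @export
setMethod("show", "KmaxPredictions", function(object) {
  p <- object@predictions
  cat("KmaxPredictions for", nrow(p), "targets",
      sprintf("(n_boot = %s)\n", paste(unique(p$n_boot), collapse = "/")))
  if (nrow(p))
    cat(sprintf("  median Kmax range: %.3f - %.3f yr^-1\n",
                min(p$median), max(p$median)))
})

#' @export
setMethod("show", "BefFit", function(object) {
  sp <- object@spec
  cat(sprintf("BefFit: %s ~ log D (ell = %s), %s family\n",
              sp$response, format(sp$ell), sp$family))
  cat(sprintf("  %d chains x %d draws; %d observations\n",
              length(unique(object@chain)),
              sum(object@chain == object@chain[1]),
              ncol(object@logLik)))
  dg <- object@diagnostics
  if (!is.null(dg$rhat))
    cat(sprintf("  max split-Rhat %.3f; min bulk ESS %.0f; divergences %d\n",
                max(dg$rhat, na.rm = TRUE),
                min(dg$ess_bulk, na.rm = TRUE),
                sum(dg$divergences)))
})
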