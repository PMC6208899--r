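#' Accessors for GeneSignature
#'
#' @param x a [GeneSignature-class].
#' @return `upGenes`/`downGenes` return character vectors of gene
#'   identifiers; `signatureMetadata` the build-metadata list.
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname signature-accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname signature-accessors
#' @export
setGeneric("signatureMetadata",
           function(x) standardGeneric("signatureMetadata"))

#' @rdname signature-accessors
setMethod("upGenes", "GeneSignature", function(x) x@upGenes)

#' @rdname signature-accessors
setMethod("downGenes", "GeneSignature", function(x) x@downGenes)

#' @rdname signature-accessors
setMethod("signatureMetadata", "GeneSignature", function(x) x@metadata)

#' Reference raw scores
#'
#' @param x a [ReferenceScoreSet-class].
#' @return sorted numeric vector of raw reference scores.
#' @export
setGeneric("refScores", function(x) standardGeneric("refScores"))

#' @rdname refScores
setMethod("refScores", "ReferenceScoreSet", function(x) x@scores)

#' DRP cutpoint accessor
#'
#' @param x a [CutpointEstimate-class].
#' @return the cutpoint percentile (numeric).
#' @export
setGeneric("drpCut", function(x) standardGeneric("drpCut"))

#' @rdname drpCut
setMethod("drpCut", "CutpointEstimate", function(x) x@drpCut)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature:", length(object@upGenes), "up /",
      length(object@downGenes), "down genes\n")
  md <- object@metadata
  if (!is.null(md$nUpCandidates)) {
    cat("  candidates before presence filter:",
        md$nUpCandidates, "up /", md$nDownCandidates, "down\n")
  }
  invisible(object)
})

setMethod("show", "ReferenceScoreSet", function(object) {
  cat("ReferenceScoreSet:", length(object@scores), "reference scores",
      sprintf("(range %.3f to %.3f)\n",
              min(object@scores), max(object@scores)))
  invisible(object)
})

setMethod("show", "DrpCoxFit", function(object) {
  s <- coxSummary(object)
  cat(sprintf(
    "DrpCoxFit [%s endpoint]: HR per %g points = %.3f (95%% CI %.3f-%.3f)\n",
    object@endpoint, object@scalePoints, s$hr, s$ci[1], s$ci[2]))
  cat(sprintf("  one-sided p = %.4g, two-sided p = %.4g; %d records, %d events",
              s$pOneSided, s$pTwoSided, object@nUsed, object@nEvents))
  if (nzchar(object@strataVar))
    cat(", stratified by", object@strataVar)
  cat("\n")
  invisible(object)
})

setMethod("show", "DrpKMResult", function(object) {
  cat(sprintf("DrpKMResult: DRP dichotomized at %g\n", object@cut))
  cat(sprintf("  groups (n): %s\n",
              paste(names(object@groupSizes), object@groupSizes,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  medians: %s\n",
              paste(names(object@medians),
                    signif(object@medians, 3), sep = "=", collapse = ", ")))
  cat(sprintf("  log-rank chi-square = %.3f, one-sided p = %.4g\n",
              object@chisq, object@pOneSided))
  invisible(object)
})

setMethod("show", "BaselineSurvival", function(object) {
  cat("BaselineSurvival:", object@source, "\n")
  cat(sprintf("  centered at drp = %.2f; supported up to t = %.3g\n",
              object@center * object@scalePoints, object@maxTime))
  invisible(object)
})

setMethod("show", "CutpointEstimate", function(object) {
  if (object@boundary == "interior") {
    cat(sprintf(
      "CutpointEstimate: DRP = %.2f (P[progression by %g mo] = %.3f)\n",
      object@drpCut, object@t0, object@achievedProb))
  } else {
    cat(sprintf(
      "CutpointEstimate: no interior solution (boundary: %s) for target %.3f at t0 = %g\n",
      object@boundary, object@targetProb, object@t0))
  }
  invisible(object)
})
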