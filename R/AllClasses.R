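#' @import methods
#' @importFrom stats cor quantile rnorm runif rexp rgamma sd
#'   pnorm pchisq qnorm lm coef vcov residuals as.formula complete.cases
#'   median setNames
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

#' GeneSignature: a two-armed drug-response gene signature
#'
#' Holds the two disjoint gene sets of a drug-response predictor: genes whose
#' expression correlates positively with drug sensitivity (`upGenes`) and
#' genes correlating with resistance (`downGenes`), together with build
#' metadata (configuration echo and candidate counts before/after the
#' clinical presence filter).
#'
#' @slot upGenes character vector of sensitivity-associated gene identifiers.
#' @slot downGenes character vector of resistance-associated gene identifiers.
#' @slot metadata named list of build metadata.
#'
#' @seealso [buildSignature()], [scoreSample()]
#' @export
setClass("GeneSignature",
  representation(
    upGenes = "character",
    downGenes = "character",
    metadata = "list"
  )
)

setValidity("GeneSignature", function(object) {
  msgs <- character()
  if (anyDuplicated(object@upGenes)) msgs <- c(msgs, "duplicate up genes")
  if (anyDuplicated(object@downGenes)) msgs <- c(msgs, "duplicate down genes")
  if (length(intersect(object@upGenes, object@downGenes)) > 0L)
    msgs <- c(msgs, "up and down gene sets must be disjoint")
  if (length(object@upGenes) == 0L || length(object@downGenes) == 0L)
    msgs <- c(msgs, "both up and down gene sets must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSignature
#'
#' @param upGenes character vector of sensitivity-associated gene ids.
#' @param downGenes character vector of resistance-associated gene ids.
#' @param metadata named list of build metadata.
#' @return A [GeneSignature-class] object.
#' @examples
#' sig <- GeneSignature(c("g1", "g2"), c("g3"))
#' upGenes(sig)
#' @export
GeneSignature <- function(upGenes, downGenes, metadata = list()) {
  new("GeneSignature",
    upGenes = as.character(upGenes),
    downGenes = as.character(downGenes),
    metadata = metadata
  )
}

#' ReferenceScoreSet: raw signature scores of a reference population
#'
#' Stores the sorted raw scores of a reference population (by default 819
#' breast-tumor biopsies in the simulators) against which new samples are
#' percentile-ranked.
#'
#' @slot scores sorted numeric vector of raw scores, length >= 2, finite.
#' @slot metadata named list describing provenance.
#' @export
setClass("ReferenceScoreSet",
  representation(scores = "numeric", metadata = "list")
)

setValidity("ReferenceScoreSet", function(object) {
  if (length(object@scores) < 2L)
    return("reference score set needs at least 2 scores")
  if (any(!is.finite(object@scores)))
    return("reference scores must be finite")
  if (is.unsorted(object@scores))
    return("reference scores must be sorted ascending")
  TRUE
})

#' Construct a ReferenceScoreSet
#'
#' Scores are sorted on construction.
#'
#' @param scores numeric vector of raw reference scores (length >= 2).
#' @param metadata named list of provenance metadata.
#' @return A [ReferenceScoreSet-class] object.
#' @export
ReferenceScoreSet <- function(scores, metadata = list()) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)))
    stop("reference scores must be finite", call. = FALSE)
  new("ReferenceScoreSet", scores = sort(scores), metadata = metadata)
}

#' DrpCoxFit: a fitted (stratified) Cox model for the DRP
#'
#' Wraps a [survival::coxph()] fit of a time-to-event endpoint on the DRP
#' percentile, scaled so the coefficient is per `scalePoints` percentile
#' points (default 50, so `exp(coef)` is the hazard ratio for a 50-point
#' difference). Records the complete-case data used, so diagnostics and
#' baseline estimation can run without re-supplying the cohort.
#'
#' @slot fit the underlying `coxph` object.
#' @slot scalePoints numeric; percentile points per coefficient unit.
#' @slot endpoint "ttp" or "os".
#' @slot drpTerm name of the DRP coefficient in `fit`.
#' @slot strataVar name of the stratification column ("" if unstratified).
#' @slot data the complete-case data.frame the model was fitted to.
#' @slot nUsed number of records used (complete cases).
#' @slot nEvents number of events among used records.
#' @export
setClass("DrpCoxFit",
  representation(
    fit = "ANY",
    scalePoints = "numeric",
    endpoint = "character",
    drpTerm = "character",
    strataVar = "character",
    data = "data.frame",
    nUsed = "integer",
    nEvents = "integer"
  )
)

setValidity("DrpCoxFit", function(object) {
  if (!inherits(object@fit, "coxph")) return("fit must be a coxph object")
  if (object@scalePoints <= 0) return("scalePoints must be positive")
  if (!object@drpTerm %in% names(coef(object@fit)))
    return("drpTerm not found among model coefficients")
  TRUE
})

#' DrpKMResult: dichotomized Kaplan-Meier / log-rank comparison
#'
#' @slot survfit the `survfit` object with one curve per DRP group.
#' @slot cut the DRP percentile used to dichotomize.
#' @slot chisq log-rank chi-square statistic.
#' @slot pOneSided one-sided log-rank p in the direction "high DRP better".
#' @slot pTwoSided two-sided log-rank p.
#' @slot medians named numeric, median survival per group (NA if undefined).
#' @slot groupSizes named integer, subjects per group.
#' @export
setClass("DrpKMResult",
  representation(
    survfit = "ANY",
    cut = "numeric",
    chisq = "numeric",
    pOneSided = "numeric",
    pTwoSided = "numeric",
    medians = "numeric",
    groupSizes = "integer"
  )
)

#' BaselineSurvival: stratum-averaged baseline survival function
#'
#' A right-continuous step (or analytic) baseline survival curve S0(t),
#' centered at a given value of the scaled DRP covariate. For stratified
#' fits the per-stratum Breslow baselines are averaged with weights
#' proportional to stratum sizes.
#'
#' @slot fun function of t returning S0(t).
#' @slot center the scaled-covariate value at which the baseline is taken
#'   (mean of drp/scalePoints in the fitted data).
#' @slot scalePoints percentile points per covariate unit.
#' @slot maxTime last supported time; evaluation beyond it returns the last
#'   value with an extrapolation warning.
#' @slot source character description of the estimator and weighting.
#' @export
setClass("BaselineSurvival",
  representation(
    fun = "function",
    center = "numeric",
    scalePoints = "numeric",
    maxTime = "numeric",
    source = "character"
  )
)

#' Construct a BaselineSurvival from an analytic survival function
#'
#' Useful for supplying a parametric baseline (e.g. exponential
#' `function(t) exp(-h0 * t)`) to [findCutpoint()].
#'
#' @param fun vectorized function of time returning S0(t) in (0, 1].
#' @param center scaled-covariate centering value (drp/scalePoints units).
#' @param scalePoints percentile points per covariate unit (default 50).
#' @param maxTime last supported time (default `Inf` for analytic curves).
#' @param source description string.
#' @return A [BaselineSurvival-class] object.
#' @examples
#' b <- baselineSurvival(function(t) exp(-0.1 * t), center = 0)
#' evaluateBaseline(b, 6)
#' @export
baselineSurvival <- function(fun, center = 0, scalePoints = 50,
                             maxTime = Inf, source = "analytic") {
  new("BaselineSurvival", fun = fun, center = center,
      scalePoints = scalePoints, maxTime = maxTime, source = source)
}

#' CutpointEstimate: DRP value solving a horizon-probability equation
#'
#' The DRP percentile at which the model-based probability of progression by
#' horizon `t0` equals `targetProb`. `boundary` is `"interior"` when the
#' solution lies inside (0, 100), otherwise `"low"`/`"high"`/`"flat"`.
#'
#' @slot drpCut the cutpoint percentile in [0, 100].
#' @slot boundary "interior", "low", "high" or "flat".
#' @slot t0 horizon in months.
#' @slot targetProb target progression probability.
#' @slot achievedProb model probability at `drpCut`.
#' @slot baselineSource description of the baseline estimator used.
#' @export
setClass("CutpointEstimate",
  representation(
    drpCut = "numeric",
    boundary = "character",
    t0 = "numeric",
    targetProb = "numeric",
    achievedProb = "numeric",
    baselineSource = "character"
  )
)

setValidity("CutpointEstimate", function(object) {
  if (object@boundary == "interior" &&
      (object@drpCut < 0 || object@drpCut > 100))
    return("interior cutpoint must lie in [0, 100]")
  TRUE
})
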