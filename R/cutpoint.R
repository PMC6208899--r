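#' Stratum-averaged Breslow baseline survival
#'
#' Turns a fitted (possibly stratified) DRP Cox model into an absolute
#' baseline survival curve. Per stratum, the Breslow cumulative-hazard
#' estimate is taken at the mean of the scaled DRP covariate (the
#' [survival::survfit()] default centering); the per-stratum curves are then
#' averaged with weights proportional to stratum sizes in the fitted data.
#' The result is a right-continuous step function with S0(0) = 1; evaluation
#' beyond the last supported time returns the last value with an
#' extrapolation warning.
#'
#' @param fit a [DrpCoxFit-class].
#' @return a [BaselineSurvival-class] centered at the mean scaled DRP.
#' @export
estimateBaselineSurvival <- function(fit) {
  stopifnot(is(fit, "DrpCoxFit"))
  sf <- survfit(fit@fit)
  center <- mean(fit@data$drp / fit@scalePoints)
  if (is.null(sf$strata)) {
    curves <- list(list(time = sf$time, surv = sf$surv))
    weights <- 1
  } else {
    ends <- cumsum(sf$strata)
    starts <- c(1L, head(ends, -1L) + 1L)
    curves <- lapply(seq_along(ends), function(i) {
      idx <- starts[i]:ends[i]
      list(time = sf$time[idx], surv = sf$surv[idx])
    })
    strataCol <- fit@strataVar
    weights <- as.numeric(table(fit@data[[strataCol]])[
      sub(".*=", "", names(sf$strata))])
    weights <- weights / sum(weights)
  }
  maxTime <- max(unlist(lapply(curves, `[[`, "time")), 0)
  evalOne <- function(curve, t) {
    # right-continuous: value at the last event time <= t; 1 before first
    vapply(t, function(ti) {
      k <- sum(curve$time <= ti)
      if (k == 0L) 1 else curve$surv[k]
    }, numeric(1))
  }
  fun <- function(t) {
    if (any(t > maxTime))
      warning(sprintf(
        "evaluating baseline survival beyond last event time %.4g; using last value",
        maxTime), call. = FALSE)
    vals <- vapply(seq_along(curves),
                   function(i) weights[i] * evalOne(curves[[i]], t),
                   numeric(length(t)))
    if (length(t) == 1L) sum(vals) else rowSums(matrix(vals, nrow = length(t)))
  }
  new("BaselineSurvival", fun = fun, center = center,
      scalePoints = fit@scalePoints, maxTime = maxTime,
      source = sprintf(
        "Breslow baseline per stratum at mean scaled DRP (%.4f), size-weighted average over %d stratum/strata",
        center, length(curves)))
}

#' Evaluate a baseline survival curve
#'
#' @param baseline a [BaselineSurvival-class].
#' @param t numeric vector of times.
#' @return S0(t), same length as `t`.
#' @export
evaluateBaseline <- function(baseline, t) {
  stopifnot(is(baseline, "BaselineSurvival"))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  baseline@fun(t)
}

#' Solve for the DRP cutpoint at a progression-probability target
#'
#' Finds the DRP percentile `d` at which the model-based probability of
#' progression by the horizon equals the target:
#' \deqn{1 - S_0(t_0)^{\exp(\beta (d/s - \bar d))} = \mathrm{target},}
#' where \eqn{S_0} is the (stratum-averaged) baseline survival centered at
#' the scaled-covariate mean \eqn{\bar d}, \eqn{\beta} the per-`s`-points
#' log-hazard, and `s = scalePoints`. Solved by bisection on [0, 100] to a
#' tolerance of 0.01 percentile points. For protective \eqn{\beta < 0},
#' patients with DRP below the returned cutpoint have progression
#' probability above the target. If the target is unreachable on [0, 100]
#' the nearest boundary is returned with a boundary flag (no exception);
#' with \eqn{\beta = 0} the probability does not depend on the DRP and the
#' result is flagged `"flat"`.
#'
#' @param fit a [DrpCoxFit-class], or a numeric log-hazard per
#'   `scalePoints` points (for analytic use).
#' @param baseline a [BaselineSurvival-class] (from
#'   [estimateBaselineSurvival()] or [baselineSurvival()]).
#' @param t0 horizon in months (> 0), e.g. 6 or 4.
#' @param targetProb target progression probability in (0, 1), e.g. 0.25.
#' @param tol bisection tolerance in percentile points (default 0.01).
#' @param scalePoints scale of a numeric `fit` (default 50; ignored for
#'   [DrpCoxFit-class]).
#' @return a [CutpointEstimate-class].
#' @examples
#' b <- baselineSurvival(function(t) exp(-0.1 * t), center = 0)
#' findCutpoint(log(0.55), b, t0 = 6, targetProb = 0.25)  # DRP ~ 61.5
#' @export
findCutpoint <- function(fit, baseline, t0, targetProb, tol = 0.01,
                         scalePoints = 50) {
  stopifnot(is(baseline, "BaselineSurvival"))
  if (!is.numeric(t0) || t0 <= 0) stop("`t0` must be > 0", call. = FALSE)
  if (!is.numeric(targetProb) || targetProb <= 0 || targetProb >= 1)
    stop("`targetProb` must lie in (0, 1)", call. = FALSE)
  if (is(fit, "DrpCoxFit")) {
    beta <- unname(coef(fit@fit)[fit@drpTerm])
    scalePoints <- fit@scalePoints
  } else {
    beta <- as.numeric(fit)
  }
  s0 <- suppressWarnings(evaluateBaseline(baseline, t0))
  if (s0 <= 0 || s0 > 1)
    stop("baseline survival at t0 must lie in (0, 1]", call. = FALSE)
  prob <- function(d)
    1 - s0^exp(beta * (d / scalePoints - baseline@center))

  mkEst <- function(d, boundary) new(
    "CutpointEstimate", drpCut = d, boundary = boundary, t0 = t0,
    targetProb = targetProb, achievedProb = prob(d),
    baselineSource = baseline@source)

  if (beta == 0 || s0 == 1) {
    return(mkEst(if (prob(0) >= targetProb) 100 else 0, "flat"))
  }
  p0 <- prob(0); p100 <- prob(100)
  lo <- min(p0, p100); hi <- max(p0, p100)
  if (targetProb < lo || targetProb > hi) {
    # decide which boundary is "nearest" in probability
    atLow <- abs(p0 - targetProb) <= abs(p100 - targetProb)
    return(mkEst(if (atLow) 0 else 100, if (atLow) "low" else "high"))
  }
  a <- 0; b <- 100
  fa <- prob(a) - targetProb
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- prob(m) - targetProb
    if ((fa <= 0) == (fm <= 0)) { a <- m; fa <- fm } else b <- m
  }
  mkEst((a + b) / 2, "interior")
}
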