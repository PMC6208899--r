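#' @importFrom survival coxph Surv strata survfit survdiff cox.zph
NULL

endpointColumns <- function(endpoint) {
  switch(endpoint,
         ttp = c(time = "ttp_months", event = "progression"),
         os = c(time = "os_months", event = "death"),
         stop("endpoint must be 'ttp' or 'os'", call. = FALSE))
}

# Complete-case subset on the modeled fields, with basic validation.
completeCases <- function(cohort, fields) {
  stopifnot(is.data.frame(cohort))
  missingCols <- setdiff(fields, names(cohort))
  if (length(missingCols))
    stop("cohort is missing required columns: ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  cohort[complete.cases(cohort[, fields, drop = FALSE]), , drop = FALSE]
}

makeDrpCoxFit <- function(fit, data, scalePoints, endpoint, strataVar) {
  new("DrpCoxFit", fit = fit, scalePoints = scalePoints,
      endpoint = endpoint, drpTerm = "drp_scaled",
      strataVar = strataVar, data = data,
      nUsed = nrow(data), nEvents = as.integer(fit$nevent))
}

#' Fit a stratified Cox model with the DRP as continuous covariate
#'
#' Fits `Surv(time, event) ~ drp/scalePoints`, stratified by treatment line
#' (or another column), with Breslow tie handling by default. The DRP enters
#' scaled by `scalePoints` (default 50), so `exp(coef)` is the hazard ratio
#' for a 50-percentile-point difference. Records with missing values in any
#' modeled field are excluded (complete-case). The one-sided p-value tests
#' the protective direction (higher DRP, lower hazard) via the Wald
#' statistic.
#'
#' @param cohort data.frame in the cohort layout of [simulateCohort()].
#' @param endpoint `"ttp"` (time to progression, default) or `"os"`.
#' @param scalePoints percentile points per coefficient unit (default 50).
#' @param strataVar stratification column name (default `"line"`; `NULL`
#'   for an unstratified fit).
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return a [DrpCoxFit-class].
#' @export
fitCoxContinuous <- function(cohort, endpoint = c("ttp", "os"),
                             scalePoints = 50, strataVar = "line",
                             ties = c("breslow", "efron")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  if (!is.numeric(scalePoints) || scalePoints <= 0)
    stop("`scalePoints` must be > 0", call. = FALSE)
  cols <- endpointColumns(endpoint)
  fields <- c("drp", cols, if (!is.null(strataVar)) strataVar)
  d <- completeCases(cohort, fields)
  if (any(d[[cols["time"]]] < 0))
    stop("negative event times", call. = FALSE)
  if (sum(d[[cols["event"]]]) < 2L)
    stop("need at least 2 events to fit", call. = FALSE)
  if (sd(d$drp) == 0)
    stop("DRP covariate is constant", call. = FALSE)
  d$drp_scaled <- d$drp / scalePoints
  rhs <- "drp_scaled"
  if (!is.null(strataVar)) rhs <- paste0(rhs, " + strata(", strataVar, ")")
  fml <- as.formula(sprintf("Surv(%s, %s) ~ %s",
                            cols["time"], cols["event"], rhs))
  fit <- coxph(fml, data = d, ties = ties)
  makeDrpCoxFit(fit, d, scalePoints, endpoint,
                if (is.null(strataVar)) "" else strataVar)
}

#' Summarize the DRP term of a fitted Cox model
#'
#' @param fit a [DrpCoxFit-class].
#' @param level confidence level (default 0.95; the study also reports 0.90).
#' @return list with `coef`, `se`, `z`, `hr` (per `scalePoints` points),
#'   `ci` (length-2), `pTwoSided`, `pOneSided` (protective direction).
#' @export
coxSummary <- function(fit, level = 0.95) {
  stopifnot(is(fit, "DrpCoxFit"))
  b <- coef(fit@fit)[fit@drpTerm]
  se <- sqrt(diag(vcov(fit@fit))[fit@drpTerm])
  z <- b / se
  q <- qnorm(1 - (1 - level) / 2)
  list(coef = unname(b), se = unname(se), z = unname(z),
       hr = unname(exp(b)),
       ci = unname(exp(c(b - q * se, b + q * se))),
       pTwoSided = unname(2 * pnorm(-abs(z))),
       pOneSided = unname(pnorm(z)))
}

#' Hazard ratio for an arbitrary DRP difference
#'
#' Rescales a fitted (or given) per-`scalePoints` log-hazard to a
#' `deltaPoints` percentile-point difference:
#' \eqn{\exp(\beta \cdot \Delta / \mathrm{scalePoints})}. E.g. an HR of 0.55
#' per 50 points corresponds to \eqn{\exp(1.6 \ln 0.55) = 0.384} per 80
#' points.
#'
#' @param fit a [DrpCoxFit-class], or a numeric hazard ratio per
#'   `scalePoints` points.
#' @param deltaPoints the DRP difference in percentile points.
#' @param scalePoints scale of a numeric `fit` (ignored for [DrpCoxFit-class],
#'   which carries its own).
#' @return the hazard ratio for a `deltaPoints` difference.
#' @examples
#' hrForDifference(0.55, 80)  # 0.384
#' @export
setGeneric("hrForDifference",
           function(fit, deltaPoints, scalePoints = 50)
             standardGeneric("hrForDifference"))

#' @rdname hrForDifference
setMethod("hrForDifference", "DrpCoxFit",
  function(fit, deltaPoints, scalePoints = 50) {
    b <- coef(fit@fit)[fit@drpTerm]
    unname(exp(b * deltaPoints / fit@scalePoints))
  })

#' @rdname hrForDifference
setMethod("hrForDifference", "numeric",
  function(fit, deltaPoints, scalePoints = 50) {
    if (fit <= 0) stop("hazard ratio must be positive", call. = FALSE)
    exp(log(fit) * deltaPoints / scalePoints)
  })

# Reference levels for the multivariate model's categorical covariates.
covariateReferenceLevels <- function() {
  c(age_group = "50-60", er_status = "positive", n_met_sites = "1",
    ps = "0-1")
}

covariateLevelOrder <- function() {
  list(age_group = c("50-60", "<50", "60-70", ">70"),
       er_status = c("positive", "negative"),
       n_met_sites = c("1", "2", "3", ">3"),
       ps = c("0-1", "2"))
}

#' Multivariate Cox model: DRP adjusted for clinical covariates
#'
#' Adds categorical clinical covariates (by default age group, ER status,
#' number of metastatic sites and performance status) to the stratified DRP
#' model. Reference levels follow the study's multivariate table: age 50-60,
#' ER positive, 1 metastatic site, PS 0-1. Records with a missing value in
#' any modeled field are excluded (complete-case); missing categorical
#' levels are treated as missing, not as their own level. A warning is
#' issued when events fall below five per estimated parameter.
#'
#' @param cohort cohort data.frame.
#' @param covariates character vector of covariate column names.
#' @param endpoint,scalePoints,strataVar,ties as in [fitCoxContinuous()].
#' @return a [DrpCoxFit-class] whose `fit` contains all terms.
#' @export
fitCoxMultivariate <- function(cohort,
                               covariates = c("age_group", "er_status",
                                              "n_met_sites", "ps"),
                               endpoint = c("ttp", "os"), scalePoints = 50,
                               strataVar = "line",
                               ties = c("breslow", "efron")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  cols <- endpointColumns(endpoint)
  fields <- c("drp", cols, covariates, if (!is.null(strataVar)) strataVar)
  d <- completeCases(cohort, fields)
  if (nrow(d) == 0L)
    stop("no complete cases for the requested covariates", call. = FALSE)
  if (sum(d[[cols["event"]]]) < 2L)
    stop("need at least 2 events to fit", call. = FALSE)
  ord <- covariateLevelOrder()
  for (cv in covariates) {
    if (is.character(d[[cv]]) || is.factor(d[[cv]])) {
      lv <- if (cv %in% names(ord)) {
        c(intersect(ord[[cv]], unique(as.character(d[[cv]]))),
          setdiff(unique(as.character(d[[cv]])), ord[[cv]]))
      } else unique(as.character(d[[cv]]))
      d[[cv]] <- factor(as.character(d[[cv]]), levels = lv)
      if (nlevels(droplevels(d[[cv]])) < 2L)
        stop(sprintf("covariate `%s` is constant after complete-case removal",
                     cv), call. = FALSE)
    }
  }
  d$drp_scaled <- d$drp / scalePoints
  rhs <- paste(c("drp_scaled", covariates), collapse = " + ")
  if (!is.null(strataVar)) rhs <- paste0(rhs, " + strata(", strataVar, ")")
  fml <- as.formula(sprintf("Surv(%s, %s) ~ %s",
                            cols["time"], cols["event"], rhs))
  fit <- coxph(fml, data = d, ties = ties)
  nPar <- length(coef(fit))
  if (fit$nevent < 5 * nPar)
    warning(sprintf("only %d events for %d parameters (< 5 per parameter)",
                    fit$nevent, nPar), call. = FALSE)
  makeDrpCoxFit(fit, d, scalePoints, endpoint,
                if (is.null(strataVar)) "" else strataVar)
}

#' Test for interaction between the DRP and a modifier
#'
#' Fits DRP, the modifier and their product term (stratified as usual) and
#' returns the two-sided Wald p-value for the product term(s); for a
#' modifier with more than two levels, a joint Wald chi-square over all
#' product terms is used.
#'
#' @param cohort cohort data.frame.
#' @param modifier column name of the potential effect modifier (e.g.
#'   `"prior_chemo"`, `"prior_anthracycline"`, `"prior_taxane"`).
#' @param endpoint,scalePoints,strataVar,ties as in [fitCoxContinuous()].
#' @return list with `p` (interaction p, two-sided), `chisq`, `df`, and
#'   `fit` (a [DrpCoxFit-class] of the interaction model).
#' @export
testInteraction <- function(cohort, modifier, endpoint = c("ttp", "os"),
                            scalePoints = 50, strataVar = "line",
                            ties = c("breslow", "efron")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  cols <- endpointColumns(endpoint)
  fields <- c("drp", cols, modifier, if (!is.null(strataVar)) strataVar)
  d <- completeCases(cohort, fields)
  if (nrow(d) == 0L)
    stop(sprintf("modifier `%s` has no observed values", modifier),
         call. = FALSE)
  mv <- d[[modifier]]
  if (length(unique(mv)) < 2L)
    stop(sprintf("modifier `%s` is constant", modifier), call. = FALSE)
  if (is.character(mv)) d[[modifier]] <- factor(mv)
  d$drp_scaled <- d$drp / scalePoints
  rhs <- sprintf("drp_scaled * %s", modifier)
  if (!is.null(strataVar)) rhs <- paste0(rhs, " + strata(", strataVar, ")")
  fml <- as.formula(sprintf("Surv(%s, %s) ~ %s",
                            cols["time"], cols["event"], rhs))
  fit <- coxph(fml, data = d, ties = ties)
  idx <- grep("^drp_scaled:", names(coef(fit)))
  if (!length(idx)) idx <- grep(":drp_scaled$", names(coef(fit)))
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V) %*% b)
  p <- pchisq(W, df = length(idx), lower.tail = FALSE)
  list(p = p, chisq = W, df = length(idx),
       fit = makeDrpCoxFit(fit, d, scalePoints, endpoint,
                           if (is.null(strataVar)) "" else strataVar))
}

#' Kaplan-Meier comparison of DRP-high vs DRP-low patients
#'
#' Dichotomizes the cohort at a DRP cut (default 50: high = DRP >= 50),
#' estimates Kaplan-Meier curves per group and runs the log-rank test. The
#' one-sided p-value is in the direction "high DRP does better" (fewer
#' events than expected in the high group).
#'
#' @param cohort cohort data.frame.
#' @param endpoint `"ttp"` (default) or `"os"`.
#' @param cut DRP percentile for dichotomization (default 50).
#' @return a [DrpKMResult-class].
#' @export
kmLogrankDichotomized <- function(cohort, endpoint = c("ttp", "os"),
                                  cut = 50) {
  endpoint <- match.arg(endpoint)
  cols <- endpointColumns(endpoint)
  d <- completeCases(cohort, c("drp", cols))
  d$group <- factor(ifelse(d$drp >= cut, "high", "low"),
                    levels = c("low", "high"))
  if (any(table(d$group) == 0L))
    stop(sprintf("dichotomization at %g leaves an empty group", cut),
         call. = FALSE)
  if (sum(d[[cols["event"]]]) == 0L)
    stop("no events observed; survival comparison undefined", call. = FALSE)
  fml <- as.formula(sprintf("Surv(%s, %s) ~ group",
                            cols["time"], cols["event"]))
  sf <- survfit(fml, data = d)
  sd <- survdiff(fml, data = d)
  chisq <- sd$chisq
  pTwo <- pchisq(chisq, df = 1, lower.tail = FALSE)
  highIdx <- grep("high", names(sd$n))
  protective <- sd$obs[highIdx] < sd$exp[highIdx]
  pOne <- if (protective) pTwo / 2 else 1 - pTwo / 2
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(sf)$table))
  gs <- table(d$group)
  new("DrpKMResult", survfit = sf, cut = cut, chisq = chisq,
      pOneSided = pOne, pTwoSided = pTwo, medians = med,
      groupSizes = setNames(as.integer(gs), names(gs)))
}

#' Martingale-residual diagnostics for a fitted DRP Cox model
#'
#' Computes martingale residuals per subject (their sum is zero under the
#' Breslow estimator), a working linear regression of the residuals on DRP
#' and DRP-squared to summarize curvature (a significant quadratic term
#' flags non-linearity of the DRP covariate), and a scaled-Schoenfeld
#' residual trend test of proportional hazards ([survival::cox.zph()]),
#' reported alongside and separately labeled.
#'
#' @param fit a [DrpCoxFit-class].
#' @return list with `residuals`, `residualSum`, `linearSlope`,
#'   `quadraticSlope`, `quadraticP` (curvature test), `phTable`
#'   (cox.zph table) and `phP` (proportional-hazards p for the DRP term).
#' @export
martingaleDiagnostics <- function(fit) {
  stopifnot(is(fit, "DrpCoxFit"))
  res <- residuals(fit@fit, type = "martingale")
  d <- fit@data
  drp <- d$drp
  wlm <- lm(res ~ drp + I(drp^2))
  cf <- summary(wlm)$coefficients
  zph <- cox.zph(fit@fit)
  phRow <- which(rownames(zph$table) == fit@drpTerm)
  if (!length(phRow)) phRow <- 1L
  list(
    residuals = res,
    residualSum = sum(res),
    linearSlope = unname(cf["drp", "Estimate"]),
    quadraticSlope = unname(cf["I(drp^2)", "Estimate"]),
    quadraticP = unname(cf["I(drp^2)", "Pr(>|t|)"]),
    phTable = zph$table,
    phP = unname(zph$table[phRow, "p"])
  )
}
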