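#' Default pipeline configuration
#'
#' Demo-scale configuration for [runPipeline()]: a 60-cell-line panel with
#' 1000 genes (60/55 planted at population correlation 0.6), a 300-sample
#' compendium with 10% silent genes, an 819-sample reference population, a
#' 140-patient cohort with the default clinical frequencies, and a
#' 6-month/25% cutpoint query.
#'
#' @return nested named list of stage configurations.
#' @export
defaultPipelineConfig <- function() {
  list(
    panel = list(nGenes = 1000, nCellLines = 60, nPlantedUp = 60,
                 nPlantedDown = 55, effectSize = 0.75, noiseSd = 1),
    compendium = list(nSamples = 300, silentFraction = 0.1),
    signature = list(rThreshold = 0.25, strict = TRUE,
                     presenceMinFraction = 0.5,
                     presenceIntensityQuantile = 0.25, epsilon = 0.025),
    reference = list(nSamples = 819),
    cohort = list(nPatients = 140),
    model = list(scalePoints = 50, strataVar = "line", endpoint = "ttp"),
    cutpoint = list(t0 = 6, targetProb = 0.25)
  )
}

mergeConfig <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(override)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      mergeConfig(defaults[[nm]], override[[nm]]) else override[[nm]]
  }
  defaults
}

writeResultJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full DRP analysis pipeline on simulated inputs
#'
#' End-to-end composition: simulate the cell-line panel and clinical
#' compendium, build the signature, simulate and score the reference
#' population, simulate the patient cohort, evaluate the DRP against TTP
#' (stratified continuous Cox fit, dichotomized Kaplan-Meier/log-rank,
#' martingale diagnostics) and solve the clinical cutpoint. All artifacts
#' (TSV/CSV/JSON) and a run manifest are written under `outDir`. Fully
#' deterministic for a fixed `seed`: per-stage seeds are derived from the
#' global seed, and rerunning with identical configuration reproduces every
#' result file byte-for-byte (the manifest carries the only timestamp).
#'
#' @param outDir output directory (created if needed).
#' @param seed global integer seed.
#' @param config optional nested list overriding parts of
#'   [defaultPipelineConfig()]; unknown keys are rejected.
#' @return the run manifest (named list), invisibly. Key artifacts:
#'   `signature.json`, `reference_scores.json`, `cohort.csv`,
#'   `evaluation.json`, `cutpoint.json`, `manifest.json`.
#' @export
runPipeline <- function(outDir, seed, config = list()) {
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logStage <- function(...) message("[drpsig] ", sprintf(...))
  stageSeed <- function(k) (as.integer(seed) + k) %% .Machine$integer.max

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  logStage("simulating cell-line panel (%d genes, %d lines)",
           cfg$panel$nGenes, cfg$panel$nCellLines)
  panel <- stage("panel", do.call(simulateCellLinePanel,
                                  c(cfg$panel, list(seed = stageSeed(1)))))
  writeExpressionTsv(panel$expr, file.path(outDir, "panel_expression.tsv"))
  writeSensitivityTsv(panel$sensitivity,
                      file.path(outDir, "panel_sensitivity.tsv"))

  logStage("simulating clinical compendium (%d samples)",
           cfg$compendium$nSamples)
  comp <- stage("compendium", do.call(simulateClinicalCompendium, c(
    cfg$compendium,
    list(geneIds = rownames(panel$expr), seed = stageSeed(2)))))

  logStage("building signature")
  sig <- stage("signature", do.call(buildSignature, c(
    list(panel = panel$expr, sens = panel$sensitivity,
         compendium = comp$expr), cfg$signature)))
  writeSignatureJson(sig, file.path(outDir, "signature.json"))

  logStage("simulating and scoring reference population (%d samples)",
           cfg$reference$nSamples)
  refMat <- stage("reference", simulateReferencePopulation(
    cfg$reference$nSamples, sig, seed = stageSeed(3)))
  refScoresSet <- stage("reference", buildReferenceScores(refMat, sig))
  writeReferenceScoresJson(refScoresSet,
                           file.path(outDir, "reference_scores.json"))

  logStage("simulating cohort (%d patients)", cfg$cohort$nPatients)
  cohort <- stage("cohort", do.call(simulateCohort, c(
    cfg$cohort, list(seed = stageSeed(4)))))
  writeCohortCsv(cohort, file.path(outDir, "cohort.csv"))

  logStage("fitting stratified Cox model on %s", cfg$model$endpoint)
  fit <- stage("evaluate", fitCoxContinuous(
    cohort, endpoint = cfg$model$endpoint,
    scalePoints = cfg$model$scalePoints, strataVar = cfg$model$strataVar))
  s95 <- coxSummary(fit, 0.95)
  s90 <- coxSummary(fit, 0.90)
  km <- stage("evaluate", kmLogrankDichotomized(
    cohort, endpoint = cfg$model$endpoint, cut = 50))
  diag <- stage("evaluate", martingaleDiagnostics(fit))
  evalOut <- list(
    endpoint = cfg$model$endpoint,
    scale_points = cfg$model$scalePoints,
    n_used = fit@nUsed, n_events = fit@nEvents,
    hr_per_scale = s95$hr, ci95 = s95$ci, ci90 = s90$ci,
    p_one_sided = s95$pOneSided, p_two_sided = s95$pTwoSided,
    km_median_low = unname(km@medians["low"]),
    km_median_high = unname(km@medians["high"]),
    km_logrank_p_one_sided = km@pOneSided,
    martingale_residual_sum = diag$residualSum,
    linearity_quadratic_p = diag$quadraticP,
    proportional_hazards_p = diag$phP)
  writeResultJson(evalOut, file.path(outDir, "evaluation.json"))

  logStage("solving cutpoint (t0 = %g months, target %.2f)",
           cfg$cutpoint$t0, cfg$cutpoint$targetProb)
  baseline <- stage("cutpoint", estimateBaselineSurvival(fit))
  cp <- stage("cutpoint", findCutpoint(
    fit, baseline, t0 = cfg$cutpoint$t0,
    targetProb = cfg$cutpoint$targetProb))
  writeResultJson(list(
    drp_cut = cp@drpCut, boundary = cp@boundary, t0 = cp@t0,
    target_prob = cp@targetProb, achieved_prob = cp@achievedProb,
    baseline_source = cp@baselineSource),
    file.path(outDir, "cutpoint.json"))

  artifacts <- c("panel_expression.tsv", "panel_sensitivity.tsv",
                 "signature.json", "reference_scores.json", "cohort.csv",
                 "evaluation.json", "cutpoint.json")
  cfgPath <- file.path(outDir, "config.json")
  writeResultJson(c(list(seed = as.integer(seed)), cfg), cfgPath)
  manifest <- list(
    tool = sprintf("drpsig %s",
                   as.character(utils::packageVersion("drpsig"))),
    seed = as.integer(seed),
    config_digest = unname(tools::md5sum(cfgPath)),
    artifact_digests = as.list(
      tools::md5sum(file.path(outDir, artifacts))),
    counts = list(
      panel_genes = nrow(panel$expr),
      signature_up = length(upGenes(sig)),
      signature_down = length(downGenes(sig)),
      reference_samples = length(refScores(refScoresSet)),
      cohort_patients = nrow(cohort),
      cox_events = fit@nEvents),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  names(manifest$artifact_digests) <- artifacts
  writeResultJson(manifest, file.path(outDir, "manifest.json"))
  logStage("done; artifacts in %s", outDir)
  invisible(manifest)
}
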