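#' Simulate an NCI60-like cell-line expression panel with drug sensitivities
#'
#' Generates a genes x cell-lines expression matrix together with a per-line
#' drug-sensitivity value on a "higher = more sensitive" scale (a
#' \eqn{-\log_{10}} GI50-like quantity). A latent sensitivity
#' \eqn{s_c \sim N(0,1)} is drawn per cell line; each planted
#' sensitivity-associated ("up") gene is \eqn{x_{gc} = w s_c + \epsilon},
#' each planted resistance-associated ("down") gene
#' \eqn{x_{gc} = -w s_c + \epsilon}, and all remaining genes are pure noise,
#' with \eqn{\epsilon \sim N(0, \sigma^2)}. The population correlation of a
#' planted gene with sensitivity is \eqn{\rho = w/\sqrt{w^2 + \sigma^2}}.
#'
#' @param nGenes total number of genes.
#' @param nCellLines number of cell lines (default 60).
#' @param nPlantedUp,nPlantedDown numbers of planted sensitivity/resistance
#'   genes; their sum must not exceed `nGenes`.
#' @param effectSize signal weight `w >= 0`.
#' @param noiseSd noise standard deviation `sigma > 0`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `expr` (matrix, genes x cell lines), `sensitivity`
#'   (named numeric, higher = more sensitive) and `truth` (list with
#'   `up`, `down`, `silent` gene-id character vectors).
#' @examples
#' p <- simulateCellLinePanel(100, nPlantedUp = 5, nPlantedDown = 5,
#'                            effectSize = 0.75, seed = 1)
#' dim(p$expr)
#' @export
simulateCellLinePanel <- function(nGenes, nCellLines = 60,
                                  nPlantedUp = 0, nPlantedDown = 0,
                                  effectSize = 0, noiseSd = 1, seed) {
  nGenes <- assertCount(nGenes, "nGenes")
  nCellLines <- assertCount(nCellLines, "nCellLines", min = 2L)
  nPlantedUp <- assertCount(nPlantedUp, "nPlantedUp", min = 0L)
  nPlantedDown <- assertCount(nPlantedDown, "nPlantedDown", min = 0L)
  if (nPlantedUp + nPlantedDown > nGenes)
    stop("nPlantedUp + nPlantedDown must not exceed nGenes", call. = FALSE)
  if (!is.finite(effectSize) || effectSize < 0)
    stop("`effectSize` must be >= 0", call. = FALSE)
  if (!is.finite(noiseSd) || noiseSd <= 0)
    stop("`noiseSd` must be > 0", call. = FALSE)

  geneIds <- sprintf("g%05d", seq_len(nGenes))
  lineIds <- sprintf("CL%02d", seq_len(nCellLines))
  upIds <- geneIds[seq_len(nPlantedUp)]
  downIds <- geneIds[nPlantedUp + seq_len(nPlantedDown)]

  withSeed(seed, {
    s <- rnorm(nCellLines)
    eps <- matrix(rnorm(nGenes * nCellLines, sd = noiseSd),
                  nrow = nGenes, dimnames = list(geneIds, lineIds))
    signal <- c(rep(effectSize, nPlantedUp),
                rep(-effectSize, nPlantedDown),
                rep(0, nGenes - nPlantedUp - nPlantedDown))
    expr <- eps + outer(signal, s)
    list(
      expr = expr,
      sensitivity = setNames(s, lineIds),
      truth = list(up = upIds, down = downIds, silent = character())
    )
  })
}

#' Simulate a clinical tumor-expression compendium with silent genes
#'
#' Emulates a large compendium of clinical tumor samples used to retain only
#' genes detectably expressed in patients. A chosen fraction of genes is
#' "silent": their intensity is pinned exactly at the detection floor in
#' every sample, so they fail the default presence rule of
#' [presenceFilter()] with probability one. Detectable genes get strictly
#' positive intensities above the floor (gamma-distributed on an
#' arbitrary-intensity scale).
#'
#' @param nSamples number of compendium samples.
#' @param geneIds character vector of gene identifiers (non-empty).
#' @param silentFraction fraction of genes simulated as undetected; the
#'   silent count is `round(silentFraction * length(geneIds))`.
#' @param seed integer seed.
#' @param floorValue detection-floor intensity for silent genes.
#' @return list with `expr` (matrix) and `truth` (list with `silent` ids;
#'   `up`/`down` empty).
#' @export
simulateClinicalCompendium <- function(nSamples, geneIds, silentFraction,
                                       seed, floorValue = 1) {
  nSamples <- assertCount(nSamples, "nSamples")
  if (length(geneIds) == 0L)
    stop("`geneIds` must be non-empty", call. = FALSE)
  geneIds <- as.character(geneIds)
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifiers", call. = FALSE)
  silentFraction <- assertProb(silentFraction, "silentFraction")

  nGenes <- length(geneIds)
  nSilent <- round(silentFraction * nGenes)
  sampleIds <- sprintf("T%04d", seq_len(nSamples))

  withSeed(seed, {
    silent <- if (nSilent > 0) sort(sample(geneIds, nSilent)) else character()
    expr <- matrix(floorValue + 1 +
                     rgamma(nGenes * nSamples, shape = 9, scale = 0.7),
                   nrow = nGenes, dimnames = list(geneIds, sampleIds))
    expr[silent, ] <- floorValue
    list(expr = expr, truth = list(up = character(), down = character(),
                                   silent = silent))
  })
}

#' Simulate a reference tumor population covering a signature
#'
#' Produces an expression matrix over the signature's genes with continuous
#' per-gene variation, so raw signature scores of the population are almost
#' surely tie-free. Default size mirrors the 819-biopsy reference population
#' used for percentile scoring.
#'
#' @param nSamples number of reference samples (default 819, minimum 2).
#' @param signature a [GeneSignature-class].
#' @param seed integer seed.
#' @return expression matrix (signature genes x samples).
#' @export
simulateReferencePopulation <- function(nSamples = 819, signature, seed) {
  nSamples <- assertCount(nSamples, "nSamples", min = 2L)
  stopifnot(is(signature, "GeneSignature"))
  genes <- c(upGenes(signature), downGenes(signature))
  sampleIds <- sprintf("R%04d", seq_len(nSamples))
  withSeed(seed, {
    geneMean <- rnorm(length(genes), mean = 6, sd = 1)
    matrix(geneMean + rnorm(length(genes) * nSamples),
           nrow = length(genes), dimnames = list(genes, sampleIds))
  })
}

# Table-1-style default covariate frequencies of the 140-patient cohort.
defaultCohortFrequencies <- function() {
  list(
    lineProbs = setNames(c(29, 30, 24, 24, 33) / 140,
                         c("1", "2", "3", "4", "5+")),
    erProbs = setNames(c(122, 17, 1) / 140,
                       c("positive", "negative", "missing")),
    metProbs = setNames(c(57, 36, 27, 20) / 140, c("1", "2", "3", ">3")),
    psProbs = setNames(c(81, 9, 50) / 140, c("0-1", "2", "missing")),
    ageProbs = setNames(c(0.25, 0.20, 0.30, 0.25),
                        c("<50", "50-60", "60-70", ">70")),
    priorChemoProb = 78 / 140,
    priorAnthracyclineProb = 20 / 140,
    priorTaxaneProb = 0.21
  )
}

#' Simulate an advanced-breast-cancer patient cohort
#'
#' Generates per-patient DRP percentiles, clinical covariates at configurable
#' frequencies, and time-to-progression / overall-survival times under a
#' proportional-hazards law with treatment-line-specific baselines:
#' \deqn{h(t) = h_{0,\mathrm{line}} \exp(\beta_{50} \cdot \mathrm{DRP}/50 +
#'   \mathrm{covariate\ terms}).}
#' Event times are exponential by default (Weibull if `weibullShape != 1`,
#' parameterized so proportional hazards holds exactly). Censoring is
#' independent exponential plus an administrative follow-up cap; observed
#' time is the minimum, the event flag marks whether the event came first.
#'
#' Default covariate frequencies follow the study cohort's baseline table
#' (e.g. 87.1% ER positive); default `beta50 = log(0.55)` and baseline
#' hazards give a cohort median TTP near 9.3 months at mid-scale DRP.
#'
#' @param nPatients cohort size (default 140).
#' @param beta50 true log-hazard per 50 DRP percentile points for TTP.
#' @param osBeta50 same for overall survival.
#' @param baselineHazards named per-treatment-line TTP baseline hazards per
#'   month (at DRP = 0 and reference covariates); names must cover the line
#'   labels.
#' @param osBaselineHazards per-line OS baseline hazards.
#' @param lineProbs,erProbs,metProbs,psProbs,ageProbs named category
#'   frequencies (each must sum to 1). `erProbs`/`psProbs` may include a
#'   `"missing"` category, emitted as `NA`.
#' @param priorChemoProb,priorAnthracyclineProb,priorTaxaneProb prior
#'   treatment flag frequencies.
#' @param covariateBetas optional named list of log-hazards added to the TTP
#'   linear predictor; supported names: `er_negative`, `met_2`, `met_3`,
#'   `met_gt3`, `ps_2`, `age_lt50`, `age_60_70`, `age_gt70`.
#' @param censorRate independent exponential censoring rate per month
#'   (0 disables).
#' @param followupCapMonths administrative censoring horizon (`Inf`
#'   disables).
#' @param weibullShape Weibull shape for event times (1 = exponential).
#' @param drp optional numeric vector of DRP percentiles (length
#'   `nPatients`); drawn Uniform(0, 100) if `NULL`.
#' @param seed integer seed.
#' @return data.frame with columns `patient_id, drp, ttp_months,
#'   progression, os_months, death, line, age_group, er_status, n_met_sites,
#'   ps, prior_chemo, prior_anthracycline, prior_taxane`.
#' @examples
#' coh <- simulateCohort(nPatients = 50, seed = 7)
#' head(coh)
#' @export
simulateCohort <- function(nPatients = 140,
                           beta50 = log(0.55),
                           osBeta50 = log(0.48),
                           baselineHazards = setNames(
                             c(0.115, 0.125, 0.135, 0.15, 0.165),
                             c("1", "2", "3", "4", "5+")),
                           osBaselineHazards = setNames(
                             rep(0.08, 5), c("1", "2", "3", "4", "5+")),
                           lineProbs = NULL, erProbs = NULL,
                           metProbs = NULL, psProbs = NULL, ageProbs = NULL,
                           priorChemoProb = NULL,
                           priorAnthracyclineProb = NULL,
                           priorTaxaneProb = NULL,
                           covariateBetas = NULL,
                           censorRate = 0.04,
                           followupCapMonths = 48,
                           weibullShape = 1,
                           drp = NULL, seed) {
  nPatients <- assertCount(nPatients, "nPatients")
  defs <- defaultCohortFrequencies()
  if (is.null(lineProbs)) lineProbs <- defs$lineProbs
  if (is.null(erProbs)) erProbs <- defs$erProbs
  if (is.null(metProbs)) metProbs <- defs$metProbs
  if (is.null(psProbs)) psProbs <- defs$psProbs
  if (is.null(ageProbs)) ageProbs <- defs$ageProbs
  if (is.null(priorChemoProb)) priorChemoProb <- defs$priorChemoProb
  if (is.null(priorAnthracyclineProb))
    priorAnthracyclineProb <- defs$priorAnthracyclineProb
  if (is.null(priorTaxaneProb)) priorTaxaneProb <- defs$priorTaxaneProb

  assertProbVector(lineProbs, "lineProbs")
  assertProbVector(erProbs, "erProbs")
  assertProbVector(metProbs, "metProbs")
  assertProbVector(psProbs, "psProbs")
  assertProbVector(ageProbs, "ageProbs")
  if (any(baselineHazards <= 0) || any(osBaselineHazards <= 0))
    stop("baseline hazards must be > 0", call. = FALSE)
  if (!all(names(lineProbs) %in% names(baselineHazards)))
    stop("`baselineHazards` must name every treatment line", call. = FALSE)
  if (!all(names(lineProbs) %in% names(osBaselineHazards)))
    stop("`osBaselineHazards` must name every treatment line", call. = FALSE)
  if (censorRate < 0) stop("`censorRate` must be >= 0", call. = FALSE)
  if (weibullShape <= 0) stop("`weibullShape` must be > 0", call. = FALSE)
  if (!is.null(drp)) {
    if (length(drp) != nPatients || any(!is.finite(drp)) ||
        any(drp < 0 | drp > 100))
      stop("`drp` must be length nPatients with values in [0, 100]",
           call. = FALSE)
  }

  cb <- function(nm) {
    if (is.null(covariateBetas) || is.null(covariateBetas[[nm]])) 0
    else as.numeric(covariateBetas[[nm]])
  }

  withSeed(seed, {
    drawCat <- function(p) {
      x <- sample(names(p), nPatients, replace = TRUE, prob = p)
      ifelse(x == "missing", NA_character_, x)
    }
    line <- sample(names(lineProbs), nPatients, replace = TRUE,
                   prob = lineProbs)
    er <- drawCat(erProbs)
    met <- drawCat(metProbs)
    ps <- drawCat(psProbs)
    age <- drawCat(ageProbs)
    if (is.null(drp)) drp <- runif(nPatients, 0, 100)

    # linear predictor on the TTP scale; missing covariates contribute the
    # reference level (simulator truth has no missing mechanism on hazards)
    lp <- beta50 * drp / 50 +
      cb("er_negative") * (!is.na(er) & er == "negative") +
      cb("met_2") * (!is.na(met) & met == "2") +
      cb("met_3") * (!is.na(met) & met == "3") +
      cb("met_gt3") * (!is.na(met) & met == ">3") +
      cb("ps_2") * (!is.na(ps) & ps == "2") +
      cb("age_lt50") * (!is.na(age) & age == "<50") +
      cb("age_60_70") * (!is.na(age) & age == "60-70") +
      cb("age_gt70") * (!is.na(age) & age == ">70")

    drawTime <- function(h0, lpVec) {
      e <- rexp(nPatients)
      (e / (h0 * exp(lpVec)))^(1 / weibullShape)
    }
    tEvent <- drawTime(baselineHazards[line], lp)
    tDeath <- drawTime(osBaselineHazards[line], osBeta50 * drp / 50)

    cens <- if (censorRate > 0) rexp(nPatients, censorRate) else
      rep(Inf, nPatients)
    cens <- pmin(cens, followupCapMonths)

    data.frame(
      patient_id = sprintf("P%04d", seq_len(nPatients)),
      drp = drp,
      ttp_months = pmin(tEvent, cens),
      progression = tEvent <= cens,
      os_months = pmin(tDeath, cens),
      death = tDeath <= cens,
      line = line,
      age_group = age,
      er_status = er,
      n_met_sites = met,
      ps = ps,
      prior_chemo = runif(nPatients) < priorChemoProb,
      prior_anthracycline = runif(nPatients) < priorAnthracyclineProb,
      prior_taxane = runif(nPatients) < priorTaxaneProb,
      stringsAsFactors = FALSE
    )
  })
}
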