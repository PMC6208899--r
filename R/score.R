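#' Raw signature score of a single sample
#'
#' The raw score is the mean expression over the signature's up
#' (sensitivity) genes minus the mean over its down (resistance) genes, on
#' the logit-normalized scale. Signature genes missing from the sample are
#' skipped with a warning provided coverage stays at or above `minCoverage`
#' in both sets; below that the score errors, naming the missing fraction.
#'
#' @param sample named numeric vector of normalized expression values, or a
#'   one-column matrix with gene row names.
#' @param signature a [GeneSignature-class].
#' @param minCoverage minimum fraction of each gene set that must be present
#'   (default 0.8).
#' @return the raw score (numeric scalar).
#' @examples
#' sig <- GeneSignature(c("u1", "u2"), c("d1", "d2"))
#' scoreSample(c(u1 = 2, u2 = 4, d1 = 1, d2 = 3), sig)  # 3 - 2 = 1
#' @export
scoreSample <- function(sample, signature, minCoverage = 0.8) {
  stopifnot(is(signature, "GeneSignature"))
  if (is.matrix(sample)) {
    if (ncol(sample) != 1L)
      stop("`sample` matrix must have exactly one column", call. = FALSE)
    sample <- setNames(sample[, 1L], rownames(sample))
  }
  if (is.null(names(sample)))
    stop("`sample` must be named by gene id", call. = FALSE)
  minCoverage <- assertProb(minCoverage, "minCoverage")

  pick <- function(genes, label) {
    found <- genes[genes %in% names(sample)]
    cov <- length(found) / length(genes)
    if (cov < minCoverage)
      stop(sprintf(
        "%s-gene coverage %.1f%% below required %.1f%% (missing %d/%d genes)",
        label, 100 * cov, 100 * minCoverage,
        length(genes) - length(found), length(genes)), call. = FALSE)
    if (cov < 1)
      warning(sprintf("%d of %d %s genes missing from sample; skipped",
                      length(genes) - length(found), length(genes), label),
              call. = FALSE)
    sample[found]
  }
  upVals <- pick(upGenes(signature), "up")
  downVals <- pick(downGenes(signature), "down")
  if (any(!is.finite(c(upVals, downVals))))
    stop("non-finite expression values among signature genes", call. = FALSE)
  mean(upVals) - mean(downVals)
}

#' Score a reference population
#'
#' Applies [scoreSample()] to every column of a reference expression matrix
#' (after logit normalization unless `normalize = FALSE`) and returns the
#' sorted raw scores as a [ReferenceScoreSet-class].
#'
#' @param reference expression matrix (genes x samples).
#' @param signature a [GeneSignature-class].
#' @param normalize run [logitNormalize()] on the input first
#'   (default TRUE; set FALSE for pre-normalized matrices).
#' @param minCoverage per-sample signature coverage requirement.
#' @param epsilon logit-normalization boundary.
#' @return a [ReferenceScoreSet-class] of size `ncol(reference)`.
#' @export
buildReferenceScores <- function(reference, signature, normalize = TRUE,
                                 minCoverage = 0.8, epsilon = 0.025) {
  assertExpressionMatrix(reference, "reference")
  if (normalize) reference <- logitNormalize(reference, epsilon = epsilon)
  scores <- vapply(seq_len(ncol(reference)), function(j) {
    scoreSample(setNames(reference[, j], rownames(reference)), signature,
                minCoverage = minCoverage)
  }, numeric(1))
  ReferenceScoreSet(scores, metadata = list(
    nSamples = ncol(reference), normalized = normalize,
    nUp = length(upGenes(signature)), nDown = length(downGenes(signature))
  ))
}

#' Percentile of a raw score against a reference population
#'
#' Midrank empirical-CDF convention on the 0-100 scale:
#' \deqn{100 \cdot (\#\{s_i < r\} + 0.5\,\#\{s_i = r\}) / N.}
#' A score below every reference score maps to 0, above every score to 100;
#' scoring a tie-free reference against itself yields percentiles with mean
#' exactly 50. Vectorized over `raw`.
#'
#' @param raw numeric vector of raw scores.
#' @param ref a [ReferenceScoreSet-class].
#' @return percentiles in [0, 100], same length as `raw`.
#' @export
percentileScore <- function(raw, ref) {
  stopifnot(is(ref, "ReferenceScoreSet"))
  s <- refScores(ref)
  n <- length(s)
  vapply(raw, function(r) {
    if (!is.finite(r)) stop("raw score must be finite", call. = FALSE)
    p <- 100 * (sum(s < r) + 0.5 * sum(s == r)) / n
    min(max(p, 0), 100)
  }, numeric(1))
}

#' Score a set of tumor samples against a signature and reference
#'
#' Batch wrapper: logit-normalizes the input (unless `normalize = FALSE`),
#' computes each column's raw score and its percentile against the
#' reference. Per-sample failures are collected; the call fails only if
#' every sample fails, otherwise failed samples get `NA` with a warning.
#'
#' @param samples expression matrix (genes x samples); zero columns allowed.
#'   `NA` entries are treated as genes missing from that sample (array
#'   dropouts), subject to the coverage rule.
#' @param signature a [GeneSignature-class].
#' @param ref a [ReferenceScoreSet-class].
#' @param normalize,minCoverage,epsilon as in [buildReferenceScores()].
#' @return data.frame with columns `sample_id, raw_score, percentile,
#'   n_up_used, n_down_used`, one row per input column in input order.
#' @export
scoreCohort <- function(samples, signature, ref, normalize = TRUE,
                        minCoverage = 0.8, epsilon = 0.025) {
  stopifnot(is(signature, "GeneSignature"), is(ref, "ReferenceScoreSet"))
  if (ncol(samples) == 0L)
    return(data.frame(sample_id = character(), raw_score = numeric(),
                      percentile = numeric(), n_up_used = integer(),
                      n_down_used = integer(), stringsAsFactors = FALSE))
  assertExpressionMatrix(samples, "samples", allowNA = TRUE)
  errs <- character()
  rows <- lapply(seq_len(ncol(samples)), function(j) {
    v <- setNames(samples[, j], rownames(samples))
    v <- v[is.finite(v)]
    raw <- tryCatch({
      if (length(v) == 0L) stop("no finite values in sample")
      if (normalize) {
        v <- setNames(
          logitNormalize(matrix(v, ncol = 1,
                                dimnames = list(names(v), "s")),
                         epsilon = epsilon)[, 1],
          names(v))
      }
      scoreSample(v, signature, minCoverage = minCoverage)
    }, error = function(e) e)
    if (inherits(raw, "error")) {
      errs <<- c(errs, sprintf("%s: %s", colnames(samples)[j],
                               conditionMessage(raw)))
      return(data.frame(sample_id = colnames(samples)[j],
                        raw_score = NA_real_, percentile = NA_real_,
                        n_up_used = NA_integer_, n_down_used = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      sample_id = colnames(samples)[j],
      raw_score = raw,
      percentile = percentileScore(raw, ref),
      n_up_used = sum(upGenes(signature) %in% names(v)),
      n_down_used = sum(downGenes(signature) %in% names(v)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(errs) == ncol(samples))
    stop(paste(c("all samples failed to score:", errs), collapse = "\n  "),
         call. = FALSE)
  if (length(errs))
    warning(paste(c("some samples failed to score:", errs),
                  collapse = "\n  "), call. = FALSE)
  out
}
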