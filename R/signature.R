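#' Logit-normalize an expression matrix per sample
#'
#' Each column (sample) is rescaled affinely so its minimum maps to
#' `epsilon` and its maximum to `1 - epsilon`, then transformed by the logit
#' \eqn{\ln(p/(1-p))}. The map is monotone within each column, so rank order
#' is preserved; a value at the exact midpoint of its column's range maps to
#' 0. Constant columns map to all-zero. Because the min-max step absorbs any
#' per-sample affine transformation, downstream correlations and signatures
#' are invariant to per-sample scaling and offsets.
#'
#' @param matrix numeric expression matrix (genes x samples) with dimnames.
#' @param epsilon boundary shrinkage, `0 < epsilon < 0.5` (default 0.025).
#' @return logit-normalized matrix with the same dimnames.
#' @examples
#' m <- matrix(c(1, 2, 3), ncol = 1,
#'             dimnames = list(c("a", "b", "c"), "s1"))
#' logitNormalize(m)  # -3.6636, 0, 3.6636
#' @export
logitNormalize <- function(matrix, epsilon = 0.025) {
  assertExpressionMatrix(matrix)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon >= 0.5)
    stop("`epsilon` must lie in (0, 0.5)", call. = FALSE)
  out <- apply(matrix, 2L, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    p <- epsilon + (1 - 2 * epsilon) * (x - rng[1]) / (rng[2] - rng[1])
    log(p / (1 - p))
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Per-gene Pearson correlation with drug sensitivity
#'
#' Correlates each gene's (normalized) expression across cell lines with the
#' sensitivity vector. Sensitivity must be on a "higher = more sensitive"
#' scale (e.g. \eqn{-\log_{10}} GI50), so positive correlation marks
#' sensitivity-associated genes. Zero-variance genes get `r = 0` with a
#' `degenerate` flag rather than an error, so flat probes pass through.
#'
#' @param normed expression matrix (genes x cell lines), typically the
#'   output of [logitNormalize()].
#' @param sens named numeric vector of sensitivities, or a data.frame with
#'   columns `cell_line` and `sensitivity`.
#' @return data.frame with columns `gene_id`, `r`, `degenerate`.
#' @export
geneCorrelations <- function(normed, sens) {
  assertExpressionMatrix(normed, "normed")
  if (is.data.frame(sens)) {
    if (!all(c("cell_line", "sensitivity") %in% names(sens)))
      stop("sensitivity data.frame needs columns `cell_line`, `sensitivity`",
           call. = FALSE)
    sens <- setNames(sens$sensitivity, sens$cell_line)
  }
  if (is.null(names(sens)))
    stop("sensitivity vector must be named by cell line", call. = FALSE)
  if (any(!is.finite(sens)))
    stop("sensitivity values must be finite", call. = FALSE)
  common <- intersect(colnames(normed), names(sens))
  onlyM <- setdiff(colnames(normed), names(sens))
  onlyS <- setdiff(names(sens), colnames(normed))
  if (length(onlyM) || length(onlyS)) {
    if (length(common) < 4L)
      stop(sprintf(
        "cell-line identifiers do not match: matrix-only {%s}; panel-only {%s}",
        paste(onlyM, collapse = ", "), paste(onlyS, collapse = ", ")),
        call. = FALSE)
  }
  if (length(common) < 4L)
    stop("need at least 4 overlapping cell lines to correlate",
         call. = FALSE)
  x <- normed[, common, drop = FALSE]
  s <- sens[common]
  geneSd <- apply(x, 1L, sd)
  degenerate <- geneSd == 0 | sd(s) == 0
  r <- rep(0, nrow(x))
  if (sd(s) > 0 && any(!degenerate)) {
    r[!degenerate] <- as.numeric(cor(t(x[!degenerate, , drop = FALSE]), s))
  }
  data.frame(gene_id = rownames(x), r = r, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Threshold a correlation table into up/down candidate sets
#'
#' Genes with correlation strictly above `rThreshold` become sensitivity
#' ("up") candidates; strictly below `-rThreshold` resistance ("down")
#' candidates (non-strict if `strict = FALSE`). Degenerate genes are never
#' selected. The sets are disjoint by construction.
#'
#' @param corr data.frame from [geneCorrelations()].
#' @param rThreshold positive correlation threshold (default 0.25).
#' @param strict use strict inequalities (default TRUE).
#' @return list with character vectors `up` and `down`.
#' @export
selectCandidates <- function(corr, rThreshold = 0.25, strict = TRUE) {
  stopifnot(is.data.frame(corr), all(c("gene_id", "r") %in% names(corr)))
  if (!is.numeric(rThreshold) || rThreshold < 0 || rThreshold >= 1)
    stop("`rThreshold` must lie in [0, 1)", call. = FALSE)
  deg <- if ("degenerate" %in% names(corr)) corr$degenerate else
    rep(FALSE, nrow(corr))
  up <- if (strict) corr$r > rThreshold else corr$r >= rThreshold
  down <- if (strict) corr$r < -rThreshold else corr$r <= -rThreshold
  if (rThreshold == 0 && !strict) down <- down & corr$r < 0  # keep disjoint
  list(up = corr$gene_id[up & !deg], down = corr$gene_id[down & !deg])
}

#' Clinical presence filter
#'
#' Retains a candidate gene only if it appears in the clinical compendium
#' and its expression exceeds the compendium-wide intensity quantile
#' (`presenceIntensityQuantile`, default 0.25) in at least
#' `presenceMinFraction` (default 0.5) of compendium samples. This stands in
#' for the original predictor's removal of markers not detectably expressed
#' in patient tumors; with `presenceMinFraction = 0` the filter reduces to
#' membership in the compendium.
#'
#' @param up,down candidate gene-id character vectors.
#' @param compendium clinical expression matrix (genes x samples).
#' @param presenceMinFraction minimum fraction of samples above threshold.
#' @param presenceIntensityQuantile quantile of all compendium intensities
#'   used as the detection threshold.
#' @param metadata optional list merged into the signature metadata.
#' @return a [GeneSignature-class]; errors if either filtered set is empty.
#' @export
presenceFilter <- function(up, down, compendium,
                           presenceMinFraction = 0.5,
                           presenceIntensityQuantile = 0.25,
                           metadata = list()) {
  assertExpressionMatrix(compendium, "compendium")
  presenceMinFraction <- assertProb(presenceMinFraction,
                                    "presenceMinFraction")
  presenceIntensityQuantile <- assertProb(presenceIntensityQuantile,
                                          "presenceIntensityQuantile")
  up <- as.character(up); down <- as.character(down)
  thr <- quantile(compendium, presenceIntensityQuantile, names = FALSE)
  present <- function(genes) {
    genes <- genes[genes %in% rownames(compendium)]
    if (!length(genes)) return(character())
    frac <- rowMeans(compendium[genes, , drop = FALSE] > thr)
    genes[frac >= presenceMinFraction]
  }
  upKept <- present(up)
  downKept <- present(down)
  if (!length(upKept) || !length(downKept))
    stop(sprintf(
      "invalid signature: presence filter left %d up and %d down genes",
      length(upKept), length(downKept)), call. = FALSE)
  md <- c(metadata, list(
    nUpCandidates = length(up), nDownCandidates = length(down),
    nUp = length(upKept), nDown = length(downKept),
    presenceMinFraction = presenceMinFraction,
    presenceIntensityQuantile = presenceIntensityQuantile,
    presenceThreshold = thr
  ))
  GeneSignature(upKept, downKept, metadata = md)
}

#' Build a drug-response gene signature from a cell-line panel
#'
#' Composition of the full signature-construction pipeline:
#' [logitNormalize()] on the panel, [geneCorrelations()] against the
#' sensitivity values, [selectCandidates()] at the correlation threshold,
#' and [presenceFilter()] against the clinical compendium. Deterministic:
#' identical inputs give an identical signature. Metadata records candidate
#' counts before and after the presence filter.
#'
#' @param panel cell-line expression matrix (genes x cell lines).
#' @param sens sensitivity values (named vector or `cell_line`/`sensitivity`
#'   data.frame), higher = more sensitive. If raw GI50 values are supplied
#'   set `sensitivityScale = "gi50"` to convert via \eqn{-\log_{10}}.
#' @param compendium clinical compendium expression matrix.
#' @param rThreshold correlation threshold (default 0.25).
#' @param strict strict threshold inequalities (default TRUE).
#' @param presenceMinFraction,presenceIntensityQuantile see
#'   [presenceFilter()].
#' @param epsilon logit-normalization boundary (default 0.025).
#' @param sensitivityScale `"sensitivity"` (higher = more sensitive,
#'   default) or `"gi50"` (raw GI50, converted to \eqn{-\log_{10}} GI50).
#' @return a [GeneSignature-class].
#' @export
buildSignature <- function(panel, sens, compendium,
                           rThreshold = 0.25, strict = TRUE,
                           presenceMinFraction = 0.5,
                           presenceIntensityQuantile = 0.25,
                           epsilon = 0.025,
                           sensitivityScale = c("sensitivity", "gi50")) {
  sensitivityScale <- match.arg(sensitivityScale)
  if (is.data.frame(sens))
    sens <- setNames(sens$sensitivity, sens$cell_line)
  if (sensitivityScale == "gi50") {
    if (any(sens <= 0))
      stop("GI50 values must be positive to take -log10", call. = FALSE)
    sens <- -log10(sens)
  }
  normed <- logitNormalize(panel, epsilon = epsilon)
  corr <- geneCorrelations(normed, sens)
  cand <- selectCandidates(corr, rThreshold = rThreshold, strict = strict)
  presenceFilter(cand$up, cand$down, compendium,
                 presenceMinFraction = presenceMinFraction,
                 presenceIntensityQuantile = presenceIntensityQuantile,
                 metadata = list(rThreshold = rThreshold, strict = strict,
                                 epsilon = epsilon))
}
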