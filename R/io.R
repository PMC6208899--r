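#' Read an expression matrix from TSV
#'
#' Expected layout: header row; first column `gene_id`, remaining columns
#' sample identifiers; all cells finite decimals. Duplicate gene or sample
#' identifiers and non-numeric cells are rejected with the offending
#' address.
#'
#' @param path TSV file path.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
readExpressionTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene_id column plus at least one sample",
         call. = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column must be named `gene_id` (got `", names(df)[1], "`)",
         call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    colRaw <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(colRaw))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value '%s' at gene %s, sample %s",
                   as.character(colRaw[bad[1]]), genes[bad[1]], samples[j]),
           call. = FALSE)
    m[, j] <- v
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix numeric matrix (genes x samples) with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeExpressionTsv <- function(matrix, path) {
  assertExpressionMatrix(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cell-line sensitivity table as TSV
#'
#' Two columns: `cell_line`, `sensitivity`.
#'
#' @param sens named numeric vector of sensitivities.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSensitivityTsv <- function(sens, path) {
  stopifnot(is.numeric(sens), !is.null(names(sens)))
  write.table(data.frame(cell_line = names(sens), sensitivity = sens),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-line sensitivity table from TSV
#'
#' @param path TSV with columns `cell_line`, `sensitivity`.
#' @return named numeric vector.
#' @export
readSensitivityTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "sensitivity") %in% names(df)))
    stop("sensitivity TSV needs columns `cell_line`, `sensitivity`",
         call. = FALSE)
  if (anyDuplicated(df$cell_line))
    stop("duplicate cell-line identifiers", call. = FALSE)
  v <- as.numeric(df$sensitivity)
  if (any(!is.finite(v)))
    stop("non-finite sensitivity values", call. = FALSE)
  setNames(v, df$cell_line)
}

cohortRequiredColumns <- function() {
  c("patient_id", "drp", "ttp_months", "progression", "os_months", "death",
    "line", "age_group", "er_status", "n_met_sites", "ps")
}

#' Read a patient cohort from CSV
#'
#' Required columns: `patient_id, drp, ttp_months, progression, os_months,
#' death, line, age_group, er_status, n_met_sites, ps` (prior-treatment flag
#' columns are optional). Empty strings become missing values for fields
#' permitting missingness; complete-case filtering happens later, at model
#' time. Times must be non-negative and `drp` in [0, 100].
#'
#' @param path CSV file path.
#' @return cohort data.frame.
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character"))
  missingCols <- setdiff(cohortRequiredColumns(), names(df))
  if (length(missingCols))
    stop("cohort CSV missing required columns: ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids", call. = FALSE)
  for (col in c("line", "age_group", "er_status", "n_met_sites", "ps")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  for (col in c("progression", "death", "prior_chemo",
                "prior_anthracycline", "prior_taxane")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  for (col in c("ttp_months", "os_months")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop(sprintf("invalid %s for patient %s: %s", col,
                   df$patient_id[bad[1]], df[[col]][bad[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(df$drp) | df$drp < 0 | df$drp > 100)
  if (length(bad))
    stop(sprintf("DRP out of [0, 100] for patient %s", df$patient_id[bad[1]]),
         call. = FALSE)
  df
}

#' Write a patient cohort as CSV
#'
#' Missing values are written as empty strings.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a GeneSignature as JSON
#'
#' JSON layout: `{up_genes: [], down_genes: [], build_metadata: {}}`.
#'
#' @param signature a [GeneSignature-class].
#' @param path JSON file path.
#' @return `writeSignatureJson` the path invisibly; `readSignatureJson` a
#'   [GeneSignature-class].
#' @export
writeSignatureJson <- function(signature, path) {
  stopifnot(is(signature, "GeneSignature"))
  jsonlite::write_json(
    list(up_genes = upGenes(signature), down_genes = downGenes(signature),
         build_metadata = signatureMetadata(signature)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSignatureJson
#' @export
readSignatureJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  GeneSignature(x$up_genes, x$down_genes,
                metadata = as.list(x$build_metadata))
}

#' Read or write a ReferenceScoreSet as JSON
#'
#' @param ref a [ReferenceScoreSet-class].
#' @param path JSON file path.
#' @return `writeReferenceScoresJson` the path invisibly;
#'   `readReferenceScoresJson` a [ReferenceScoreSet-class].
#' @export
writeReferenceScoresJson <- function(ref, path) {
  stopifnot(is(ref, "ReferenceScoreSet"))
  jsonlite::write_json(
    list(scores = refScores(ref), metadata = ref@metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeReferenceScoresJson
#' @export
readReferenceScoresJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ReferenceScoreSet(x$scores, metadata = as.list(x$metadata))
}
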