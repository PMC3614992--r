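## Tab-delimited readers/writers for expression matrices, sample times,
## similarity matrices and orderings. All formats are plain TSV so that
## exports from any upstream tool can be used directly.

.stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("chronoq_format_error", "error")))
}
.stop_input <- function(...) {
  stop(errorCondition(sprintf(...), class = c("chronoq_input_error", "error")))
}

.check_rect <- function(file) {
  if (!file.exists(file)) .stop_input("file '%s' not found", file)
  nf <- utils::count.fields(file, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) .stop_input("'%s' is empty", file)
  nf
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Cells equal to one of the \code{missing} tokens are flagged
#' as missing (\code{NA}); [removeIncompleteGenes()] drops such genes before
#' any downstream computation.
#'
#' @param file path to a tab-delimited file.
#' @param missing character vector of tokens encoding a missing measurement.
#' @return numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames; missing entries are \code{NA}.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(file, missing = c("", "NA")) {
  nf <- .check_rect(file)
  if (length(unique(nf)) != 1L)
    .stop_format("'%s' is ragged: rows have %s fields", file,
                 paste(unique(nf), collapse = ", "))
  raw <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = NULL)
  if (ncol(raw) < 3L) .stop_input("fewer than 2 samples in '%s'", file)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(genes)) .stop_format("duplicated gene ids in '%s'", file)
  if (anyDuplicated(samples)) .stop_format("duplicated sample ids in '%s'", file)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals %in% missing] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad))
    .stop_format("non-numeric expression value '%s' in '%s'",
                 vals[which(bad)[1]], file)
  dimnames(num) <- list(genes, samples)
  num
}

#' Write an expression matrix to TSV
#'
#' @param x numeric genes-by-samples matrix with dimnames.
#' @param file output path.
#' @param missing token written for \code{NA} entries.
#' @return invisibly, \code{file}.
#' @export
writeExpressionMatrix <- function(x, file, missing = "NA") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  chr[is.na(x)] <- missing
  lines <- c(paste(c("gene", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Read per-sample times (survival or sampling time points) from TSV
#'
#' Two tab-separated columns: sample id, time value. Times must be finite
#' and nonnegative; the unit (days for survival, minutes/hours for time
#' series) is the caller's to track, as every computation in the package is
#' invariant to it.
#'
#' @param file path to a two-column tab-delimited file (no header).
#' @return named numeric vector of times.
#' @seealso [writeSampleTimes()]
#' @export
readSampleTimes <- function(file) {
  nf <- .check_rect(file)
  if (any(nf != 2L)) .stop_format("'%s' must have exactly 2 columns", file)
  raw <- utils::read.table(file, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) .stop_format("duplicated sample ids in '%s'", file)
  tv <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(tv)) .stop_format("non-numeric time value in '%s'", file)
  if (any(!is.finite(tv) | tv < 0))
    .stop_format("times must be finite and nonnegative in '%s'", file)
  stats::setNames(tv, ids)
}

#' Write per-sample times to TSV
#'
#' @param times named numeric vector.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeSampleTimes <- function(times, file) {
  stopifnot(is.numeric(times), !is.null(names(times)))
  writeLines(paste(names(times), format(times, trim = TRUE, digits = 15),
                   sep = "\t"), file)
  invisible(file)
}

#' Read a precomputed similarity matrix from TSV
#'
#' Square matrix with a header row and a first column of matching sample
#' identifiers. Diagonal cells may hold a placeholder (em dash, hyphen or an
#' empty cell): the diagonal is never used by the ordering objective and is
#' stored as \code{NA}.
#'
#' @param file path to a square tab-delimited file.
#' @param tol maximum tolerated absolute asymmetry.
#' @return a [SampleSimilarity-class] object (construction constant unknown).
#' @export
readSimilarityMatrix <- function(file, tol = 1e-9) {
  nf <- .check_rect(file)
  if (length(unique(nf)) != 1L) .stop_format("'%s' is ragged", file)
  raw <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = NULL)
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(vals) != ncol(vals)) .stop_format("'%s' is not square", file)
  if (!identical(ids, colnames(vals)))
    .stop_format("row and column ids differ in '%s'", file)
  placeholder <- vals %in% c("", "-", "–", "—", "NA")
  vals[placeholder] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) .stop_format("non-numeric similarity in '%s'", file)
  dimnames(num) <- list(ids, ids)
  offNA <- is.na(num) & row(num) != col(num)
  if (any(offNA)) .stop_format("missing off-diagonal similarity in '%s'", file)
  asym <- abs(num - t(num))
  if (max(asym, na.rm = TRUE) > tol)
    .stop_input("similarity matrix in '%s' is asymmetric (max |a-b| = %g)",
                file, max(asym, na.rm = TRUE))
  SampleSimilarity(num)
}

#' Write a similarity matrix to TSV
#'
#' @param similarity a [SampleSimilarity-class] object.
#' @param file output path.
#' @param diagonal placeholder written on the diagonal.
#' @return invisibly, \code{file}.
#' @export
writeSimilarityMatrix <- function(similarity, file, diagonal = "-") {
  s <- similarityMatrix(similarity)
  chr <- format(s, trim = TRUE, digits = 15)
  diag(chr) <- diagonal
  lines <- c(paste(c("similarity", colnames(s)), collapse = "\t"),
             paste(rownames(s), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Write an ordering (and its summary) to disk
#'
#' Writes a tab-delimited table with columns \code{rank}, \code{sample} and,
#' when \code{times} is given, \code{time}; plus a JSON side-car summarising
#' the run (overall similarity, validity flag, and the SMD against
#' \code{times} when available).
#'
#' @param ordering a [SampleOrdering-class] object.
#' @param file output TSV path.
#' @param times optional named numeric vector of known times.
#' @param summaryFile path for the JSON summary; default appends
#'   \code{.summary.json} to \code{file}; \code{NULL} skips it.
#' @return invisibly, \code{file}.
#' @seealso [readOrdering()]
#' @export
writeOrdering <- function(ordering, file, times = NULL,
                          summaryFile = paste0(file, ".summary.json")) {
  stopifnot(is(ordering, "SampleOrdering"))
  ids <- ordering@ids[ordering@ordering]
  df <- data.frame(rank = seq_along(ids), sample = ids)
  if (!is.null(times)) df$time <- unname(times[ids])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryFile)) {
    summary <- list(n = length(ids),
                    overall_similarity = ordering@similarity,
                    valid = ordering@valid)
    if (!is.null(times)) {
      res <- smd(ordering, times)
      summary$smd <- smdValue(res)
    }
    jsonlite::write_json(summary, summaryFile, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(file)
}

#' Read an ordering written by [writeOrdering()]
#'
#' @param file path to the TSV file.
#' @return a [SampleOrdering-class] object (similarity/validity unannotated).
#' @export
readOrdering <- function(file) {
  if (!file.exists(file)) .stop_input("file '%s' not found", file)
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("rank", "sample") %in% colnames(df)))
    .stop_format("'%s' lacks rank/sample columns", file)
  ids_in_path <- df$sample[order(as.integer(df$rank))]
  SampleOrdering(ids_in_path, ids = sort(ids_in_path))
}
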