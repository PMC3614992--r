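## Pre-processing: removal of genes with missing measurements and
## Pearson-correlation filtering against the per-sample time signal
## (survival time for cancer sets, known sampling times for time series).

.stop_empty <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("chronoq_empty_result", "chronoq_input_error",
                                "error")))
}

#' Drop genes with missing expression values
#'
#' Genes with a missing measurement in any sample carry unusable distance
#' information and are excluded before similarity construction. Gene order of
#' the survivors is preserved.
#'
#' @param x numeric genes-by-samples matrix; \code{NA} marks missing.
#' @return the matrix restricted to complete genes.
#' @export
removeIncompleteGenes <- function(x) {
  stopifnot(is.matrix(x))
  keep <- stats::complete.cases(x)
  if (!any(keep))
    .stop_empty("every gene has at least one missing value")
  x[keep, , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that signals undefined correlation
#' (either vector has zero variance) by returning \code{NA} instead of
#' warning. The gene filter treats an undefined correlation as 0: a constant
#' gene carries no ordering signal.
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return correlation in \[-1, 1\], or \code{NA} if undefined.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) .stop_input("'x' and 'y' lengths differ")
  if (length(x) < 2L) .stop_input("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Filter genes by absolute correlation with the time signal
#'
#' Keeps exactly the genes whose expression has absolute Pearson correlation
#' with the per-sample time signal strictly greater than \code{threshold}.
#' Genes with missing values are removed first (and counted separately);
#' genes with undefined correlation (zero variance) are treated as
#' correlation 0 and dropped. The strict inequality means a gene sitting
#' exactly at the threshold is dropped.
#'
#' @param x numeric genes-by-samples matrix (missing entries allowed; they
#'   are removed here).
#' @param times named numeric vector covering all samples of \code{x}:
#'   survival times, or known sampling time points for time-series data.
#' @param threshold correlation threshold in \[0, 1\]; the default 0.6 gives
#'   a radical dimensionality reduction on typical microarray sets.
#' @return list with elements \code{matrix} (the filtered matrix) and
#'   \code{report}: a list with \code{threshold}, \code{keptGeneIDs},
#'   \code{droppedMissing}, \code{droppedLowCorrelation} and
#'   \code{correlations} (named, per complete gene; \code{NA} = undefined).
#'   If no gene survives, an error of class \code{chronoq_empty_result} is
#'   signalled (catch it and lower the threshold).
#' @examples
#' x <- rbind(g1 = 1:4, g2 = c(2, 2, 2, 2))
#' colnames(x) <- paste0("S", 1:4)
#' times <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4)
#' filterGenesByTimeCorrelation(x, times, 0.6)$report$keptGeneIDs
#' @export
filterGenesByTimeCorrelation <- function(x, times, threshold = 0.6) {
  stopifnot(is.matrix(x), threshold >= 0, threshold <= 1)
  if (is.null(names(times))) {
    if (length(times) != ncol(x))
      .stop_input("'times' must be named or match the number of samples")
    names(times) <- colnames(x)
  }
  if (!all(colnames(x) %in% names(times)))
    .stop_input("'times' must cover every sample of the matrix")
  tv <- times[colnames(x)]
  n0 <- nrow(x)
  complete <- tryCatch(removeIncompleteGenes(x),
                       chronoq_empty_result = function(e) x[0, , drop = FALSE])
  droppedMissing <- n0 - nrow(complete)
  if (nrow(complete) == 0L)
    .stop_empty("no gene without missing values")
  r <- apply(complete, 1L, pearsonCorrelation, y = tv)
  keep <- !is.na(r) & abs(r) > threshold
  report <- list(threshold = threshold,
                 keptGeneIDs = rownames(complete)[keep],
                 droppedMissing = droppedMissing,
                 droppedLowCorrelation = sum(!keep),
                 correlations = r)
  if (!any(keep))
    .stop_empty("no gene passes |r| > %g; lower the threshold", threshold)
  list(matrix = complete[keep, , drop = FALSE], report = report)
}
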