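## End-to-end composition: pre-processing -> similarity -> training ->
## greedy extraction -> orientation/evaluation against known times.

#' Temporally order a set of samples
#'
#' Runs the full pipeline. Given an expression matrix and per-sample times,
#' the genes are first filtered ([removeIncompleteGenes()],
#' [filterGenesByTimeCorrelation()]), the similarity matrix is built
#' ([similarityFromExpression()]), the Q-learning agent is trained
#' ([trainOrderingAgent()]) and the greedy solution extracted
#' ([extractSolution()]). The objective is direction-symmetric, so when
#' times are available the result is oriented with [orientOrdering()] and
#' scored with [smd()].
#'
#' @param x a numeric genes-by-samples matrix, a
#'   [SampleSimilarity-class] (pre-processing and similarity construction
#'   are then skipped), or a \code{SummarizedExperiment} (the first assay is
#'   used).
#' @param times optional named numeric vector of survival times or known
#'   sampling time points. Required for gene filtering; without it an
#'   expression matrix is only cleaned of incomplete genes.
#' @param config an [RLConfig-class]; see [rlConfig()].
#' @param threshold Pearson filter threshold (used only when \code{x} is an
#'   expression matrix and \code{times} is given).
#' @param constant similarity construction constant (see
#'   [similarityFromExpression()]).
#' @param direction orientation convention passed to [orientOrdering()]:
#'   \code{"increasing"} (time series) or \code{"decreasing"} (survival
#'   sets, where later disease stages mean shorter survival).
#' @return a list with elements \code{ordering} (a [SampleOrdering-class],
#'   oriented when times are known), \code{fit} (the [OrderingFit-class]),
#'   \code{similarity}, \code{filterReport} (or \code{NULL}), and \code{smd}
#'   (an [SMDResult-class], or \code{NULL} without times).
#' @examples
#' S <- orderingFixture("table2_similarity")
#' res <- orderSamples(S, times = orderingFixture("table1_survival"),
#'                     config = rlConfig(episodes = 3000, seed = 1))
#' res$ordering
#' @export
orderSamples <- function(x, times = NULL, config = rlConfig(),
                         threshold = 0.6, constant = "auto",
                         direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  filterReport <- NULL
  if (is(x, "SampleSimilarity")) {
    similarity <- x
  } else {
    if (!is.matrix(x) && inherits(x, "SummarizedExperiment")) {
      if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
        .stop_input("SummarizedExperiment input needs the package installed")
      x <- SummarizedExperiment::assay(x)
    }
    if (!is.matrix(x)) .stop_input("unsupported input type")
    if (ncol(x) < 2L) .stop_input("need at least 2 samples")
    if (!is.null(times)) {
      filt <- filterGenesByTimeCorrelation(x, times, threshold)
      x <- filt$matrix
      filterReport <- filt$report
    } else {
      x <- removeIncompleteGenes(x)
    }
    similarity <- similarityFromExpression(x, constant)
  }
  if (!is.null(times) && !all(sampleIDs(similarity) %in% names(times)))
    .stop_input("'times' must cover every sample")
  fit <- trainOrderingAgent(similarity, config)
  ordering <- extractSolution(fit)
  smd_res <- NULL
  if (!is.null(times)) {
    ordering <- orientOrdering(ordering, times, direction)
    ordering@similarity <- overallSimilarity(ordering, similarity)
    ordering@valid <- isValidOrdering(ordering, similarity)
    smd_res <- smd(ordering, times)
  }
  list(ordering = ordering, fit = fit, similarity = similarity,
       filterReport = filterReport, smd = smd_res)
}
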