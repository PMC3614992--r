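#' Pairwise sample similarity matrix
#'
#' Symmetric matrix of pairwise similarities between samples. When built from
#' expression profiles the similarity is \code{constant - d(s_i, s_j)}, with
#' \code{d} the Euclidean distance between the expression vectors of the two
#' samples and \code{constant} a large constant chosen so that all
#' similarities stay positive. The diagonal carries no information for the
#' ordering objective (only distinct adjacent pairs are ever summed) and is
#' stored as \code{NA}.
#'
#' @slot sim numeric matrix, n x n, symmetric off the diagonal, with matching
#'   row and column names (the sample identifiers); diagonal is \code{NA}.
#' @slot constant the construction constant, or \code{NA} when the matrix was
#'   read from a file rather than built from expression data.
#'
#' @seealso [similarityFromExpression()], [readSimilarityMatrix()],
#'   [overallSimilarity()], [isValidOrdering()]
#' @export
setClass("SampleSimilarity",
  representation(sim = "matrix", constant = "numeric"))

setValidity("SampleSimilarity", function(object) {
  s <- object@sim
  if (!is.numeric(s) || !is.matrix(s)) return("'sim' must be a numeric matrix")
  if (nrow(s) != ncol(s)) return("'sim' must be square")
  if (nrow(s) < 2L) return("at least 2 samples are required")
  ids <- rownames(s)
  if (is.null(ids) || is.null(colnames(s)))
    return("'sim' must have row and column names (sample identifiers)")
  if (!identical(ids, colnames(s)))
    return("row and column names of 'sim' must be identical")
  if (anyDuplicated(ids)) return("duplicated sample identifiers")
  off <- s[row(s) != col(s)]
  if (any(!is.finite(off))) return("off-diagonal similarities must be finite")
  if (max(abs(s - t(s)), na.rm = TRUE) > 1e-9)
    return("'sim' must be symmetric (tolerance 1e-9)")
  if (length(object@constant) != 1L) return("'constant' must have length 1")
  TRUE
})

#' Construct a SampleSimilarity object
#'
#' @param sim symmetric numeric matrix with sample ids as dimnames. The
#'   diagonal is ignored and stored as \code{NA}.
#' @param constant construction constant (see [similarityFromExpression()]);
#'   \code{NA} when unknown.
#' @return a [SampleSimilarity-class] object.
#' @examples
#' m <- matrix(c(NA, 2, 2, NA), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' SampleSimilarity(m)
#' @export
SampleSimilarity <- function(sim, constant = NA_real_) {
  if (is.null(rownames(sim)) && is.null(colnames(sim))) {
    ids <- paste0("S", seq_len(nrow(sim)))
    dimnames(sim) <- list(ids, ids)
  } else if (is.null(rownames(sim))) {
    rownames(sim) <- colnames(sim)
  } else if (is.null(colnames(sim))) {
    colnames(sim) <- rownames(sim)
  }
  diag(sim) <- NA_real_
  new("SampleSimilarity", sim = sim, constant = as.numeric(constant)[1])
}

#' A (candidate) temporal ordering of samples
#'
#' A permutation of the sample indices, optionally annotated with its overall
#' similarity (the sum of similarities over adjacent pairs) and whether it
#' satisfies the successor-dominance validity constraint.
#'
#' @slot ordering integer permutation of \code{seq_along(ids)}.
#' @slot ids sample identifiers, indexed by the values in \code{ordering}.
#' @slot similarity overall similarity of the ordering (\code{NA} if not
#'   computed).
#' @slot valid does the ordering satisfy the validity constraint (\code{NA}
#'   if not checked).
#'
#' @seealso [overallSimilarity()], [isValidOrdering()], [extractSolution()]
#' @export
setClass("SampleOrdering",
  representation(ordering = "integer", ids = "character",
                 similarity = "numeric", valid = "logical"))

setValidity("SampleOrdering", function(object) {
  n <- length(object@ids)
  if (length(object@ordering) != n)
    return("'ordering' and 'ids' must have the same length")
  if (!identical(sort(object@ordering), seq_len(n)))
    return("'ordering' must be a permutation of seq_along(ids)")
  if (anyDuplicated(object@ids)) return("duplicated sample identifiers")
  if (length(object@similarity) != 1L || length(object@valid) != 1L)
    return("'similarity' and 'valid' must have length 1")
  TRUE
})

#' Construct a SampleOrdering
#'
#' @param ordering integer permutation (1-based sample indices) or a character
#'   vector of sample ids drawn without repetition from \code{ids}.
#' @param ids sample identifiers; defaults to \code{S1..Sn} for integer input,
#'   or to \code{ordering} itself for character input.
#' @param similarity,valid optional annotations.
#' @return a [SampleOrdering-class] object.
#' @examples
#' SampleOrdering(c(2L, 1L, 3L), ids = c("a", "b", "c"))
#' @export
SampleOrdering <- function(ordering, ids = NULL, similarity = NA_real_,
                           valid = NA) {
  if (is.character(ordering)) {
    if (is.null(ids)) ids <- sort(ordering)
    idx <- match(ordering, ids)
    if (anyNA(idx)) stop("ordering contains ids not present in 'ids'")
    ordering <- idx
  }
  ordering <- as.integer(ordering)
  if (is.null(ids)) ids <- paste0("S", seq_along(ordering))
  new("SampleOrdering", ordering = ordering, ids = as.character(ids),
      similarity = as.numeric(similarity)[1], valid = as.logical(valid)[1])
}

#' Configuration of the Q-learning ordering agent
#'
#' Holds the learning parameters. Create with [rlConfig()], which documents
#' the defaults and their rationale.
#'
#' @slot alpha learning rate in (0, 1].
#' @slot gamma discount factor in (0, 1].
#' @slot epsilon probability of the Q-greedy selection branch, in \[0, 1\];
#'   with probability \code{1 - epsilon} the one-step look-ahead branch is
#'   used instead.
#' @slot episodes number of training episodes.
#' @slot invalidPenalty positive penalty subtracted for repeated actions and
#'   for terminal paths violating the validity constraint; \code{NA} means
#'   "auto": twice the largest off-diagonal similarity of the instance.
#' @slot seed integer seed for the training RNG (\code{NA}: leave the RNG
#'   state alone).
#' @slot logEvery record the greedy solution's overall similarity every this
#'   many episodes.
#' @export
setClass("RLConfig",
  representation(alpha = "numeric", gamma = "numeric", epsilon = "numeric",
                 episodes = "integer", invalidPenalty = "numeric",
                 seed = "integer", logEvery = "integer"))

setValidity("RLConfig", function(object) {
  chk1 <- function(x) length(x) == 1L
  if (!all(vapply(list(object@alpha, object@gamma, object@epsilon,
                       object@episodes, object@invalidPenalty, object@seed,
                       object@logEvery), chk1, logical(1))))
    return("all configuration fields must have length 1")
  if (is.na(object@alpha) || object@alpha <= 0 || object@alpha > 1)
    return("'alpha' must be in (0, 1]")
  if (is.na(object@gamma) || object@gamma <= 0 || object@gamma > 1)
    return("'gamma' must be in (0, 1]")
  if (is.na(object@epsilon) || object@epsilon < 0 || object@epsilon > 1)
    return("'epsilon' must be in [0, 1]")
  if (is.na(object@episodes) || object@episodes < 0)
    return("'episodes' must be a nonnegative integer")
  if (!is.na(object@invalidPenalty) && object@invalidPenalty <= 0)
    return("'invalidPenalty' must be positive (or NA for auto)")
  if (is.na(object@logEvery) || object@logEvery < 1)
    return("'logEvery' must be a positive integer")
  TRUE
})

#' A trained ordering agent
#'
#' Result of [trainOrderingAgent()]: the learned Q table (an environment
#' mapping path-prefix keys to per-action value vectors, stored sparsely
#' because the full tree has on the order of n^n states), the training log,
#' the configuration used, and the similarity instance trained on.
#'
#' @slot q environment; keys are comma-separated action prefixes ("r" is the
#'   root), values numeric vectors of length n (one Q estimate per action).
#' @slot log data.frame with columns \code{episode} and \code{similarity}:
#'   the overall similarity of the greedy solution extracted at that episode.
#' @slot config the [RLConfig-class] used (with the penalty resolved).
#' @slot similarity the [SampleSimilarity-class] instance.
#' @slot simEvals total number of similarity-matrix evaluations performed
#'   during training (instrumentation; grows as episodes * n^2).
#' @seealso [extractSolution()], [trainingLog()]
#' @export
setClass("OrderingFit",
  representation(q = "environment", log = "data.frame", config = "RLConfig",
                 similarity = "SampleSimilarity", simEvals = "numeric"))

#' Result of the exhaustive oracle search
#'
#' All optimal orderings found by [bestValidOrderings()], together with the
#' certified maximum overall similarity. The ordering objective is
#' direction-symmetric and the validity constraint is checked left to right,
#' so each optimal valid chain represents two temporal readings; reversed
#' counterparts are listed (flagged \code{"reversed"}) when requested and not
#' independently valid.
#'
#' @slot bestSimilarity the certified maximum overall similarity.
#' @slot orderings list of integer permutations attaining it.
#' @slot direction character vector parallel to \code{orderings}:
#'   \code{"forward"} for independently valid chains, \code{"reversed"} for
#'   time-reversed counterparts.
#' @slot ids sample identifiers.
#' @slot nodes number of search-tree nodes explored.
#' @export
setClass("OracleResult",
  representation(bestSimilarity = "numeric", orderings = "list",
                 direction = "character", ids = "character",
                 nodes = "integer"))

#' Samples misplacement degree of an ordering
#'
#' Result of [smd()]: the number of misplaced samples, plus the per-position
#' flags. See [smd()] for the definition.
#'
#' @slot smd integer misplacement count, in \[0, n\].
#' @slot misplaced logical vector of length n, in ordering position order.
#' @export
setClass("SMDResult",
  representation(smd = "integer", misplaced = "logical"))

setValidity("SMDResult", function(object) {
  if (object@smd != sum(object@misplaced))
    return("'smd' must equal the number of TRUE flags")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "SampleSimilarity", function(object) {
  cat(sprintf("SampleSimilarity: %d samples", nrow(object@sim)))
  if (!is.na(object@constant))
    cat(sprintf(" (constant %.4g)", object@constant))
  cat("\n  ids: ", paste(utils::head(rownames(object@sim), 6), collapse = ", "),
      if (nrow(object@sim) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SampleOrdering", function(object) {
  cat("SampleOrdering: ",
      paste(object@ids[object@ordering], collapse = " -> "), "\n", sep = "")
  if (!is.na(object@similarity))
    cat(sprintf("  overall similarity: %.6g\n", object@similarity))
  if (!is.na(object@valid))
    cat("  valid:", object@valid, "\n")
})

setMethod("show", "RLConfig", function(object) {
  cat(sprintf(
    "RLConfig: alpha=%g gamma=%g epsilon=%g episodes=%d penalty=%s seed=%s logEvery=%d\n",
    object@alpha, object@gamma, object@epsilon, object@episodes,
    ifelse(is.na(object@invalidPenalty), "auto", format(object@invalidPenalty)),
    ifelse(is.na(object@seed), "none", format(object@seed)), object@logEvery))
})

setMethod("show", "OrderingFit", function(object) {
  cat(sprintf("OrderingFit: %d samples, %d episodes, %d states visited\n",
              nrow(object@similarity@sim), object@config@episodes,
              length(ls(object@q))))
  if (nrow(object@log))
    cat(sprintf("  last logged greedy similarity: %.6g (episode %d)\n",
                object@log$similarity[nrow(object@log)],
                object@log$episode[nrow(object@log)]))
})

setMethod("show", "OracleResult", function(object) {
  cat(sprintf("OracleResult: best similarity %.6g, %d optimal ordering(s), %d nodes\n",
              object@bestSimilarity, length(object@orderings), object@nodes))
  for (i in seq_along(object@orderings))
    cat(sprintf("  [%s] %s\n", object@direction[i],
                paste(object@ids[object@orderings[[i]]], collapse = " -> ")))
})

setMethod("show", "SMDResult", function(object) {
  cat(sprintf("SMD: %d misplaced of %d samples\n",
              object@smd, length(object@misplaced)))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn SampleSimilarity sample identifiers.
#' @param object an object of the documented class.
#' @export
setMethod("sampleIDs", "SampleSimilarity", function(object) rownames(object@sim))

#' @describeIn SampleSimilarity number of samples.
#' @export
setMethod("nSamples", "SampleSimilarity", function(object) nrow(object@sim))

#' @describeIn SampleSimilarity the similarity matrix (diagonal \code{NA}).
#' @export
setMethod("similarityMatrix", "SampleSimilarity", function(object) object@sim)

#' @describeIn SampleSimilarity the construction constant (\code{NA} if read).
#' @export
setMethod("constructionConstant", "SampleSimilarity",
          function(object) object@constant)

#' @describeIn SampleOrdering sample identifiers (in index order, not path
#'   order).
#' @param object an object of the documented class.
#' @export
setMethod("sampleIDs", "SampleOrdering", function(object) object@ids)

#' @describeIn SampleOrdering number of samples.
#' @export
setMethod("nSamples", "SampleOrdering", function(object) length(object@ids))

#' @describeIn SampleOrdering the integer permutation.
#' @export
setMethod("orderingIndices", "SampleOrdering", function(object) object@ordering)

#' @describeIn OrderingFit the training log (data.frame: episode, similarity).
#' @param object an object of the documented class.
#' @export
setMethod("trainingLog", "OrderingFit", function(object) object@log)

#' @describeIn OrderingFit the learned Q table (environment).
#' @export
setMethod("qTable", "OrderingFit", function(object) object@q)

#' @describeIn OracleResult the certified maximum overall similarity.
#' @param object an object of the documented class.
#' @export
setMethod("bestSimilarity", "OracleResult", function(object) object@bestSimilarity)

#' @describeIn OracleResult list of optimal orderings (integer permutations).
#' @export
setMethod("optimalOrderings", "OracleResult", function(object) object@orderings)

#' @describeIn OracleResult sample identifiers.
#' @export
setMethod("sampleIDs", "OracleResult", function(object) object@ids)

#' @describeIn SMDResult the misplacement count.
#' @param object an object of the documented class.
#' @export
setMethod("smdValue", "SMDResult", function(object) object@smd)

#' @describeIn SMDResult logical per-position misplacement flags.
#' @export
setMethod("misplacedSamples", "SMDResult", function(object) object@misplaced)
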