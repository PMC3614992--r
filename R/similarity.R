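## The similarity model: sim(i, j) = W - d(s_i, s_j) with d the Euclidean
## distance and W a large constant; the ordering objective Sim (sum over
## adjacent pairs) and the successor-dominance validity constraint.

#' Euclidean distance between two expression vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return the L2 norm of \code{u - v}.
#' @export
euclideanDistance <- function(u, v) {
  if (length(u) != length(v)) .stop_input("'u' and 'v' lengths differ")
  sqrt(sum((u - v)^2))
}

#' Build the pairwise similarity matrix from expression profiles
#'
#' Computes \code{sim(i, j) = constant - d(s_i, s_j)} for every pair of
#' samples, where \code{d} is the Euclidean distance between their expression
#' vectors. With \code{constant = "auto"} the constant is the largest
#' pairwise distance plus 1, which guarantees all similarities are at least 1
#' and leaves the maximizing ordering unchanged (the objective is affine in
#' the constant: Sim = (n-1) * constant - total adjacent distance).
#'
#' @param x numeric genes-by-samples matrix without missing values.
#' @param constant \code{"auto"} or a positive number. A constant smaller
#'   than the maximum pairwise distance yields negative similarities; this is
#'   allowed but flagged with a warning.
#' @return a [SampleSimilarity-class] object.
#' @export
similarityFromExpression <- function(x, constant = "auto") {
  stopifnot(is.matrix(x))
  if (anyNA(x))
    .stop_input("matrix has missing values; run removeIncompleteGenes() first")
  if (ncol(x) < 2L) .stop_input("need at least 2 samples")
  d <- as.matrix(stats::dist(t(x)))
  if (identical(constant, "auto")) {
    constant <- max(d) + 1
  } else {
    stopifnot(is.numeric(constant), length(constant) == 1L)
    if (constant < max(d))
      warning(sprintf(
        "constant %g is below the maximum pairwise distance %g; negative similarities",
        constant, max(d)))
  }
  SampleSimilarity(constant - d, constant = constant)
}

.resolve_ordering <- function(ordering, similarity) {
  ids <- sampleIDs(similarity)
  if (is(ordering, "SampleOrdering")) {
    if (!setequal(ordering@ids, ids))
      .stop_input("ordering and similarity refer to different samples")
    perm <- match(ordering@ids, ids)[ordering@ordering]
  } else if (is.character(ordering)) {
    perm <- match(ordering, ids)
    if (anyNA(perm)) .stop_input("unknown sample id in ordering")
  } else {
    perm <- as.integer(ordering)
  }
  n <- nSamples(similarity)
  if (!identical(sort(perm), seq_len(n)))
    .stop_input("ordering is not a permutation of the %d samples", n)
  perm
}

#' Overall similarity of an ordering
#'
#' The objective of the temporal ordering problem: the sum of pairwise
#' similarities over all adjacent samples of the sequence, to be maximized.
#'
#' @param ordering a [SampleOrdering-class], an integer permutation, or a
#'   character vector of sample ids.
#' @param similarity a [SampleSimilarity-class] object.
#' @return the summed adjacent similarity (0 for a single sample).
#' @examples
#' S <- orderingFixture("table2_similarity")
#' overallSimilarity(c(6, 3, 10, 5, 7, 9, 1, 8, 4, 2), S)  # 53.01
#' @export
overallSimilarity <- function(ordering, similarity) {
  perm <- .resolve_ordering(ordering, similarity)
  n <- length(perm)
  if (n < 2L) return(0)
  s <- similarityMatrix(similarity)
  sum(s[cbind(perm[-n], perm[-1L])])
}

#' Is an ordering valid (successor dominance)?
#'
#' An ordering is valid when every sample is at least as similar to its
#' immediate successor as to any sample appearing later in the sequence:
#' \code{sim(t_i, t_{i+1}) >= sim(t_i, t_j)} for all \code{j > i + 1}. The
#' comparison is non-strict, so exact ties do not invalidate. Equivalently,
#' each successor is an arg-max of similarity over the samples still
#' remaining — valid orderings are exactly nearest-neighbour chains.
#' Validity is direction-sensitive: the reverse of a valid ordering need not
#' be valid.
#'
#' @inheritParams overallSimilarity
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isValidOrdering <- function(ordering, similarity) {
  perm <- .resolve_ordering(ordering, similarity)
  n <- length(perm)
  if (n <= 2L) return(TRUE)
  s <- similarityMatrix(similarity)
  for (i in seq_len(n - 2L)) {
    here <- perm[i]
    succ <- s[here, perm[i + 1L]]
    if (succ < max(s[here, perm[(i + 2L):n]])) return(FALSE)
  }
  TRUE
}
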