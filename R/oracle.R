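## Exhaustive search for the optimal valid ordering(s). Used as ground truth
## on small instances. The successor-dominance constraint makes every valid
## ordering a nearest-neighbour chain (each successor is an arg-max of
## similarity over the remaining samples), so depth-first backtracking only
## branches on the start sample and on exact arg-max ties, with an
## admissible optimistic bound for additional pruning.

#' Exhaustive backtracking search for optimal valid orderings
#'
#' Certifies the maximum overall similarity over all orderings satisfying
#' [isValidOrdering()], by depth-first extension: a prefix is only extended
#' with samples that are arg-maxes of similarity to the current endpoint
#' over the remaining set (any other extension already violates successor
#' dominance), and abandoned when the current sum plus an optimistic bound
#' (remaining steps times the largest off-diagonal similarity — admissible,
#' so exactness is preserved) cannot reach the best sum found.
#'
#' The ordering objective is direction-symmetric and the validity constraint
#' reads the sequence left to right, so every optimal valid chain stands for
#' two temporal readings of the data. With \code{includeReversed = TRUE}
#' (the default) the reversed counterpart of each optimal chain is included
#' in the result, flagged \code{"reversed"} unless it is independently valid
#' (in which case both directions are found as chains and flagged
#' \code{"forward"}).
#'
#' @param similarity a [SampleSimilarity-class] object.
#' @param maxN safety limit on the number of samples (default 12); larger
#'   instances are refused.
#' @param includeReversed include time-reversed counterparts of the optimal
#'   chains (see above).
#' @param tol numeric tolerance used to compare accumulated sums against the
#'   incumbent (tie detection).
#' @return an [OracleResult-class] object.
#' @examples
#' bestValidOrderings(orderingFixture("table2_similarity"))
#' @export
bestValidOrderings <- function(similarity, maxN = 12L,
                               includeReversed = TRUE, tol = 1e-9) {
  stopifnot(is(similarity, "SampleSimilarity"))
  n <- nSamples(similarity)
  if (n > maxN)
    .stop_input("instance has %d samples; oracle refuses above maxN = %d",
                n, maxN)
  smat <- similarityMatrix(similarity)
  diag(smat) <- -Inf
  maxoff <- max(smat)
  best <- -Inf
  opt <- list()
  nodes <- 0L
  rec <- function(prefix, remaining, total) {
    nodes <<- nodes + 1L
    if (length(remaining) == 0L) {
      if (total > best + tol) {
        best <<- total; opt <<- list(prefix)
      } else if (total >= best - tol) {
        opt[[length(opt) + 1L]] <<- prefix
      }
      return(invisible())
    }
    if (total + length(remaining) * maxoff < best - tol) return(invisible())
    last <- prefix[length(prefix)]
    v <- smat[last, remaining]
    for (a in remaining[v == max(v)])
      rec(c(prefix, a), remaining[remaining != a], total + smat[last, a])
  }
  for (s in seq_len(n)) rec(s, seq_len(n)[-s], 0)
  direction <- rep("forward", length(opt))
  if (includeReversed) {
    keys <- vapply(opt, paste, "", collapse = ",")
    for (i in seq_along(keys)) {
      revp <- rev(opt[[i]])
      if (!(paste(revp, collapse = ",") %in% keys)) {
        opt[[length(opt) + 1L]] <- revp
        direction <- c(direction, "reversed")
      }
    }
  }
  new("OracleResult", bestSimilarity = best, orderings = opt,
      direction = direction, ids = sampleIDs(similarity),
      nodes = nodes)
}

## Iterative-insertion generation of all permutations of v (m! x m matrix).
.all_perms <- function(v) {
  m <- length(v)
  P <- matrix(v[1L], 1L, 1L)
  for (k in seq_len(m)[-1L]) {
    r <- nrow(P)
    blocks <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1L) P[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos <= k - 1L) P[, pos:(k - 1L), drop = FALSE] else NULL
      blocks[[pos]] <- cbind(left, rep(v[k], r), right, deparse.level = 0)
    }
    P <- do.call(rbind, blocks)
  }
  P
}

#' Enumerate every ordering (unpruned cross-check)
#'
#' Scores and validity-checks all n! orderings. This is the independent,
#' unpruned counterpart of [bestValidOrderings()] used to certify the pruned
#' search. Enumeration is chunked by the first sample to bound memory; the
#' limit of 10 samples keeps the largest case (10! = 3,628,800 orderings)
#' within a couple of minutes and a few hundred MB.
#'
#' @param similarity a [SampleSimilarity-class] object.
#' @param maxN refusal limit (default 10).
#' @return a list with \code{orderings} (n! x n integer matrix, one ordering
#'   per row), \code{similarity} (numeric vector of overall similarities)
#'   and \code{valid} (logical vector).
#' @export
enumerateOrderings <- function(similarity, maxN = 10L) {
  stopifnot(is(similarity, "SampleSimilarity"))
  n <- nSamples(similarity)
  if (n > maxN)
    .stop_input("instance has %d samples; enumeration refuses above maxN = %d",
                n, maxN)
  smat <- similarityMatrix(similarity)
  score_chunk <- function(P) {
    m <- nrow(P)
    sim <- numeric(m)
    valid <- rep(TRUE, m)
    for (i in seq_len(n - 1L))
      sim <- sim + smat[cbind(P[, i], P[, i + 1L])]
    for (i in seq_len(max(n - 2L, 0L))) {
      succ <- smat[cbind(P[, i], P[, i + 1L])]
      for (j in (i + 2L):n)
        valid <- valid & (succ >= smat[cbind(P[, i], P[, j])])
    }
    list(sim = sim, valid = valid)
  }
  if (n == 1L) {
    return(list(orderings = matrix(1L, 1L, 1L), similarity = 0,
                valid = TRUE))
  }
  chunks_P <- vector("list", n)
  chunks_s <- vector("list", n)
  chunks_v <- vector("list", n)
  for (s in seq_len(n)) {
    rest <- seq_len(n)[-s]
    P <- if (length(rest)) cbind(s, .all_perms(rest), deparse.level = 0)
         else matrix(s, 1L, 1L)
    storage.mode(P) <- "integer"
    sc <- score_chunk(P)
    chunks_P[[s]] <- P
    chunks_s[[s]] <- sc$sim
    chunks_v[[s]] <- sc$valid
  }
  list(orderings = do.call(rbind, chunks_P),
       similarity = unlist(chunks_s, use.names = FALSE),
       valid = unlist(chunks_v, use.names = FALSE))
}
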