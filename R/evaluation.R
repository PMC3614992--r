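## Ordering evaluation: the samples-misplacement-degree (SMD) statistic,
## orientation of a direction-ambiguous ordering by known times, and
## half-average reporting for survival data.

.resolve_times <- function(ordering, times) {
  stopifnot(is(ordering, "SampleOrdering"))
  ids_path <- ordering@ids[ordering@ordering]
  if (!is.null(names(times))) {
    if (!all(ids_path %in% names(times)))
      .stop_input("'times' is missing samples: %s",
                  paste(setdiff(ids_path, names(times)), collapse = ", "))
    unname(times[ids_path])
  } else {
    if (length(times) != length(ids_path))
      .stop_input("unnamed 'times' must have one value per sample")
    times[ordering@ordering]
  }
}

.as_ordering <- function(ordering, times = NULL) {
  if (is(ordering, "SampleOrdering")) return(ordering)
  if (is.character(ordering)) return(SampleOrdering(ordering))
  ids <- if (!is.null(times) && !is.null(names(times)) &&
             length(times) == length(ordering)) names(times)
         else paste0("S", seq_along(ordering))
  SampleOrdering(as.integer(ordering), ids = ids)
}

#' Samples misplacement degree (SMD)
#'
#' Counts the samples that sit in the wrong local position of an ordering,
#' judged against known times. An interior sample is misplaced when its time
#' lies outside the closed interval bounded by its two neighbours' times —
#' equivalently, when \code{sgn(t_i - t_{i-1}) * sgn(t_{i+1} - t_i) < 0}
#' (boundary-equal times count as placed). The first and last samples are
#' misplaced when their time is neither the earliest nor the latest of the
#' set (any sample attaining the extreme value qualifies). The statistic is
#' 0 for the time-sorted ordering and for its exact reverse (orderings are
#' time-reversible without additional information), lies in \[0, n\], and
#' depends on the times only through their ordering and extremes, so it is
#' invariant to strictly increasing transformations.
#'
#' @param ordering a [SampleOrdering-class], integer permutation, or
#'   character vector of sample ids.
#' @param times named numeric vector of known times (a plain vector is
#'   taken as indexed by sample index).
#' @return an [SMDResult-class] object.
#' @examples
#' hs <- orderingFixture("table4_orderings")$heat_shock
#' smd(hs$literature, hs$times)  # 2 misplaced samples
#' @export
smd <- function(ordering, times) {
  ordering <- .as_ordering(ordering, times)
  t_path <- .resolve_times(ordering, times)
  n <- length(t_path)
  if (n < 2L) .stop_input("SMD needs at least 2 samples")
  mis <- logical(n)
  mis[1L] <- t_path[1L] != min(t_path) && t_path[1L] != max(t_path)
  mis[n] <- t_path[n] != min(t_path) && t_path[n] != max(t_path)
  if (n > 2L) {
    d_in <- sign(t_path[2:(n - 1L)] - t_path[1:(n - 2L)])
    d_out <- sign(t_path[3:n] - t_path[2:(n - 1L)])
    mis[2:(n - 1L)] <- d_in * d_out < 0
  }
  new("SMDResult", smd = as.integer(sum(mis)), misplaced = mis)
}

#' Orient an ordering using known times
#'
#' The ordering objective is symmetric under reversal, so a recovered
#' ordering carries no intrinsic direction; the known times (survival or
#' sampling times) decide which end comes first. Returns the ordering or
#' its reverse, whichever has the larger Spearman rank correlation between
#' position and time (rank rather than product-moment, to be robust to
#' non-linearly spaced time points). With \code{direction = "decreasing"}
#' anti-correlation is selected instead — the convention for survival data,
#' where samples later in the disease course have shorter survival. An
#' exact tie leaves the input unchanged.
#'
#' @inheritParams smd
#' @param direction \code{"increasing"} or \code{"decreasing"}.
#' @return a [SampleOrdering-class] (annotations preserved; validity is
#'   direction-sensitive, so revalidate if needed).
#' @export
orientOrdering <- function(ordering, times,
                           direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  ordering <- .as_ordering(ordering, times)
  t_path <- .resolve_times(ordering, times)
  n <- length(t_path)
  rho <- suppressWarnings(
    stats::cor(seq_len(n), t_path, method = "spearman"))
  if (is.na(rho) || rho == 0) return(ordering)
  flip <- if (direction == "increasing") rho < 0 else rho > 0
  if (!flip) return(ordering)
  SampleOrdering(rev(ordering@ordering), ids = ordering@ids,
                 similarity = ordering@similarity, valid = NA)
}

#' Mean times of the two halves of an ordering
#'
#' Splits the ordered sequence into its first \code{ceiling(n/2)} and
#' remaining positions and returns the mean time of each half. For survival
#' data ordered by disease progression the left mean is expected to exceed
#' the right mean markedly (earlier-stage patients live longer).
#'
#' @inheritParams smd
#' @return named numeric vector \code{c(left = ..., right = ...)}.
#' @export
halfAverages <- function(ordering, times) {
  ordering <- .as_ordering(ordering, times)
  t_path <- .resolve_times(ordering, times)
  n <- length(t_path)
  if (n < 2L) .stop_input("need at least 2 samples")
  k <- ceiling(n / 2)
  c(left = mean(t_path[seq_len(k)]), right = mean(t_path[(k + 1L):n]))
}
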