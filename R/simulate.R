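## Synthetic expression data with a known latent temporal order: the
## statistical structure the ordering method assumes. Informative genes vary
## monotonically (linear or sigmoidal, random sign) along latent time plus
## Gaussian noise; the remaining genes are pure noise; survival times are an
## affine function of latent time with rank-preserving jitter.

#' Simulate expression samples along a latent trajectory
#'
#' Latent times are drawn uniformly over \code{[0, timeSpan]}; sorting them
#' defines the true ordering. Each informative gene follows a monotone
#' programme of latent time — linear, or sigmoidal with a random midpoint —
#' with random sign and an amplitude drawn from \code{Unif(3, 6)}, plus
#' \code{N(0, noiseSD)} measurement noise; in the zero-noise limit every
#' between-sample distance then grows strictly with latent-time separation,
#' so adjacent-similarity maximization provably aligns with latent time.
#' Non-informative genes are \code{N(0, 1)} noise. Survival times are affine
#' in latent time (increasing or decreasing with \code{survivalDirection}),
#' mapped to a 30-630 day range, plus jitter bounded by 45% of the smallest
#' gap between consecutive affine values so the survival rank order always
#' matches the latent order.
#'
#' @param nSamples number of samples (>= 2).
#' @param nGenes total number of genes.
#' @param fractionInformative fraction of genes tied to latent time.
#' @param noiseSD standard deviation of the measurement noise on
#'   informative genes.
#' @param timeSpan length of the latent-time interval (arbitrary units).
#' @param survivalDirection \code{"increasing"} (later latent time, longer
#'   survival) or \code{"decreasing"} (the cancer convention: progression
#'   shortens survival).
#' @param seed optional integer seed.
#' @return a list with \code{expression} (genes x samples matrix),
#'   \code{times} (named survival vector, days), \code{latentTimes},
#'   \code{ordering} (a [SampleOrdering-class]: the true latent order) and
#'   \code{informative} (ids of the informative genes).
#' @examples
#' sim <- simulateTemporalExpression(nSamples = 6, nGenes = 50, seed = 1)
#' sim$ordering
#' @export
simulateTemporalExpression <- function(nSamples = 10L, nGenes = 500L,
                                       fractionInformative = 0.1,
                                       noiseSD = 0.5, timeSpan = 100,
                                       survivalDirection = c("increasing",
                                                             "decreasing"),
                                       seed = NULL) {
  survivalDirection <- match.arg(survivalDirection)
  stopifnot(nSamples >= 2L, nGenes >= 1L,
            fractionInformative >= 0, fractionInformative <= 1,
            noiseSD >= 0, timeSpan > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nSamples)
  m <- as.integer(nGenes)
  nInf <- round(fractionInformative * m)
  latent <- stats::runif(n, 0, timeSpan)
  u <- latent / timeSpan
  ids <- paste0("S", seq_len(n))
  genes <- sprintf("G%04d", seq_len(m))
  x <- matrix(0, m, n, dimnames = list(genes, ids))
  if (nInf > 0) {
    for (g in seq_len(nInf)) {
      amp <- stats::runif(1, 3, 6) * sample(c(-1, 1), 1)
      if (stats::runif(1) < 0.5) {
        signal <- amp * (u - 0.5)
      } else {
        mid <- stats::runif(1, 0.25, 0.75)
        signal <- amp * (1 / (1 + exp(-8 * (u - mid))) - 0.5)
      }
      x[g, ] <- signal + stats::rnorm(n, 0, noiseSD)
    }
  }
  if (nInf < m)
    x[(nInf + 1L):m, ] <- stats::rnorm((m - nInf) * n, 0, 1)
  base <- if (survivalDirection == "increasing") 30 + u * 600
          else 30 + (1 - u) * 600
  gaps <- diff(sort(base))
  jit_bound <- if (length(gaps) && min(gaps) > 0) 0.45 * min(gaps) else 0
  survival <- base + stats::runif(n, -jit_bound, jit_bound)
  survival <- pmax(survival, 0)
  list(expression = x,
       times = stats::setNames(survival, ids),
       latentTimes = stats::setNames(latent, ids),
       ordering = SampleOrdering(order(latent), ids = ids),
       informative = genes[seq_len(nInf)])
}
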