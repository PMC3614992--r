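## The core method: a tabular Q-learning agent over a tree-shaped episodic
## environment whose root-to-leaf paths are candidate sample orderings.
## States are identified by their action prefix (the environment is a tree),
## the Q table is stored sparsely in an environment keyed by prefix, and
## action selection mixes a Q-greedy branch with a one-step look-ahead branch
## that follows the locally most similar unused sample.

#' Create a Q-learning configuration
#'
#' Defaults: undiscounted returns (\code{gamma = 1}) so the summed reward of
#' a distinct-action path telescopes to its overall similarity;
#' \code{alpha = 0.8}, \code{epsilon = 0.8} and 13,000 training episodes,
#' which solve instances of up to ~18 samples in seconds; the invalid-path
#' penalty defaults to twice the largest off-diagonal similarity of the
#' instance, large enough that no invalid path can out-value a valid one.
#'
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor in (0, 1].
#' @param epsilon probability of the Q-greedy branch in \[0, 1\] (the
#'   look-ahead branch is used otherwise).
#' @param episodes number of training episodes.
#' @param invalidPenalty positive penalty, or \code{NA} for the automatic
#'   choice above.
#' @param seed integer RNG seed for training (\code{NA}: do not reseed).
#' @param logEvery greedy-solution logging period, in episodes.
#' @return an [RLConfig-class] object.
#' @export
rlConfig <- function(alpha = 0.8, gamma = 1.0, epsilon = 0.8,
                     episodes = 13000L, invalidPenalty = NA_real_,
                     seed = NA_integer_, logEvery = 100L) {
  new("RLConfig", alpha = as.numeric(alpha), gamma = as.numeric(gamma),
      epsilon = as.numeric(epsilon), episodes = as.integer(episodes),
      invalidPenalty = as.numeric(invalidPenalty), seed = as.integer(seed),
      logEvery = as.integer(logEvery))
}

.resolve_penalty <- function(config, similarity) {
  if (!is.na(config@invalidPenalty)) return(config@invalidPenalty)
  2 * max(similarityMatrix(similarity), na.rm = TRUE)
}

.qkey <- function(state) {
  if (length(state) == 0L) "r" else paste0("r,", paste(state, collapse = ","))
}

#' Successor actions of a path state
#'
#' In the tree environment every non-terminal state has n outgoing
#' transitions, one per sample, with uniform blind-transition probability
#' 1/n. Repeated samples are physically possible transitions (they are
#' discouraged through the reward, not excluded from the environment);
#' terminal states (prefix length n) have none.
#'
#' @param state integer vector: the action prefix (possibly empty).
#' @param n number of samples.
#' @return integer vector of available actions (empty when terminal).
#' @export
pathSuccessors <- function(state, n) {
  if (length(state) >= n) return(integer(0))
  seq_len(n)
}

#' Reward of taking an action in a path state
#'
#' A repeated action is punished with \code{-invalidPenalty}. A fresh action
#' earns the similarity between the last sample of the prefix and the new
#' sample (0 at the root), so the undiscounted reward sum of a
#' distinct-action path telescopes to the overall similarity of its action
#' configuration. If the action completes a distinct-action path that fails
#' [isValidOrdering()], an additional \code{-invalidPenalty} is applied to
#' this final reward, which is what steers the agent towards valid paths.
#'
#' @param state integer action prefix (non-terminal).
#' @param action the sample index taken.
#' @param similarity a [SampleSimilarity-class] object.
#' @param config an [RLConfig-class]; only the (resolved) penalty is used.
#' @return the scalar reward.
#' @export
stepReward <- function(state, action, similarity, config = rlConfig()) {
  n <- nSamples(similarity)
  if (length(state) >= n) .stop_input("state is terminal")
  penalty <- .resolve_penalty(config, similarity)
  if (action %in% state) return(-penalty)
  r <- if (length(state) == 0L) 0
       else similarityMatrix(similarity)[state[length(state)], action]
  full <- c(state, action)
  if (length(full) == n && !anyDuplicated(full) &&
      !isValidOrdering(full, similarity))
    r <- r - penalty
  r
}

## Shared selection core. Draws one uniform for the branch choice and, only
## when several candidates tie exactly at the maximum and ties = "random",
## one more uniform to pick among them. `last` is 0 at the root; `smat` has
## -Inf on the diagonal so used rows never interfere.
.step_select <- function(key, last, cand, q, smat, epsilon, ties) {
  if (stats::runif(1) < epsilon) {
    qs <- get0(key, envir = q, ifnotfound = NULL)
    vals <- if (is.null(qs)) numeric(length(cand)) else qs[cand]
  } else {
    vals <- if (last == 0L) numeric(length(cand)) else smat[last, cand]
  }
  tied <- cand[vals == max(vals)]
  if (length(tied) == 1L || ties == "first") tied[1L]
  else tied[floor(stats::runif(1) * length(tied)) + 1L]
}

#' Select the next action (modified epsilon-greedy with look-ahead)
#'
#' With probability \code{epsilon} returns the unused action of maximal
#' Q-value at the current state (in the tree environment each successor
#' state is reached by exactly one arc, so the arc's Q-value is the reached
#' state's value); otherwise the one-step look-ahead branch returns the
#' unused action maximizing the total similarity of the extended path, i.e.
#' the most similar unused sample. Used actions are excluded whenever an
#' unused one exists (always the case for non-terminal states here).
#'
#' Exact ties are broken uniformly at random by default: both branches are
#' deterministic arg-maxes, so random tie-breaking is the mechanism's only
#' source of exploration (most importantly at the root, where the look-ahead
#' scores are all equal and the branch acts as a uniformly random restart).
#' \code{ties = "first"} gives the deterministic lowest-index rule instead.
#'
#' @param state integer action prefix (non-terminal).
#' @param q the Q-table environment (as in [OrderingFit-class]).
#' @param similarity a [SampleSimilarity-class] object.
#' @param config an [RLConfig-class]; only \code{epsilon} is used.
#' @param ties \code{"random"} (default) or \code{"first"}.
#' @return the selected action (sample index).
#' @export
selectAction <- function(state, q, similarity, config = rlConfig(),
                         ties = c("random", "first")) {
  ties <- match.arg(ties)
  n <- nSamples(similarity)
  if (length(state) >= n) .stop_input("state is terminal")
  smat <- similarityMatrix(similarity)
  diag(smat) <- -Inf
  used <- logical(n); used[state] <- TRUE
  cand <- which(!used)
  last <- if (length(state)) state[length(state)] else 0L
  .step_select(.qkey(state), last, cand, q, smat, config@epsilon, ties)
}

#' One Q-learning update
#'
#' Applies \code{Q(s,a) <- Q(s,a) + alpha * (r + gamma * maxQ(next) -
#' Q(s,a))}, where the next state is \code{state} extended by \code{action},
#' \code{maxQ(next)} is the largest Q-value at that state, and the maximum
#' over an empty successor set (terminal next state) is 0.
#' Unseen (state, action) pairs default to 0. The table is modified in
#' place.
#'
#' @param q the Q-table environment.
#' @param state integer action prefix (non-terminal).
#' @param action the action taken.
#' @param reward the received reward.
#' @param config an [RLConfig-class]; \code{alpha} and \code{gamma} are used.
#' @param n number of samples (determines whether the next state is
#'   terminal).
#' @return invisibly, the updated Q(s, a).
#' @export
qUpdate <- function(q, state, action, reward, config, n) {
  key <- .qkey(state)
  qs <- get0(key, envir = q, ifnotfound = NULL)
  if (is.null(qs)) qs <- numeric(n)
  maxnext <- 0
  if (length(state) + 1L < n) {
    qn <- get0(.qkey(c(state, action)), envir = q, ifnotfound = NULL)
    if (!is.null(qn)) maxnext <- max(qn)
  }
  qs[action] <- qs[action] +
    config@alpha * (reward + config@gamma * maxnext - qs[action])
  assign(key, qs, envir = q)
  invisible(qs[action])
}

## Deterministic greedy descent (lowest index on ties). Returns the integer
## permutation; restricted to unused actions, so always a permutation.
.greedy_extract <- function(q, n) {
  key <- "r"; used <- logical(n); ord <- integer(n)
  for (k in seq_len(n)) {
    cand <- which(!used)
    qs <- get0(key, envir = q, ifnotfound = NULL)
    vals <- if (is.null(qs)) numeric(length(cand)) else qs[cand]
    a <- cand[which.max(vals)]
    ord[k] <- a; used[a] <- TRUE
    key <- paste0(key, ",", a)
  }
  ord
}

#' Train the temporal-ordering agent
#'
#' Runs \code{config@episodes} root-to-terminal episodes. Each episode walks
#' the tree with [selectAction()] (random tie-breaking) and applies
#' [qUpdate()] at every step; path validity is tracked incrementally (the
#' successor-dominance constraint is equivalent to "each step picks an
#' arg-max of similarity over the remaining samples") and an invalid
#' terminal path receives the extra penalty of [stepReward()]. Every
#' \code{config@logEvery} episodes the current greedy solution's overall
#' similarity is recorded.
#'
#' @param similarity a [SampleSimilarity-class] object.
#' @param config an [RLConfig-class]; see [rlConfig()].
#' @return an [OrderingFit-class] object.
#' @examples
#' S <- orderingFixture("table2_similarity")
#' fit <- trainOrderingAgent(S, rlConfig(episodes = 2000, seed = 1))
#' extractSolution(fit)
#' @export
trainOrderingAgent <- function(similarity, config = rlConfig()) {
  stopifnot(is(similarity, "SampleSimilarity"), is(config, "RLConfig"))
  n <- nSamples(similarity)
  penalty <- .resolve_penalty(config, similarity)
  config2 <- rlConfig(config@alpha, config@gamma, config@epsilon,
                      config@episodes, penalty, config@seed, config@logEvery)
  if (!is.na(config@seed)) set.seed(config@seed)
  smat <- similarityMatrix(similarity)
  diag(smat) <- -Inf
  alpha <- config@alpha; gamma <- config@gamma; epsilon <- config@epsilon
  q <- new.env(hash = TRUE, parent = emptyenv())
  log_ep <- integer(0); log_sim <- numeric(0)
  sim_evals <- 0
  osim <- function(ord) sum(smat[cbind(ord[-n], ord[-1L])])
  for (ep in seq_len(config@episodes)) {
    key <- "r"; used <- logical(n); last <- 0L; path_valid <- TRUE
    for (k in seq_len(n)) {
      cand <- which(!used)
      a <- .step_select(key, last, cand, q, smat, epsilon, "random")
      r <- if (last == 0L) 0 else smat[last, a]
      if (last != 0L) {
        sim_evals <- sim_evals + length(cand)
        if (smat[last, a] < max(smat[last, cand])) path_valid <- FALSE
      }
      if (k == n && !path_valid) r <- r - penalty
      nextkey <- paste0(key, ",", a)
      qs <- get0(key, envir = q, ifnotfound = NULL)
      if (is.null(qs)) qs <- numeric(n)
      maxnext <- 0
      if (k < n) {
        qn <- get0(nextkey, envir = q, ifnotfound = NULL)
        if (!is.null(qn)) maxnext <- max(qn)
      }
      qs[a] <- qs[a] + alpha * (r + gamma * maxnext - qs[a])
      assign(key, qs, envir = q)
      used[a] <- TRUE; last <- a; key <- nextkey
    }
    if (ep %% config@logEvery == 0L) {
      log_ep <- c(log_ep, ep)
      log_sim <- c(log_sim, osim(.greedy_extract(q, n)))
    }
  }
  new("OrderingFit", q = q,
      log = data.frame(episode = log_ep, similarity = log_sim),
      config = config2, similarity = similarity, simEvals = sim_evals)
}

#' Extract the learned solution by greedy descent
#'
#' Starting from the root, repeatedly moves to the unused action of maximal
#' Q-value (lowest index on exact ties, so an untrained all-zero table
#' yields the identity ordering). The unused-action restriction guarantees a
#' permutation.
#'
#' @param fit an [OrderingFit-class], or a Q-table environment (then
#'   \code{similarity} is required).
#' @param similarity a [SampleSimilarity-class]; taken from \code{fit} when
#'   omitted.
#' @return a [SampleOrdering-class] annotated with its overall similarity
#'   and validity.
#' @export
extractSolution <- function(fit, similarity = NULL) {
  if (is(fit, "OrderingFit")) {
    q <- fit@q
    if (is.null(similarity)) similarity <- fit@similarity
  } else {
    stopifnot(is.environment(fit), is(similarity, "SampleSimilarity"))
    q <- fit
  }
  n <- nSamples(similarity)
  ord <- .greedy_extract(q, n)
  SampleOrdering(ord, ids = sampleIDs(similarity),
                 similarity = overallSimilarity(ord, similarity),
                 valid = isValidOrdering(ord, similarity))
}
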