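test_that("path successors list all n actions until the path is terminal", {
  expect_identical(pathSuccessors(integer(0), 10L), 1:10)
  expect_identical(pathSuccessors(c(3L, 1L), 4L), 1:4)
  expect_length(pathSuccessors(1:4, 4L), 0)
})

test_that("step rewards telescope to the overall similarity on valid paths", {
  S <- table2()
  cfg <- rlConfig()
  expect_equal(stepReward(c(6L), 3L, S, cfg), 7)
  expect_equal(stepReward(c(6L), 6L, S, cfg), -14)  # 2 * max sim = 14
  expect_equal(stepReward(integer(0), 6L, S, cfg), 0)
  total <- 0
  for (k in seq_along(optimum10))
    total <- total + stepReward(optimum10[seq_len(k - 1)], optimum10[k], S, cfg)
  expect_equal(total, 53.01)
  # an invalid distinct-action terminal path pays the extra penalty
  p <- c(2L, 4L, 8L, 1L, 9L, 7L, 5L, 10L, 3L, 6L)  # reverse of the optimum
  total <- 0
  for (k in seq_along(p))
    total <- total + stepReward(p[seq_len(k - 1)], p[k], S, cfg)
  expect_equal(total, overallSimilarity(p, S) - 14)
})

test_that("selectAction follows the documented branches and tie rules", {
  S <- table2()
  q <- new.env(parent = emptyenv())
  # epsilon = 0: pure look-ahead, most similar unused sample to S6 is S3
  a <- selectAction(c(6L), q, S, rlConfig(epsilon = 0))
  expect_identical(a, 3L)
  # all Q equal with the deterministic rule: lowest index
  expect_identical(
    selectAction(integer(0), q, S, rlConfig(epsilon = 1), ties = "first"), 1L)
  # used actions are excluded
  set.seed(1)
  picks <- replicate(50, selectAction(c(1L, 2L, 3L), q, S, rlConfig()))
  expect_true(all(picks %in% 4:10))
  # fixed seed reproduces the sequence
  set.seed(99); s1 <- replicate(20, selectAction(integer(0), q, S, rlConfig()))
  set.seed(99); s2 <- replicate(20, selectAction(integer(0), q, S, rlConfig()))
  expect_identical(s1, s2)
})

test_that("qUpdate implements the Q-learning rule", {
  S <- randomSimilarity(3, seed = 5)
  q <- new.env(parent = emptyenv())
  # alpha = 1, gamma = 0: Q(s, a) = reward
  qUpdate(q, integer(0), 2L, 4.5, rlConfig(alpha = 1, gamma = 1e-9), 3L)
  expect_equal(get("r", q)[2], 4.5, tolerance = 1e-8)
  # alpha -> 0: (numerically) unchanged
  before <- get("r", q)
  qUpdate(q, integer(0), 2L, 100, rlConfig(alpha = 1e-12), 3L)
  expect_equal(get("r", q), before, tolerance = 1e-9)
})

test_that("repeated sweeps converge to the analytic fixed point (2-sample tree)", {
  # n = 2, one off-diagonal similarity s. Fixed point of the update rule:
  #   Q((i), j != i) = s          (terminal reward, no successors)
  #   Q((i), i)      = -penalty   (repeat punishment)
  #   Q(root, i)     = gamma * s  (root reward 0 + discounted child value)
  s_val <- 3.5
  m <- matrix(c(NA, s_val, s_val, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  S <- SampleSimilarity(m)
  cfg <- rlConfig(alpha = 0.5, gamma = 0.9, invalidPenalty = 7)
  q <- new.env(parent = emptyenv())
  for (sweep in 1:40) {
    for (first in 1:2) {
      for (second in 1:2) {
        qUpdate(q, c(first), second,
                stepReward(c(first), second, S, cfg), cfg, 2L)
      }
      qUpdate(q, integer(0), first,
              stepReward(integer(0), first, S, cfg), cfg, 2L)
    }
  }
  expect_equal(get("r,1", q), c(-7, s_val), tolerance = 1e-3)
  expect_equal(get("r,2", q), c(s_val, -7), tolerance = 1e-3)
  expect_equal(get("r", q), rep(0.9 * s_val, 2), tolerance = 1e-3)
})

test_that("a manual episode loop with the exported operations replays training", {
  S <- randomSimilarity(4, seed = 8)
  n <- nSamples(S)
  cfg <- rlConfig(episodes = 5L, seed = 123L, invalidPenalty = 10)
  fit <- trainOrderingAgent(S, cfg)
  q <- new.env(parent = emptyenv())
  set.seed(123)
  for (ep in 1:5) {
    state <- integer(0)
    for (k in 1:n) {
      a <- selectAction(state, q, S, cfg)
      r <- stepReward(state, a, S, cfg)
      qUpdate(q, state, a, r, cfg, n)
      state <- c(state, a)
    }
  }
  expect_setequal(ls(fit@q), ls(q))
  for (key in ls(q))
    expect_equal(get(key, q), get(key, fit@q), tolerance = 0)
})

test_that("training is deterministic under a fixed seed", {
  S <- table2()
  cfg <- rlConfig(episodes = 600L, seed = 7L)
  f1 <- trainOrderingAgent(S, cfg)
  f2 <- trainOrderingAgent(S, cfg)
  expect_identical(trainingLog(f1), trainingLog(f2))
  expect_identical(orderingIndices(extractSolution(f1)),
                   orderingIndices(extractSolution(f2)))
})

test_that("zero episodes give an empty log and an untrained table", {
  S <- randomSimilarity(5, seed = 2)
  fit <- trainOrderingAgent(S, rlConfig(episodes = 0L, seed = 1L))
  expect_identical(nrow(trainingLog(fit)), 0L)
  expect_length(ls(fit@q), 0)
  # greedy extraction from an all-zero table: identity via the tie-break
  expect_identical(orderingIndices(extractSolution(fit)), 1:5)
})

test_that("greedy log converges: final value dominates the early phase", {
  S <- table2()
  for (seed in 1:5) {
    fit <- trainOrderingAgent(S, rlConfig(seed = seed))
    log <- trainingLog(fit)
    early <- log$similarity[seq_len(ceiling(nrow(log) * 0.1))]
    expect_gte(log$similarity[nrow(log)], max(early))
  }
})

test_that("per-episode work scales quadratically in the sample count", {
  evals <- vapply(c(4L, 8L, 16L), function(n) {
    fit <- trainOrderingAgent(randomSimilarity(n, seed = n),
                              rlConfig(episodes = 200L, seed = 1L))
    fit@simEvals / 200
  }, numeric(1))
  # validity scanning visits each remaining candidate once per step:
  # exactly n (n - 1) / 2 similarity evaluations per episode
  expect_equal(evals, c(4 * 3, 8 * 7, 16 * 15) / 2)
  expect_gt(evals[3] / evals[2], 2)   # clearly super-linear
  expect_lt(evals[3] / evals[2], 8)   # and no worse than quadratic-ish
})

test_that("solve matches the exhaustive oracle on small random instances", {
  hits <- 0L
  trials <- 20L
  for (seed in seq_len(trials)) {
    S <- randomSimilarity(4 + (seed %% 5), seed = 1000 + seed)
    oracle <- bestValidOrderings(S, includeReversed = FALSE)
    res <- orderSamples(S, config = rlConfig(seed = seed))
    sol <- res$ordering
    expect_lte(sol@similarity, bestSimilarity(oracle) + 1e-9)
    if (abs(sol@similarity - bestSimilarity(oracle)) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.9)
})

test_that("single-sample inputs are refused end to end", {
  x <- matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "S1"))
  expect_error(orderSamples(x), class = "chronoq_input_error")
})
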