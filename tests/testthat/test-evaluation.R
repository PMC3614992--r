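test_that("SMD reproduces every published score of the benchmark orderings", {
  t4 <- orderingFixture("table4_orderings")
  expect_length(t4, 10)
  for (nm in names(t4)) {
    en <- t4[[nm]]
    expect_identical(smdValue(smd(en$rl, en$times)), en$rl_smd,
                     label = paste(nm, "recovered"))
    expect_identical(smdValue(smd(en$literature, en$times)),
                     en$literature_smd,
                     label = paste(nm, "literature"))
  }
})

test_that("SMD flags the expected positions in the worked cases", {
  hs <- orderingFixture("table3_timepoints")$heat_shock
  expect_identical(smdValue(smd(1:8, hs)), 0L)
  res <- smd(c(1, 8, 7, 6, 5, 4, 3, 2), hs)
  expect_identical(smdValue(res), 2L)
  # the spike at position 2 and the non-extreme final sample
  expect_identical(which(misplacedSamples(res)), c(2L, 8L))
})

test_that("correct orderings and their reverses score zero", {
  for (seed in 1:10) {
    n <- sample(3:12, 1)
    set.seed(seed)
    times <- sort(runif(n, 0, 100)) + seq_len(n) * 1e-6  # strictly increasing
    expect_identical(smdValue(smd(seq_len(n), times)), 0L)
    expect_identical(smdValue(smd(rev(seq_len(n)), times)), 0L)
    # and any permutation stays within [0, n]
    p <- sample(n)
    v <- smdValue(smd(p, times))
    expect_gte(v, 0L); expect_lte(v, n)
  }
})

test_that("SMD is invariant to strictly increasing time transformations", {
  times <- orderingFixture("table3_timepoints")$nitrogen_depletion
  p <- c(4, 3, 2, 1, 5, 6, 7, 8, 9, 10)
  base <- smd(p, times)
  for (f in list(function(t) t^2, function(t) log1p(t),
                 function(t) 1000 + 3 * t)) {
    tr <- smd(p, f(times))
    expect_identical(smdValue(tr), smdValue(base))
    expect_identical(misplacedSamples(tr), misplacedSamples(base))
  }
})

test_that("SMD input validation", {
  expect_error(smd(1L, 5), class = "chronoq_input_error")
  ord <- SampleOrdering(1:3, ids = c("a", "b", "c"))
  expect_error(smd(ord, c(a = 1, b = 2)), class = "chronoq_input_error")
})

test_that("orientation picks the time-concordant direction", {
  times <- c(S1 = 10, S2 = 20, S3 = 30, S4 = 40)
  inc <- SampleOrdering(1:4, ids = names(times))
  dec <- SampleOrdering(4:1, ids = names(times))
  expect_identical(orderingIndices(orientOrdering(inc, times)), 1:4)
  expect_identical(orderingIndices(orientOrdering(dec, times)), 1:4)
  # survival convention: decreasing times along the sequence
  expect_identical(orderingIndices(orientOrdering(inc, times, "decreasing")),
                   4:1)
  # exact tie leaves the input unchanged
  tied <- c(S1 = 1, S2 = 2, S3 = 2, S4 = 1)
  expect_identical(orderingIndices(orientOrdering(inc, tied)), 1:4)
})

test_that("half averages split the ordering at ceiling(n/2)", {
  times <- c(S1 = 10, S2 = 20, S3 = 30, S4 = 40)
  ha <- halfAverages(SampleOrdering(1:4, ids = names(times)), times)
  expect_equal(ha, c(left = 15, right = 35))
  ha_rev <- halfAverages(SampleOrdering(4:1, ids = names(times)), times)
  expect_equal(ha_rev, c(left = 35, right = 15))
  # odd n: left half takes the middle element
  t5 <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(halfAverages(SampleOrdering(1:5, ids = names(t5)), t5),
               c(left = 2, right = 4.5))
})

test_that("an oriented cancer-like simulation has higher left-half survival", {
  sim <- simulateTemporalExpression(nSamples = 10, nGenes = 200,
                                    fractionInformative = 0.25,
                                    noiseSD = 0.2,
                                    survivalDirection = "decreasing",
                                    seed = 31)
  truth <- sim$ordering
  oriented <- orientOrdering(truth, sim$times, direction = "decreasing")
  ha <- halfAverages(oriented, sim$times)
  expect_gt(ha["left"], ha["right"])
})
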