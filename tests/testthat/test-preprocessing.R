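test_that("genes with missing values are removed, survivors in order", {
  x <- matrix(1, 5, 3, dimnames = list(paste0("g", 1:5), paste0("S", 1:3)))
  x[3, 2] <- NA
  y <- removeIncompleteGenes(x)
  expect_identical(rownames(y), paste0("g", c(1, 2, 4, 5)))
  x2 <- matrix(rnorm(6), 2, 3,
               dimnames = list(c("a", "b"), paste0("S", 1:3)))
  expect_identical(removeIncompleteGenes(x2), x2)
  x2[1, 1] <- NA; x2[2, 3] <- NA
  expect_error(removeIncompleteGenes(x2), class = "chronoq_empty_result")
})

test_that("pearsonCorrelation matches the textbook cases", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(pearsonCorrelation(0:3, rep(1, 4))))
  expect_error(pearsonCorrelation(1:3, 1:4), class = "chronoq_input_error")
  expect_error(pearsonCorrelation(1, 1), class = "chronoq_input_error")
  # r(x, a x + b) = sign(a) for a != 0
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(8)
    a <- runif(1, -4, 4)
    if (abs(a) < 1e-3) a <- 1
    expect_equal(pearsonCorrelation(x, a * x + runif(1)), sign(a),
                 tolerance = 1e-12)
  }
})

test_that("time-correlation filter keeps exactly the |r| > t genes", {
  times <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4, S5 = 5)
  x <- rbind(perfect = 1:5,
             constant = rep(2, 5),
             anti = 5:1,
             weak = c(1, 5, 2, 4, 3))
  colnames(x) <- names(times)
  res <- filterGenesByTimeCorrelation(x, times, 0.6)
  expect_setequal(res$report$keptGeneIDs, c("perfect", "anti"))
  expect_true(is.na(res$report$correlations["constant"]))
  expect_identical(res$report$droppedLowCorrelation, 2L)
  x_weak <- x[c("constant", "weak"), , drop = FALSE]
  expect_error(filterGenesByTimeCorrelation(x_weak, times, 0.6),
               class = "chronoq_empty_result")
})

test_that("filter counts missing-dropped genes and satisfies the ledger identity", {
  times <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4)
  x <- rbind(a = 1:4, b = c(NA, 2, 3, 4), c = 4:1, d = c(2, 2, 2, 2))
  colnames(x) <- names(times)
  res <- filterGenesByTimeCorrelation(x, times, 0.6)
  rep <- res$report
  expect_identical(rep$droppedMissing, 1L)
  expect_identical(length(rep$keptGeneIDs) + rep$droppedMissing +
                     rep$droppedLowCorrelation, nrow(x))
})

test_that("filter separates informative from noise genes on simulated data", {
  sim <- simulateTemporalExpression(nSamples = 10, nGenes = 500,
                                    fractionInformative = 0.1,
                                    noiseSD = 0.5, seed = 42)
  res <- filterGenesByTimeCorrelation(sim$expression, sim$times, 0.6)
  kept <- res$report$keptGeneIDs
  # independent check: brute-force per-gene correlation with cor()
  tv <- sim$times[colnames(sim$expression)]
  r <- apply(sim$expression, 1, function(g)
    suppressWarnings(cor(g, tv)))
  expect_setequal(kept, rownames(sim$expression)[!is.na(r) & abs(r) > 0.6])
  inf <- sim$informative
  noise <- setdiff(rownames(sim$expression), inf)
  expect_gt(mean(inf %in% kept), 0.6)
  expect_lt(mean(noise %in% kept), 0.1)
})

test_that("filtering is idempotent and monotone in the threshold", {
  sim <- simulateTemporalExpression(nSamples = 8, nGenes = 120,
                                    fractionInformative = 0.3,
                                    noiseSD = 0.4, seed = 11)
  res <- filterGenesByTimeCorrelation(sim$expression, sim$times, 0.6)
  again <- filterGenesByTimeCorrelation(res$matrix, sim$times, 0.6)
  expect_identical(again$matrix, res$matrix)
  kept_at <- function(t)
    tryCatch(filterGenesByTimeCorrelation(sim$expression, sim$times,
                                          t)$report$keptGeneIDs,
             chronoq_empty_result = function(e) character(0))
  thresholds <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  sets <- lapply(thresholds, kept_at)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})
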