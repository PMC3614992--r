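# Shared helpers: small instances built in code, independent oracles.

table2 <- function() orderingFixture("table2_similarity")
table1 <- function() orderingFixture("table1_survival")

# The certified optimum of the bundled 10-sample benchmark (survival-sorted).
optimum10 <- c(6L, 3L, 10L, 5L, 7L, 9L, 1L, 8L, 4L, 2L)

# Random symmetric similarity instance; values on a coarse grid so that
# exact ties occur and tie-handling is exercised.
randomSimilarity <- function(n, seed, grid = seq(1, 9, by = 0.5)) {
  set.seed(seed)
  s <- matrix(0, n, n)
  vals <- sample(grid, n * (n - 1) / 2, replace = TRUE)
  s[upper.tri(s)] <- vals
  s <- s + t(s)
  ids <- paste0("S", seq_len(n))
  dimnames(s) <- list(ids, ids)
  SampleSimilarity(s)
}

# Independent reference for the ordering objective: naive loop.
simOfOrdering <- function(perm, S) {
  m <- similarityMatrix(S)
  total <- 0
  for (i in seq_len(length(perm) - 1)) total <- total + m[perm[i], perm[i + 1]]
  total
}

# Independent validity check: literal double loop over the definition.
validByDefinition <- function(perm, S) {
  m <- similarityMatrix(S)
  n <- length(perm)
  for (i in seq_len(max(n - 2, 0))) {
    for (j in (i + 2):n) {
      if (m[perm[i], perm[i + 1]] < m[perm[i], perm[j]]) return(FALSE)
    }
  }
  TRUE
}

permKey <- function(p) paste(p, collapse = ",")
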