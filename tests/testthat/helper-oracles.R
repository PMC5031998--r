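# Shared fixtures and independent oracles used across test files.

# brute-force kNN: all-pairs sort, majority vote with equal class weights,
# distance ties broken by training index, vote ties -> IRR
bruteKNN <- function(trainX, trainY, query, k) {
  d <- sqrt(colSums((t(trainX) - query)^2))
  nb <- order(d, seq_along(d))[seq_len(k)]
  votes <- table(factor(trainY[nb], levels = c("IRR", "NonIRR")))
  if (votes[["IRR"]] >= votes[["NonIRR"]]) "IRR" else "NonIRR"
}

# brute-force Sens+Spec threshold scan over a dense grid
gridThresholdMax <- function(t, y, nGrid = 10001) {
  grid <- seq(min(t) - 1, max(t) + 1, length.out = nGrid)
  max(vapply(grid, function(th)
    100 * mean(t[y == "IRR"] > th) + 100 * mean(t[y == "NonIRR"] <= th),
    numeric(1)))
}

# random labelled feature data with both classes guaranteed
randomFeatures <- function(n, d, shift = 1) {
  y <- c("IRR", "NonIRR", sample(c("IRR", "NonIRR"), n - 2, replace = TRUE))
  X <- matrix(rnorm(n * d), n, d) + shift * (y == "IRR")
  list(X = X, y = y)
}

# small fast synthetic dataset for pipeline tests
smallEEMSet <- function(nIrr = 8, nNonIrr = 7, grid = 16, seed = 7, ...) {
  generateEEMSet(generatorConfig(nIrr = nIrr, nNonIrr = nNonIrr,
                                 gridSize = grid, seed = seed, ...))
}

# relabel an EEMSet (for permutation tests); order of samples unchanged
relabelEEMSet <- function(eset, newLabels) {
  samples <- lapply(seq_len(ncol(eset)), function(i) {
    s <- getSample(eset, i)
    CompoundSample(s@compoundId, newLabels[i], s@control, s@cells)
  })
  EEMSet(samples)
}
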