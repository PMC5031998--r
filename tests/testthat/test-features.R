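test_that("task vectorization has the documented lengths and order", {
  fx <- tinyFixture()
  s <- getSample(fx, 1)
  expect_length(vectorizeSample(s, 1), 25)
  expect_length(vectorizeSample(s, 2), 25)
  v3 <- vectorizeSample(s, 3)
  expect_length(v3, 50)
  # control first, then with-cells; row-major in the rows = emission layout
  expect_equal(v3[1:25], as.vector(t(s@control@intensities)))
  expect_equal(v3[26:50], as.vector(t(s@cells@intensities)))
})

test_that("standardizeVector gives zero mean, unit norm, affine invariance", {
  set.seed(1)
  v <- rnorm(40)
  s <- standardizeVector(v)
  expect_equal(mean(s), 0, tolerance = 1e-14)
  expect_equal(sum(s^2), 1, tolerance = 1e-12)
  expect_equal(standardizeVector(3.7 * v + 11), s, tolerance = 1e-12)
  expect_error(standardizeVector(rep(2, 10)), "constant")
})

test_that("correlationVector reproduces Pearson correlation", {
  expect_equal(correlationVector(c(1, 2, 3),
                                 rbind(standardizeVector(c(1, 3, 2)))), 0.5)
  set.seed(2)
  v <- rnorm(30)
  refsRaw <- replicate(4, rnorm(30))
  refs <- t(apply(refsRaw, 2, standardizeVector))
  expect_equal(correlationVector(v, refs),
               as.numeric(cor(v, refsRaw)), tolerance = 1e-12)
  expect_equal(correlationVector(v, rbind(standardizeVector(v))), 1)
  expect_equal(correlationVector(v, rbind(standardizeVector(-v))), -1)
  expect_error(correlationVector(v, refs[, 1:10]), "length mismatch")
})

test_that("correlation embedding is the squared-distance embedding (r = 1 - d2/2)", {
  # canonical cases: identical (d2=0, r=1), orthogonal (d2=2, r=0),
  # antipodal (d2=4, r=-1)
  a <- standardizeVector(c(1, 2, 3, 4))
  b <- standardizeVector(c(4, 1, 2, 3))
  expect_equal(correlationDistanceCheck(rbind(a, a)), 0, tolerance = 1e-15)
  expect_lt(correlationDistanceCheck(rbind(a, b, -a)), 1e-14)
  set.seed(3)
  V <- t(apply(matrix(rnorm(20 * 50), 20), 1, standardizeVector))
  expect_lt(correlationDistanceCheck(V), 1e-10)
})

test_that("Kaiser rule counts eigenvalues strictly above 1", {
  expect_equal(kaiserSelect(c(2.5, 1.2, 0.8, 0.5)), 2)
  expect_equal(kaiserSelect(c(1, 1, 1)), 0)
  expect_equal(kaiserSelect(5.0), 1)
  expect_error(kaiserSelect(numeric(0)), "empty")
})

test_that("broken-stick expectations are exact, normalized, decreasing", {
  expect_equal(brokenStickExpectation(1), 1)
  expect_equal(brokenStickExpectation(3), c(11, 5, 2) / 18)
  for (n in c(2, 4, 7, 25)) {
    b <- brokenStickExpectation(n)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(diff(b) < 0))
  }
})

test_that("broken-stick expectation matches simulated stick breaking", {
  # Monte-Carlo oracle: mean sorted piece lengths of random unit-stick breaks
  set.seed(4)
  n <- 4; B <- 20000
  cuts <- matrix(runif(B * (n - 1)), B)
  pieces <- t(apply(cbind(0, cuts, 1), 1, function(r) sort(diff(sort(r)),
                                                           decreasing = TRUE)))
  mc <- colMeans(pieces)
  se <- apply(pieces, 2, sd) / sqrt(B)
  expect_true(all(abs(mc - brokenStickExpectation(n)) < 3 * se))
})

test_that("broken-stick selection takes the maximal leading run (strict)", {
  expect_equal(brokenStickSelect(c(0.70, 0.20, 0.10)), 1)
  b <- brokenStickExpectation(4)
  expect_equal(brokenStickSelect(b), 0)            # ties reject
  # b(4) = (0.5208, 0.2708, 0.1458, 0.0625): run of 2 before the first failure
  expect_equal(brokenStickSelect(c(0.60, 0.28, 0.08, 0.04)), 2)
  expect_error(brokenStickSelect(c(0, 0)), "positive sum")
})

test_that("fitExtractor produces orthonormal, decorrelating, self-consistent scores", {
  fx <- tinyFixture()
  ext <- fitExtractor(fx, task = 2, rule = "fixed", nComponents = 2)
  expect_equal(ext@nRetained, 2L)
  # eigenvalue sum = trace of a correlation matrix = n training samples
  expect_equal(sum(ext@eigenvalues), 6, tolerance = 1e-10)
  # loadings orthonormality
  G <- crossprod(ext@loadings)
  expect_lt(max(abs(G - diag(2))), 1e-10)
  # training scores decorrelate with variances = top eigenvalues
  S <- extractFeatures(ext, fx)
  expect_equal(unname(cov(S)), diag(ext@eigenvalues[1:2]), tolerance = 1e-10)
  # transform() on training samples reproduces the training rows
  for (i in 1:6)
    expect_lt(max(abs(extractFeatures(ext, getSample(fx, i)) - S[i, ])), 1e-8)
  # retention floor: never less than one component
  extBS <- fitExtractor(fx, task = 2, rule = "broken_stick")
  expect_gte(extBS@nRetained, 1L)
  extK <- fitExtractor(fx, task = 2, rule = "kaiser")
  expect_equal(extK@nRetained, sum(extK@eigenvalues > 1))
})

test_that("features are invariant to per-image affine intensity changes", {
  fx <- tinyFixture()
  ext <- fitExtractor(fx, task = 3, rule = "fixed", nComponents = 3)
  s <- getSample(fx, 2)
  scaled <- CompoundSample(s@compoundId, s@label,
    EEMImage(2 * s@control@intensities + 5, s@control@excitation, s@control@emission),
    EEMImage(2 * s@cells@intensities + 5, s@cells@excitation, s@cells@emission))
  expect_equal(extractFeatures(ext, scaled), extractFeatures(ext, s),
               tolerance = 1e-10)
  bad <- getSample(smallEEMSet(2, 2, grid = 9), 1)
  expect_error(extractFeatures(ext, bad), "grid")
})

test_that("PCA scores from correlation and squared-distance embeddings agree up to sign", {
  fx <- tinyFixture()
  ext <- fitExtractor(fx, task = 2, rule = "fixed", nComponents = 3)
  corScores <- extractFeatures(ext, fx)
  # independent route: embed as squared distances d2 = 2 - 2r, then the same
  # column standardization + PCA
  V <- vapply(1:6, function(i) vectorizeSample(getSample(fx, i), 2), numeric(25))
  X <- t(apply(V, 2, standardizeVector))
  D2 <- as.matrix(dist(X))^2
  Z <- scale(D2)
  eig <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  distScores <- Z %*% eig$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(unname(distScores[, j])), abs(unname(corScores[, j])),
                 tolerance = 1e-8)
})

test_that("mask route equals the transform route and has the right shapes", {
  eset <- smallEEMSet(nIrr = 6, nNonIrr = 5, grid = 12, seed = 21)
  for (task in c(2, 3)) {
    ext <- fitExtractor(eset[, 1:8], task, rule = "fixed", nComponents = 4)
    m <- computeMasks(ext)
    expect_length(m$masks, 4)
    expectedRows <- if (task == 3) 24 else 12
    expect_equal(nrow(m$masks[[1]]), expectedRows)
    F <- extractFeatures(ext, eset)
    for (i in 9:11) {  # held-out samples
      s <- getSample(eset, i)
      expect_lt(max(abs(applyMasks(m, s) - F[i, ])), 1e-8)
    }
  }
})

test_that("extractor serialization round trips through text files", {
  fx <- tinyFixture()
  ext <- fitExtractor(fx, task = 3, rule = "fixed", nComponents = 2)
  dir <- withr::local_tempdir()
  saveExtractor(ext, dir)
  back <- loadExtractor(dir)
  expect_equal(back@task, ext@task)
  expect_equal(back@nRetained, ext@nRetained)
  expect_equal(back@refVectors, ext@refVectors)
  expect_equal(back@loadings, ext@loadings)
  expect_equal(extractFeatures(back, getSample(fx, 5)),
               extractFeatures(ext, getSample(fx, 5)))
})
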