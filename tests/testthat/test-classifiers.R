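test_that("Fisher direction matches the closed form and orients toward IRR", {
  # classes arranged so the pooled covariance is proportional to the identity
  offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(sweep(offsets, 2, c(1, 0), "+"), sweep(offsets, 2, c(-1, 0), "+"))
  y <- rep(c("IRR", "NonIRR"), each = 4)
  m <- fitFisher(X, y)
  expect_equal(m@w, c(1, 0), tolerance = 1e-12)
  expect_equal(sum(m@w^2), 1, tolerance = 1e-12)

  # random data: w proportional to solve(S_pooled, mu_I - mu_N)
  set.seed(10)
  rf <- randomFeatures(30, 4)
  m2 <- fitFisher(rf$X, rf$y)
  SI <- cov(rf$X[rf$y == "IRR", ]); SN <- cov(rf$X[rf$y == "NonIRR", ])
  nI <- sum(rf$y == "IRR"); nN <- sum(rf$y == "NonIRR")
  S <- ((nI - 1) * SI + (nN - 1) * SN) / (nI + nN - 2)
  wRef <- solve(S, colMeans(rf$X[rf$y == "IRR", ]) - colMeans(rf$X[rf$y == "NonIRR", ]))
  expect_equal(m2@w, as.numeric(wRef / sqrt(sum(wRef^2))), tolerance = 1e-10)
})

test_that("Fisher threshold is the midpoint maximizer of Sens+Spec", {
  # separable 1-D projections IRR {2,3}, NonIRR {-1,0}: theta = 1.0
  X <- matrix(c(2, 3, -1, 0), ncol = 1)
  y <- c("IRR", "IRR", "NonIRR", "NonIRR")
  m <- fitFisher(X, y)
  expect_equal(m@threshold, 1.0)
  pr <- predictLabels(m, X)
  expect_equal(as.character(pr$label), y)
  # predict agrees with sign(<w, x> - theta)
  expect_equal(pr$score, as.numeric(X %*% m@w) - m@threshold)

  # optimality against a dense grid-scan oracle on random data
  set.seed(11)
  for (rep in 1:10) {
    rf <- randomFeatures(20 + rep, 3, shift = runif(1, 0, 2))
    m <- fitFisher(rf$X, rf$y)
    t <- as.numeric(rf$X %*% m@w)
    achieved <- 100 * mean(t[rf$y == "IRR"] > m@threshold) +
      100 * mean(t[rf$y == "NonIRR"] <= m@threshold)
    expect_gte(achieved, gridThresholdMax(t, rf$y) - 1e-9)
  }
  expect_error(fitFisher(matrix(1:4, ncol = 1), rep("IRR", 4)), "both classes")
})

test_that("kNN vote arithmetic follows kernel times class weight", {
  # query at origin; neighbours NonIRR (d=1), NonIRR (d=2), IRR (d=3);
  # uniform kernel, weights 0.45/0.55: NonIRR wins 0.90 > 0.55
  X <- matrix(c(1, 2, 3, 100), ncol = 1)
  y <- c("NonIRR", "NonIRR", "IRR", "IRR")
  m <- fitKNN(X, y, k = 3, distance = "euclidean", kernel = "uniform",
              weightNonIrr = 0.45)
  pr <- predictLabels(m, matrix(0))
  expect_equal(as.character(pr$label), "NonIRR")
  expect_equal(pr$score, 0.55 - 0.90)

  # all three nearest IRR -> IRR regardless of config
  y2 <- c("IRR", "IRR", "IRR", "NonIRR")
  for (kern in c("uniform", "triangular")) {
    m2 <- fitKNN(X, y2, k = 3, distance = "adaptive", kernel = kern,
                 weightNonIrr = 0.45)
    expect_equal(as.character(predictLabels(m2, matrix(0))$label), "IRR")
  }

  # triangular kernel: neighbour at the normalization distance has zero weight
  X3 <- matrix(c(1, 2, 2), ncol = 1)
  y3 <- c("IRR", "NonIRR", "NonIRR")
  m3 <- fitKNN(X3, y3, k = 2, distance = "adaptive", kernel = "triangular",
               weightNonIrr = 0.45)
  # neighbours: IRR at u = 0.5 (weight 0.55 * 0.5), NonIRR at u = 1 (weight 0)
  expect_equal(predictLabels(m3, matrix(0))$score, 0.275)
  expect_error(fitKNN(X3, y3, k = 5), "k must be")
})

test_that("kNN with uniform kernel and equal weights matches the brute-force oracle", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(5:50, 1); d <- sample(1:5, 1); k <- sample(1:min(7, n), 1)
    rf <- randomFeatures(n, d, shift = runif(1, 0, 1.5))
    m <- fitKNN(rf$X, rf$y, k = k, distance = "euclidean", kernel = "uniform",
                weightNonIrr = 0.5)
    Q <- matrix(rnorm(3 * d), 3, d)
    got <- as.character(predictLabels(m, Q)$label)
    want <- vapply(1:3, function(q) bruteKNN(rf$X, rf$y, Q[q, ], k), "")
    expect_identical(got, want)
  }
  # 1NN on its own training set recovers the training labels
  rf <- randomFeatures(25, 3)
  m1 <- fitKNN(rf$X, rf$y, k = 1, distance = "euclidean", kernel = "uniform",
               weightNonIrr = 0.5)
  expect_identical(as.character(predictLabels(m1, rf$X)$label), rf$y)
})

test_that("naive Bayes splits symmetric 1-D classes at the midpoint and matches e1071", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(rep("NonIRR", 3), rep("IRR", 3))
  m <- fitNaiveBayes(X, y)
  expect_equal(as.character(predictLabels(m, matrix(c(-0.1, 0.1), ncol = 1))$label),
               c("NonIRR", "IRR"))
  # boundary tie at exactly 0 goes to IRR (fail-safe)
  expect_equal(as.character(predictLabels(m, matrix(0))$label), "IRR")

  set.seed(13)
  rf <- randomFeatures(40, 3)
  m2 <- fitNaiveBayes(rf$X, rf$y)
  ref <- e1071::naiveBayes(rf$X, factor(rf$y, levels = c("IRR", "NonIRR")))
  pRef <- predict(ref, rf$X, type = "raw")[, "IRR"]
  expect_equal(predictLabels(m2, rf$X)$score, unname(pRef), tolerance = 1e-6)
})

test_that("density classifiers produce complementary, order-invariant posteriors", {
  set.seed(14)
  rf <- randomFeatures(30, 2)
  swap <- ifelse(rf$y == "IRR", "NonIRR", "IRR")
  q <- matrix(rnorm(10 * 2), 10)
  m <- fitNaiveBayes(rf$X, rf$y)
  mSwap <- fitNaiveBayes(rf$X, swap)
  # P(IRR) under the swapped labelling is 1 - P(IRR): posteriors sum to one
  expect_equal(predictLabels(m, q)$score, 1 - predictLabels(mSwap, q)$score,
               tolerance = 1e-12)

  perm <- sample(nrow(rf$X))
  for (fitFun in list(fitNaiveBayes, fitPDFE,
                      function(X, y) fitGaussianMixture(X, y, modelNames = "XXX"))) {
    a <- predictLabels(fitFun(rf$X, rf$y), q)
    b <- predictLabels(fitFun(rf$X[perm, ], rf$y[perm]), q)
    expect_equal(a$score, b$score, tolerance = 1e-9)
  }
})

test_that("one-component Gaussian mixture equals a single full-covariance Gaussian", {
  set.seed(15)
  rf <- randomFeatures(40, 3)
  m <- fitGaussianMixture(rf$X, rf$y, G = 1, modelNames = "XXX")
  q <- matrix(rnorm(8 * 3), 8)
  # oracle: per-class Gaussian with MLE mean/covariance (denominator n)
  logd <- function(P, x) {
    mu <- colMeans(P); S <- cov(P) * (nrow(P) - 1) / nrow(P)
    -0.5 * (ncol(P) * log(2 * pi) + determinant(S)$modulus +
              stats::mahalanobis(x, mu, S))
  }
  lI <- logd(rf$X[rf$y == "IRR", ], q) + log(mean(rf$y == "IRR"))
  lN <- logd(rf$X[rf$y == "NonIRR", ], q) + log(mean(rf$y == "NonIRR"))
  want <- as.numeric(1 / (1 + exp(lN - lI)))
  expect_equal(predictLabels(m, q)$score, want, tolerance = 1e-8)
})

test_that("PDFE density matches the brute-force kernel sum and is positive at training points", {
  set.seed(16)
  rf <- randomFeatures(30, 2)
  m <- fitPDFE(rf$X, rf$y, kRadius = 5)
  PI <- m@points[["IRR"]]; hI <- m@bandwidths[["IRR"]]
  expect_equal(hI, vapply(seq_len(nrow(PI)), function(i)
    sort(sqrt(colSums((t(PI) - PI[i, ])^2))[-i])[min(5, nrow(PI) - 1)],
    numeric(1)), tolerance = 1e-12)
  # oracle: mean of products of univariate normal kernels (radial Gaussian)
  for (i in c(1, 7, 20)) {
    x <- rf$X[i, ]
    want <- mean(vapply(seq_len(nrow(PI)), function(j)
      prod(dnorm(x, PI[j, ], hI[j])), numeric(1)))
    got <- eemscreen:::.pdfeDensity(x, PI, hI, "gaussian")
    expect_equal(got, want, tolerance = 1e-10)
    expect_gt(got, 0)
  }
  # triangular kernel integrates to one in 1-D (normalizer check)
  h <- 0.8
  dens <- function(x) eemscreen:::.pdfeDensity(x, matrix(0), h, "triangular")
  grid <- seq(-1, 1, length.out = 2001) * h
  expect_equal(sum(vapply(grid, dens, numeric(1))) * diff(grid)[1], 1,
               tolerance = 1e-3)
  expect_error(fitPDFE(rf$X, rf$y, kRadius = 2), "between 5 and 30")
})

test_that("weighted logistic regression honours separability, priors and weights", {
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y <- c(rep("NonIRR", 3), rep("IRR", 3))
  m <- fitLogistic(X, y)
  expect_identical(as.character(predictLabels(m, X)$label), y)

  # all-zero features: posterior equals the weighted class prior
  X0 <- matrix(0, 10, 2)
  y0 <- rep(c("IRR", "NonIRR"), c(6, 4))
  for (w in c(0.3, 0.5)) {
    m0 <- fitLogistic(X0, y0, weightNonIrr = w)
    want <- (1 - w) * 6 / ((1 - w) * 6 + w * 4)
    expect_equal(predictLabels(m0, matrix(0, 1, 2))$score, want, tolerance = 1e-8)
  }

  # raising the Non-IRR weight shrinks the predicted IRR probability everywhere
  set.seed(17)
  rf <- randomFeatures(40, 2)
  pLo <- predictLabels(fitLogistic(rf$X, rf$y, weightNonIrr = 0.3), rf$X)$score
  pHi <- predictLabels(fitLogistic(rf$X, rf$y, weightNonIrr = 0.7), rf$X)$score
  expect_true(all(pHi <= pLo + 1e-9))
})

test_that("decision tree respects separability, impurity arithmetic and minLeaf", {
  X <- matrix(c(1, 2, 3, 10, 11, 12, rnorm(6)), ncol = 2)
  y <- rep(c("NonIRR", "IRR"), each = 3)
  m <- fitTree(X, y, minLeaf = 1)
  expect_identical(as.character(predictLabels(m, X)$label), y)
  expect_equal(nrow(m@fit$frame[m@fit$frame$var == "<leaf>", ]), 2)  # depth-1

  # Gini: 2 IRR | 2 NonIRR unsplit = 0.5; perfect split halves = 0
  expect_equal(eemscreen:::.gini(c("IRR", "IRR", "NonIRR", "NonIRR")), 0.5)
  expect_equal(eemscreen:::.gini(c("IRR", "IRR")), 0)

  mAll <- fitTree(X, y, minLeaf = 6)
  pr <- predictLabels(mAll, X)
  expect_equal(length(unique(as.character(pr$label))), 1)  # single leaf
})

test_that("the registry covers the report methods and refits deterministically", {
  set.seed(18)
  rf <- randomFeatures(24, 3)
  q <- matrix(rnorm(6 * 3), 6)
  for (m in c("DT", "GM", "3NN", "LDA", "LR", "PDFE", "NB")) {
    a <- predictLabels(fitClassifier(m, rf$X, rf$y), q)
    b <- predictLabels(fitClassifier(m, rf$X, rf$y), q)
    expect_identical(a, b, label = m)
    expect_true(all(as.character(a$label) %in% c("IRR", "NonIRR")), label = m)
  }
  expect_error(fitClassifier("SVM", rf$X, rf$y), "unknown method")
  # dimension mismatch is caught
  m <- fitClassifier("LDA", rf$X, rf$y)
  expect_error(predictLabels(m, matrix(0, 2, 5)), "mismatch")
})
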