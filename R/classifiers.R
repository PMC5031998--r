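# Classifier families in the retained feature space, under one fit/predict
# contract: fitClassifier(method, X, y) -> model; predictLabels(model, X) ->
# data.frame(label, score). IRR is the positive class throughout and larger
# scores mean "more irritant-like". Vote/posterior ties predict IRR
# (fail-safe toward flagging toxicity).

.asLabelChr <- function(y) {
  y <- as.character(y)
  if (!all(y %in% .CLASS_LEVELS))
    stop("labels must be 'IRR' or 'NonIRR'")
  y
}

.checkBothClasses <- function(y) {
  if (length(unique(y)) < 2) stop("both classes must be present in the training set")
}

.asRowMatrix <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(X))
  X <- as.matrix(X)
  if (ncol(X) != d)
    stop("feature count mismatch: model expects ", d, ", got ", ncol(X))
  X
}

.prediction <- function(isIrr, score) {
  data.frame(label = factor(ifelse(isIrr, "IRR", "NonIRR"), levels = .CLASS_LEVELS),
             score = as.numeric(score))
}

.classWeights <- function(weightNonIrr) {
  stopifnot(weightNonIrr > 0, weightNonIrr < 1)
  c(IRR = 1 - weightNonIrr, NonIRR = weightNonIrr)
}

# pooled within-class covariance, with optional ridge when singular
.pooledCov <- function(X, y, ridge = TRUE) {
  d <- ncol(X)
  S <- matrix(0, d, d)
  dof <- 0
  for (cl in unique(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) > 1) {
      S <- S + cov(Xc) * (nrow(Xc) - 1)
      dof <- dof + nrow(Xc) - 1
    }
  }
  if (dof == 0) stop("cannot estimate a pooled covariance from singleton classes")
  S <- S / dof
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    if (!ridge) stop("pooled within-class covariance is singular (ridge disabled)")
    S <- S + diag(1e-8 * sum(diag(S)) / d, d)
  }
  S
}

# ---------------------------------------------------------------- Fisher ----

#' Fit Fisher's linear discriminant with a Sens+Spec-maximizing threshold
#'
#' The direction is the classical `w = S_pooled^-1 (mu_IRR - mu_NonIRR)`
#' (unit-normalized, oriented so IRR projects higher). Because no normality
#' assumption is made for the threshold, it is chosen by exhaustive scan over
#' the midpoints of consecutive sorted training projections (plus one
#' candidate beyond each extreme), maximizing training Sensitivity +
#' Specificity; ties are broken toward the widest margin, then the smallest
#' threshold. Projections strictly above the threshold classify as IRR.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y labels (`"IRR"`/`"NonIRR"`).
#' @param ridge add a small ridge `1e-8 * trace(S)/d * I` if the pooled
#'   covariance is singular; with `ridge = FALSE` a singular covariance is an
#'   error.
#' @return a [FisherModel-class].
#' @export
fitFisher <- function(X, y, ridge = TRUE) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  S <- .pooledCov(X, y, ridge)
  muI <- colMeans(X[y == "IRR", , drop = FALSE])
  muN <- colMeans(X[y == "NonIRR", , drop = FALSE])
  w <- solve(S, muI - muN)
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(X %*% w)
  th <- .bestThreshold(t, y)
  new("FisherModel", w = as.numeric(w), threshold = th, positiveSide = "greater")
}

# Sens+Spec over candidate thresholds; candidates are midpoints of
# consecutive sorted unique projections plus one beyond each extreme.
.thresholdSum <- function(theta, t, y) {
  100 * mean(t[y == "IRR"] > theta) + 100 * mean(t[y == "NonIRR"] <= theta)
}

.bestThreshold <- function(t, y) {
  u <- sort(unique(t))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  gaps <- c(2, if (length(u) > 1) diff(u), 2)
  sums <- vapply(cands, .thresholdSum, numeric(1), t = t, y = y)
  best <- which(sums == max(sums))
  best <- best[order(-gaps[best], cands[best])][1]
  cands[best]
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "FisherModel", function(model, X) {
  X <- .asRowMatrix(X, length(model@w))
  s <- as.numeric(X %*% model@w) - model@threshold
  .prediction(s > 0, s)
})

# ------------------------------------------------------------------- kNN ----

#' Fit a weighted kernel k-nearest-neighbour classifier
#'
#' Neighbours are ranked by the configured distance; each of the k nearest
#' votes `kernel(d_i / d_(k+1)) * classWeight(label_i)` and the class with
#' the larger vote total wins (ties predict IRR). Distance ties are broken
#' by training-set order.
#'
#' Distances: `"euclidean"`; `"fisher_transformed"` (Euclidean after
#' whitening by the pooled within-class covariance, i.e. pooled Mahalanobis);
#' `"adaptive"` (query-local normalization of Euclidean distances by the
#' distance to the (k+1)-th neighbour, which puts the kernel argument on a
#' common [0, 1] scale -- our reading of the "adaptive distance"; it shares
#' the Euclidean neighbour ranking). The kernel argument is always the
#' normalized distance, so the triangular kernel is well-posed for every
#' distance choice and a neighbour exactly at the normalization distance
#' contributes zero weight. The recommended "advanced 3NN" configuration is
#' k = 3, adaptive distance, triangular kernel, Non-IRR class weight 0.45.
#'
#' @param X,y training features and labels.
#' @param k neighbourhood size (default 3), at most `nrow(X)`.
#' @param distance `"euclidean"`, `"adaptive"` or `"fisher_transformed"`.
#' @param kernel `"uniform"` or `"triangular"`.
#' @param weightNonIrr vote weight of Non-IRR in (0, 1); IRR gets 1 minus it.
#' @return a [KNNModel-class].
#' @export
fitKNN <- function(X, y, k = 3,
                   distance = c("euclidean", "adaptive", "fisher_transformed"),
                   kernel = c("uniform", "triangular"), weightNonIrr = 0.45) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  distance <- match.arg(distance); kernel <- match.arg(kernel)
  .classWeights(weightNonIrr)  # validates range
  if (k < 1 || k > nrow(X)) stop("k must be in [1, n_train]")
  W <- diag(ncol(X))
  if (distance == "fisher_transformed") {
    S <- .pooledCov(X, y, ridge = TRUE)
    es <- eigen(S, symmetric = TRUE)
    W <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)),
                             ncol(X)) %*% t(es$vectors)
  }
  new("KNNModel", trainX = X %*% W, trainY = y, k = as.integer(k),
      distance = distance, kernel = kernel,
      weightNonIrr = weightNonIrr, whitening = W)
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "KNNModel", function(model, X) {
  X <- .asRowMatrix(X, ncol(model@whitening)) %*% model@whitening
  cw <- .classWeights(model@weightNonIrr)
  k <- model@k
  n <- nrow(model@trainX)
  res <- lapply(seq_len(nrow(X)), function(q) {
    d <- sqrt(rowSums(sweep(model@trainX, 2, X[q, ])^2))
    ord <- order(d, seq_along(d))          # distance ties: training order
    nb <- ord[seq_len(k)]
    dnorm <- if (k < n) d[ord[k + 1]] else max(d[nb])
    u <- if (dnorm > 0) d[nb] / dnorm else rep(0, k)
    kw <- switch(model@kernel,
                 uniform = rep(1, k),
                 triangular = pmax(1 - u, 0))
    votes <- kw * cw[model@trainY[nb]]
    vI <- sum(votes[model@trainY[nb] == "IRR"])
    vN <- sum(votes[model@trainY[nb] == "NonIRR"])
    c(vI - vN)
  })
  s <- unlist(res)
  .prediction(s >= 0, s)
})

# -------------------------------------------------------------- logistic ----

#' Fit class-weighted logistic regression
#'
#' Maximizes the class-weighted binomial log-likelihood via iteratively
#' reweighted least squares (through [stats::glm]); each sample carries its
#' class weight. Constant feature columns are dropped from the fit.
#' Prediction thresholds the IRR posterior at 0.5.
#'
#' @param X,y training features and labels.
#' @param weightNonIrr weight of Non-IRR samples in (0, 1).
#' @param maxit IRLS iteration cap; non-convergence is an error (of class
#'   `eemscreen_nonconvergence`, carrying the last coefficient iterate).
#' @return a [LogisticModel-class].
#' @export
fitLogistic <- function(X, y, weightNonIrr = 0.5, maxit = 100) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  cw <- .classWeights(weightNonIrr)
  kept <- which(apply(X, 2, function(col) diff(range(col)) > 0))
  df <- as.data.frame(X[, kept, drop = FALSE])
  names(df) <- if (length(kept)) paste0("f", kept) else character(0)
  df$.y <- as.numeric(y == "IRR")
  wts <- unname(cw[y])
  fit <- suppressWarnings(glm(.y ~ ., data = df, weights = wts,
                              family = quasibinomial(),
                              control = list(maxit = maxit)))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  if (!fit$converged)
    stop(errorCondition(
      "logistic regression did not converge; last iterate attached as 'coef'",
      coef = beta, class = "eemscreen_nonconvergence"))
  new("LogisticModel", coef = unname(beta), keptCols = as.integer(kept),
      weightNonIrr = weightNonIrr)
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "LogisticModel", function(model, X) {
  X <- as.matrix(X)
  if (is.null(dim(X)) || ncol(X) < max(c(model@keptCols, 1L)))
    X <- .asRowMatrix(X, max(c(model@keptCols, 1L)))
  eta <- model@coef[1] +
    as.numeric(X[, model@keptCols, drop = FALSE] %*% model@coef[-1])
  p <- stats::plogis(eta)
  .prediction(p >= 0.5, p)
})

# ----------------------------------------------------------- naive Bayes ----

#' Fit a Gaussian naive Bayes classifier
#'
#' Standard version: per-class, per-feature Gaussian likelihoods with
#' empirical class priors. Zero variances are floored at `1e-9` times the
#' mean feature variance (with a message), keeping densities proper.
#'
#' @param X,y training features and labels.
#' @return a [NaiveBayesModel-class].
#' @export
fitNaiveBayes <- function(X, y) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  cls <- .CLASS_LEVELS
  means <- do.call(rbind, lapply(cls, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  vars <- do.call(rbind, lapply(cls, function(cl)
    apply(X[y == cl, , drop = FALSE], 2, var)))
  floorv <- 1e-9 * mean(apply(X, 2, var))
  if (!is.finite(floorv) || floorv <= 0) floorv <- 1e-12
  if (any(!is.finite(vars) | vars <= 0)) {
    message("naive Bayes: zero/undefined class variance floored")
    vars[!is.finite(vars) | vars <= floorv] <- floorv
  }
  priors <- prop.table(table(factor(y, levels = cls)))
  new("NaiveBayesModel", means = means, vars = vars,
      priors = setNames(as.numeric(priors), cls))
}

# shared posterior machinery for density-based classifiers:
# log-likelihood matrix (samples x 2 classes) + priors -> predictions
.posteriorPredict <- function(logLik, priors) {
  lp <- sweep(logLik, 2, log(priors), "+")
  keep <- is.finite(lp)
  post <- t(apply(lp, 1, function(r) {
    if (all(!is.finite(r))) return(priors / sum(priors))  # no density support
    m <- max(r[is.finite(r)])
    e <- ifelse(is.finite(r), exp(r - m), 0)
    e / sum(e)
  }))
  .prediction(post[, 1] >= post[, 2], post[, 1])
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "NaiveBayesModel", function(model, X) {
  X <- .asRowMatrix(X, ncol(model@means))
  ll <- vapply(1:2, function(ci) {
    per <- vapply(seq_len(ncol(X)), function(j)
      stats::dnorm(X[, j], model@means[ci, j], sqrt(model@vars[ci, j]), log = TRUE),
      numeric(nrow(X)))
    rowSums(matrix(per, nrow = nrow(X)))
  }, numeric(nrow(X)))
  .posteriorPredict(matrix(ll, ncol = 2), model@priors)
})

# ------------------------------------------------------- Gaussian mixture ----

#' Fit a per-class Gaussian mixture classifier
#'
#' Each class density is a Gaussian mixture fitted by EM
#' (via [mclust::densityMclust]); classification is by posterior
#' `prior x density`. The prior-correction mode selects empirical or equal
#' class priors.
#'
#' @param X,y training features and labels.
#' @param G mixture components per class (default 1).
#' @param priorMode `"empirical"` or `"equal"`.
#' @param modelNames optional mclust covariance model restriction
#'   (e.g. `"XXX"` for a single full-covariance Gaussian).
#' @return a [GaussianMixtureModel-class].
#' @export
fitGaussianMixture <- function(X, y, G = 1, priorMode = c("empirical", "equal"),
                               modelNames = NULL) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  priorMode <- match.arg(priorMode)
  dens <- lapply(.CLASS_LEVELS, function(cl)
    mclust::densityMclust(X[y == cl, , drop = FALSE], G = G,
                          modelNames = modelNames, plot = FALSE, verbose = FALSE))
  names(dens) <- .CLASS_LEVELS
  priors <- if (priorMode == "equal") c(IRR = 0.5, NonIRR = 0.5) else
    setNames(as.numeric(prop.table(table(factor(y, levels = .CLASS_LEVELS)))),
             .CLASS_LEVELS)
  new("GaussianMixtureModel", densities = dens, priors = priors)
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "GaussianMixtureModel", function(model, X) {
  d <- ncol(model@densities[["IRR"]]$data)
  X <- .asRowMatrix(X, d)
  ll <- vapply(.CLASS_LEVELS, function(cl)
    as.numeric(predict(model@densities[[cl]], newdata = X, what = "dens",
                       logarithm = TRUE)),
    numeric(nrow(X)))
  .posteriorPredict(matrix(ll, ncol = 2), model@priors)
})

# ------------------------------------------------------------------ PDFE ----

# radial kernel normalizing constant in d dimensions
.triangularConst <- function(d) d * (d + 1) * gamma(d / 2) / (2 * pi^(d / 2))

.pdfeDensity <- function(x, points, h, kernel) {
  d <- ncol(points)
  r <- sqrt(rowSums(sweep(points, 2, x)^2))
  k <- switch(kernel,
    gaussian = (2 * pi)^(-d / 2) * h^(-d) * exp(-r^2 / (2 * h^2)),
    triangular = .triangularConst(d) * h^(-d) * pmax(1 - r / h, 0))
  mean(k)
}

#' Fit a kernel PDF-estimation classifier (PDFE)
#'
#' Per-class kernel density with a per-training-point bandwidth equal to the
#' distance from that point to its `kRadius`-th nearest same-class neighbour
#' (the "radius of the neighbourhood"); each kernel integrates to one, so
#' the class density is proper. Classification is by posterior
#' `prior x density`; where both class densities vanish (possible with the
#' compact triangular kernel) the posterior falls back to the priors.
#'
#' @param X,y training features and labels.
#' @param kRadius neighbour count for the bandwidth, in [5, 30]
#'   (default 10), clipped to `n_class - 1`.
#' @param kernel `"gaussian"` (default) or `"triangular"`.
#' @param priorMode `"empirical"` or `"equal"`.
#' @return a [PDFEModel-class].
#' @export
fitPDFE <- function(X, y, kRadius = 10, kernel = c("gaussian", "triangular"),
                    priorMode = c("empirical", "equal")) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  kernel <- match.arg(kernel); priorMode <- match.arg(priorMode)
  if (kRadius < 5 || kRadius > 30) stop("kRadius must be between 5 and 30")
  pts <- lapply(.CLASS_LEVELS, function(cl) X[y == cl, , drop = FALSE])
  names(pts) <- .CLASS_LEVELS
  bw <- lapply(pts, function(P) {
    if (nrow(P) < 2) stop("PDFE needs at least 2 samples per class")
    k <- min(kRadius, nrow(P) - 1)
    D <- as.matrix(dist(P))
    h <- vapply(seq_len(nrow(P)), function(i) sort(D[i, -i])[k], numeric(1))
    pos <- h[h > 0]
    if (!length(pos)) stop("PDFE: all same-class neighbour distances are zero")
    h[h == 0] <- min(pos) * 1e-6
    h
  })
  priors <- if (priorMode == "equal") c(IRR = 0.5, NonIRR = 0.5) else
    setNames(as.numeric(prop.table(table(factor(y, levels = .CLASS_LEVELS)))),
             .CLASS_LEVELS)
  new("PDFEModel", points = pts, bandwidths = bw, kernel = kernel,
      priors = priors, kRadius = as.integer(kRadius))
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "PDFEModel", function(model, X) {
  X <- .asRowMatrix(X, ncol(model@points[["IRR"]]))
  ll <- vapply(.CLASS_LEVELS, function(cl)
    log(vapply(seq_len(nrow(X)), function(q)
      .pdfeDensity(X[q, ], model@points[[cl]], model@bandwidths[[cl]],
                   model@kernel), numeric(1))),
    numeric(nrow(X)))
  .posteriorPredict(matrix(ll, ncol = 2), model@priors)
})

# ------------------------------------------------------------------ tree ----

# Gini impurity of a label vector (used for split bookkeeping and tests)
.gini <- function(y) {
  p <- prop.table(table(y))
  1 - sum(p^2)
}

#' Fit a classification tree
#'
#' Greedy binary single-feature splits (via [rpart::rpart]) with the chosen
#' impurity criterion; every leaf holds at least `minLeaf` training samples
#' and leaves are labelled by majority.
#'
#' @param X,y training features and labels.
#' @param minLeaf minimal number of training samples per leaf (default 1).
#' @param criterion `"gini"` or `"entropy"`.
#' @return a [TreeModel-class].
#' @export
fitTree <- function(X, y, minLeaf = 1, criterion = c("gini", "entropy")) {
  X <- as.matrix(X); y <- .asLabelChr(y); .checkBothClasses(y)
  criterion <- match.arg(criterion)
  if (minLeaf < 1) stop("minLeaf must be >= 1")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- factor(y, levels = .CLASS_LEVELS)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
    parms = list(split = if (criterion == "gini") "gini" else "information"),
    control = rpart::rpart.control(minsplit = max(2, 2 * minLeaf),
                                   minbucket = minLeaf, cp = 0, xval = 0,
                                   maxcompete = 0, maxsurrogate = 0))
  new("TreeModel", fit = fit, minLeaf = as.integer(minLeaf))
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "TreeModel", function(model, X) {
  nf <- sum(startsWith(attr(model@fit$terms, "term.labels"), "f"))
  X <- .asRowMatrix(X, nf)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  p <- predict(model@fit, newdata = df, type = "prob")[, "IRR"]
  .prediction(p >= 0.5, p)
})

# -------------------------------------------------------------- registry ----

#' Fit a classifier by registry name
#'
#' Maps the method names used in the evaluation reports to fit routines:
#' `LDA` (Fisher discriminant), `3NN` (k = 3, adaptive distance, triangular
#' kernel, Non-IRR weight 0.45), `KNN` (configurable), `LR`, `NB`, `GM`,
#' `PDFE`, `DT`.
#'
#' @param method one of [registryMethods()].
#' @param X,y training features and labels.
#' @param params named list of method hyperparameters (passed through).
#' @return a fitted [EEMClassifier-class].
#' @export
fitClassifier <- function(method, X, y, params = list()) {
  call2 <- function(f, defaults = list())
    do.call(f, c(list(X = X, y = y), utils::modifyList(defaults, params)))
  switch(method,
    "LDA" = , "Fisher" = call2(fitFisher),
    "3NN" = call2(fitKNN, list(k = 3, distance = "adaptive",
                               kernel = "triangular", weightNonIrr = 0.45)),
    "KNN" = call2(fitKNN),
    "LR" = call2(fitLogistic),
    "NB" = call2(fitNaiveBayes),
    "GM" = call2(fitGaussianMixture),
    "PDFE" = call2(fitPDFE),
    "DT" = call2(fitTree),
    stop("unknown method '", method, "'; known: ",
         paste(registryMethods(), collapse = ", ")))
}

#' @rdname fitClassifier
#' @export
registryMethods <- function()
  c("DT", "GM", "3NN", "KNN", "LDA", "Fisher", "LR", "NB", "PDFE")
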