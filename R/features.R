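# Cross-correlation-space feature extraction.
#
# Three steps: (1) each image (or image pair) is standardized and represented
# by its vector of Pearson correlations with the training images; (2) PCA on
# the column-standardized training correlation matrix; (3) component
# retention by the Kaiser rule, the broken-stick model, or a fixed count
# (default 5). On test samples the whole map is linear and can be written as
# correlations with a small set of "mask" images (see computeMasks()).

#' Flatten a compound sample into the task input vector
#'
#' Task 1 uses the control image, task 2 the with-cells image, task 3 the
#' concatenation (control first, then with-cells). Images are flattened
#' row-major in the package orientation (rows = emission).
#'
#' @param sample a [CompoundSample-class].
#' @param task 1, 2 or 3.
#' @return numeric vector of length `nEm * nEx` (tasks 1-2) or
#'   `2 * nEm * nEx` (task 3).
#' @export
vectorizeSample <- function(sample, task) {
  stopifnot(is(sample, "CompoundSample"), task %in% 1:3)
  switch(task,
    .flattenImage(sample@control@intensities),
    .flattenImage(sample@cells@intensities),
    c(.flattenImage(sample@control@intensities),
      .flattenImage(sample@cells@intensities)))
}

# task input matrix for a whole EEMSet: pixels x samples (columns already in
# the vectorizeSample() order, since assays store the same flattening)
.taskMatrix <- function(eset, task) {
  ctl <- SummarizedExperiment::assay(eset, "control")
  cel <- SummarizedExperiment::assay(eset, "cells")
  switch(task, ctl, cel, rbind(ctl, cel))
}

#' Standardize a vector for correlation geometry
#'
#' Centers `v` and scales it to unit Euclidean norm, so that the dot product
#' of two standardized vectors is exactly their Pearson correlation and the
#' squared distance between them is `2 - 2 r`.
#'
#' @param v numeric vector, not constant.
#' @return standardized vector (mean 0, norm 1).
#' @export
standardizeVector <- function(v) {
  c0 <- v - mean(v)
  nrm <- sqrt(sum(c0^2))
  if (nrm <= 0 || !is.finite(nrm))
    stop("constant vector: correlation is undefined")
  c0 / nrm
}

#' Correlate a vector against a set of standardized references
#'
#' @param v numeric vector (raw; standardized internally).
#' @param references matrix with one standardized reference per row (or a
#'   list of standardized vectors).
#' @return numeric vector of Pearson correlations, each in [-1, 1].
#' @export
correlationVector <- function(v, references) {
  if (is.list(references)) references <- do.call(rbind, references)
  if (ncol(references) != length(v))
    stop("length mismatch: v has ", length(v), " entries, references have ",
         ncol(references))
  as.numeric(references %*% standardizeVector(v))
}

#' Verify the correlation / squared-distance equivalence
#'
#' For standardized (centered, unit-norm) vectors, `r_ij = 1 - d2_ij / 2`
#' where `d2` is the squared Euclidean distance: the cross-correlation
#' embedding and the squared-distance embedding are affinely equivalent.
#'
#' @param vectors matrix with one standardized vector per row, or a list.
#' @return maximum absolute deviation `|r_ij - (1 - d2_ij / 2)|` over all pairs.
#' @export
correlationDistanceCheck <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  stopifnot(nrow(vectors) >= 2)
  R <- tcrossprod(vectors)
  sq <- rowSums(vectors^2)
  D2 <- outer(sq, sq, "+") - 2 * R
  max(abs(R - (1 - D2 / 2)))
}

#' Kaiser rule component count
#'
#' Number of eigenvalues strictly greater than 1, the average eigenvalue of
#' any correlation matrix (the features fed to PCA are column-standardized,
#' so the average eigenvalue is exactly 1). Ties at 1 are rejected.
#'
#' @param eigenvalues non-empty numeric vector, descending.
#' @return integer count (possibly 0; [fitExtractor()] floors retention at 1).
#' @export
kaiserSelect <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("empty eigenvalue vector")
  sum(eigenvalues > 1)
}

#' Broken-stick expected proportions
#'
#' Expected sorted piece lengths when a unit stick is broken at `n - 1`
#' independent uniform cuts: `b_k = (1/n) * sum_{i=k}^{n} 1/i`. The `b_k`
#' are strictly decreasing and sum to one.
#'
#' @param n number of pieces (>= 1).
#' @return numeric vector of length `n`.
#' @export
brokenStickExpectation <- function(n) {
  stopifnot(n >= 1)
  rev(cumsum(rev(1 / seq_len(n)))) / n
}

#' Broken-stick component count
#'
#' Eigenvalue proportions `p_k = lambda_k / sum(lambda)` are compared with
#' the broken-stick expectations; components are retained along the maximal
#' leading run with `p_k > b_k` (strict; the run stops at the first failure).
#'
#' @param eigenvalues numeric vector, descending, not all zero.
#' @return integer count (possibly 0; [fitExtractor()] floors retention at 1).
#' @export
brokenStickSelect <- function(eigenvalues) {
  if (!length(eigenvalues) || sum(eigenvalues) <= 0)
    stop("eigenvalues must be non-empty with a positive sum")
  p <- eigenvalues / sum(eigenvalues)
  b <- brokenStickExpectation(length(p))
  fail <- which(!(p > b))
  if (!length(fail)) length(p) else fail[1] - 1L
}

#' Fit the cross-correlation / PCA feature extractor
#'
#' Builds the n x n matrix of pairwise Pearson correlations between the
#' standardized task vectors of the training compounds, standardizes its
#' columns (zero mean, unit variance, so the eigenvalue sum equals n and the
#' Kaiser threshold of 1 is the average eigenvalue), eigen-decomposes, and
#' retains components by the requested rule with a floor of one component.
#' Loading signs are fixed by making each loading's largest-magnitude entry
#' positive.
#'
#' @param training an [EEMSet-class] with at least 3 compounds and both
#'   classes present.
#' @param task 1 (control), 2 (with-cells) or 3 (both, concatenated).
#' @param rule `"fixed"` (default, retaining `nComponents`), `"kaiser"` or
#'   `"broken_stick"`.
#' @param nComponents retained count for `rule = "fixed"` (default 5,
#'   capped at the training size).
#' @return an [EEMFeatureExtractor-class].
#' @export
fitExtractor <- function(training, task, rule = c("fixed", "kaiser", "broken_stick"),
                         nComponents = 5) {
  stopifnot(is(training, "EEMSet"), task %in% 1:3)
  rule <- match.arg(rule)
  n <- ncol(training)
  if (n < 3) stop("need at least 3 training samples")
  if (nlevels(droplevels(classLabels(training))) < 2)
    stop("both classes must be present in the training set")
  V <- .taskMatrix(training, as.integer(task))           # pixels x n
  X <- t(apply(V, 2, standardizeVector))                 # n x pixels, rows standardized
  dimnames(X) <- NULL
  R <- tcrossprod(X)                                     # n x n correlation matrix
  mu <- colMeans(R)
  s <- apply(R, 2, sd)
  if (any(s <= 0))
    stop("degenerate correlation feature: a column of the correlation matrix is constant")
  Z <- sweep(sweep(R, 2, mu), 2, s, "/")
  C <- crossprod(Z) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  m <- switch(rule,
    fixed = as.integer(nComponents),
    kaiser = kaiserSelect(ev),
    broken_stick = brokenStickSelect(ev))
  m <- max(1L, min(as.integer(m), n))
  L <- eig$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    peak <- which.max(abs(L[, j]))
    if (L[peak, j] < 0) L[, j] <- -L[, j]
  }
  new("EEMFeatureExtractor", task = as.integer(task), rule = rule,
      nRetained = m, refVectors = X, colMeans = mu, colSds = s,
      loadings = L, eigenvalues = ev,
      excitation = eemExcitation(training), emission = eemEmission(training),
      sampleIds = compoundIds(training))
}

#' Project samples into the retained feature space
#'
#' Standardizes each task vector, correlates it against the stored training
#' references, applies the stored column standardization and projects onto
#' the retained loadings. Applying it to the training set reproduces the
#' training score matrix; the map is invariant to per-image affine intensity
#' changes (gain/offset) by correlation's construction.
#'
#' @param extractor an [EEMFeatureExtractor-class].
#' @param x an [EEMSet-class] or a single [CompoundSample-class] on the
#'   training wavelength grid.
#' @return numeric score matrix, samples x `nRetained` (a single sample
#'   yields a 1-row matrix).
#' @export
extractFeatures <- function(extractor, x) {
  stopifnot(is(extractor, "EEMFeatureExtractor"))
  if (is(x, "CompoundSample")) {
    v <- vectorizeSample(x, extractor@task)
    if (length(v) != ncol(extractor@refVectors))
      stop("sample grid does not match the training grid")
    Vstd <- matrix(standardizeVector(v), ncol = 1)
    ids <- x@compoundId
  } else if (is(x, "EEMSet")) {
    if (!isTRUE(all.equal(eemExcitation(x), extractor@excitation)) ||
        !isTRUE(all.equal(eemEmission(x), extractor@emission)))
      stop("sample grid does not match the training grid")
    Vstd <- apply(.taskMatrix(x, extractor@task), 2, standardizeVector)
    ids <- compoundIds(x)
  } else stop("x must be an EEMSet or a CompoundSample")
  R <- extractor@refVectors %*% Vstd                  # n_train x k correlations
  Zt <- sweep(sweep(R, 1, extractor@colMeans), 1, extractor@colSds, "/")
  scores <- t(Zt) %*% extractor@loadings              # k x m
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Compute the mask representation of a fitted extractor
#'
#' After training, each retained feature is a linear functional of the
#' standardized test vector: `feature_j(x) = <standardize(x), mask_j> +
#' offset_j`, where `mask_j` folds the reference vectors, the column
#' standardization and the loading into a single image. Tasks 1-2 give masks
#' shaped like one image; task 3 gives two stacked images (control on top).
#'
#' @param extractor an [EEMFeatureExtractor-class].
#' @return object of class `eem_masks`: list with `masks` (list of
#'   `nRetained` matrices), `offsets`, `task` and the wavelength axes.
#' @seealso [applyMasks()]
#' @export
computeMasks <- function(extractor) {
  stopifnot(is(extractor, "EEMFeatureExtractor"))
  Ls <- extractor@loadings / extractor@colSds          # rows scaled by 1/sd
  W <- crossprod(extractor@refVectors, Ls)             # pixels x m
  offsets <- -as.numeric(crossprod(extractor@colMeans / extractor@colSds,
                                   extractor@loadings))
  nEm <- length(extractor@emission); nEx <- length(extractor@excitation)
  masks <- lapply(seq_len(ncol(W)), function(j) {
    if (extractor@task == 3L) {
      p <- nEm * nEx
      rbind(.unflattenImage(W[seq_len(p), j], nEm, nEx),
            .unflattenImage(W[p + seq_len(p), j], nEm, nEx))
    } else {
      .unflattenImage(W[, j], nEm, nEx)
    }
  })
  structure(list(masks = masks, offsets = offsets, task = extractor@task,
                 excitation = extractor@excitation, emission = extractor@emission),
            class = "eem_masks")
}

#' Apply masks to a sample (linear test-time route)
#'
#' @param maskObj result of [computeMasks()] (or masks reloaded from disk).
#' @param sample a [CompoundSample-class].
#' @return numeric feature vector, identical (to numerical precision) to the
#'   corresponding row of [extractFeatures()].
#' @export
applyMasks <- function(maskObj, sample) {
  stopifnot(inherits(maskObj, "eem_masks"), is(sample, "CompoundSample"))
  v <- standardizeVector(vectorizeSample(sample, maskObj$task))
  vapply(seq_along(maskObj$masks), function(j) {
    sum(v * .flattenImage(maskObj$masks[[j]])) + maskObj$offsets[j]
  }, numeric(1))
}
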