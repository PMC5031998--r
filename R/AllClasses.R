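#' @import methods
#' @importFrom stats cor cov sd rnorm runif predict setNames var glm coef
#'   quasibinomial dist plogis dnorm
#' @importFrom utils read.csv write.csv packageVersion
NULL

.CLASS_LEVELS <- c("IRR", "NonIRR")

#' EEMImage: a single excitation-emission fluorescence matrix
#'
#' Intensities are stored with rows indexed by emission wavelength and
#' columns by excitation wavelength (the convention used throughout the
#' package and in the on-disk format). Wavelength axes must be strictly
#' increasing. Intensity content (finiteness, non-negativity) is checked by
#' [validateSample()] and enforced when datasets are read from disk, so that
#' malformed images can be represented and reported rather than merely
#' rejected at construction.
#'
#' @slot excitation numeric vector of excitation wavelengths (nm), one per column.
#' @slot emission numeric vector of emission wavelengths (nm), one per row.
#' @slot intensities numeric matrix, `length(emission)` x `length(excitation)`.
#' @export
setClass("EEMImage",
  slots = c(excitation = "numeric", emission = "numeric", intensities = "matrix")
)

setValidity("EEMImage", function(object) {
  msg <- character()
  if (anyNA(object@excitation) || anyNA(object@emission))
    msg <- c(msg, "wavelength axes must not contain NA")
  if (length(object@excitation) > 1 && any(diff(object@excitation) <= 0))
    msg <- c(msg, "excitation axis must be strictly increasing")
  if (length(object@emission) > 1 && any(diff(object@emission) <= 0))
    msg <- c(msg, "emission axis must be strictly increasing")
  if (!is.numeric(object@intensities))
    msg <- c(msg, "intensities must be numeric")
  if (nrow(object@intensities) != length(object@emission) ||
      ncol(object@intensities) != length(object@excitation))
    msg <- c(msg, "intensity matrix dimensions must match the wavelength grid (rows = emission, columns = excitation)")
  if (length(msg)) msg else TRUE
})

#' @describeIn EEMImage-class Constructor.
#' @param intensities numeric matrix (rows = emission, columns = excitation).
#' @param excitation,emission wavelength axes in nm.
#' @return An `EEMImage`.
#' @export
EEMImage <- function(intensities, excitation, emission) {
  new("EEMImage",
    excitation = as.numeric(excitation),
    emission = as.numeric(emission),
    intensities = as.matrix(intensities))
}

#' CompoundSample: one chemical with paired control / with-cells images
#'
#' @slot compoundId single non-empty string, unique within a dataset.
#' @slot label `"IRR"` (irritant, the positive class) or `"NonIRR"`.
#' @slot control `EEMImage` recorded without growing cells.
#' @slot cells `EEMImage` recorded with growing cells.
#' @export
setClass("CompoundSample",
  slots = c(compoundId = "character", label = "character",
            control = "EEMImage", cells = "EEMImage")
)

setValidity("CompoundSample", function(object) {
  msg <- character()
  if (length(object@compoundId) != 1L || !nzchar(object@compoundId))
    msg <- c(msg, "compoundId must be a single non-empty string")
  if (length(object@label) != 1L || !object@label %in% .CLASS_LEVELS)
    msg <- c(msg, sprintf("label must be one of %s", paste(.CLASS_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn CompoundSample-class Constructor.
#' @param compoundId sample identifier.
#' @param label class label, `"IRR"` or `"NonIRR"`.
#' @param control,cells `EEMImage` objects on a shared wavelength grid.
#' @return A `CompoundSample`.
#' @export
CompoundSample <- function(compoundId, label, control, cells) {
  new("CompoundSample", compoundId = as.character(compoundId),
      label = as.character(label), control = control, cells = cells)
}

#' EEMSet: a dataset of paired EEM images
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays,
#' `"control"` and `"cells"`, whose rows are image pixels flattened row-major
#' in the documented orientation (emission-major: pixel index runs fastest
#' over excitation within each emission row) and whose columns are compounds.
#' The shared wavelength grid lives in `metadata(x)$excitation` /
#' `metadata(x)$emission`; class labels in `colData(x)$label`.
#'
#' @export
#' @import SummarizedExperiment
setClass("EEMSet", contains = "SummarizedExperiment")

setValidity("EEMSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("control", "cells") %in% an))
    msg <- c(msg, "assays 'control' and 'cells' are required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$excitation) || is.null(md$emission)) {
    msg <- c(msg, "metadata must carry the 'excitation' and 'emission' wavelength axes")
  } else if (nrow(object) != length(md$excitation) * length(md$emission)) {
    msg <- c(msg, "row count must equal length(emission) * length(excitation)")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) {
    msg <- c(msg, "colData must have a 'label' column")
  } else if (!all(as.character(cd$label) %in% .CLASS_LEVELS)) {
    msg <- c(msg, "labels must be 'IRR' or 'NonIRR'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "compound ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' EEMFeatureExtractor: frozen cross-correlation + PCA training artifacts
#'
#' Holds everything needed to map a new compound sample linearly into the
#' retained principal-component space: the standardized training image
#' vectors (the correlation references), the column statistics of the
#' training correlation matrix, and the PCA loadings/eigenvalues.
#'
#' @slot task integer 1 (control image), 2 (with-cells image) or
#'   3 (both images concatenated, control first).
#' @slot rule component selection rule actually applied
#'   (`"kaiser"`, `"broken_stick"` or `"fixed"`).
#' @slot nRetained number of retained principal components.
#' @slot refVectors matrix (n_train x n_pixels) of standardized training vectors.
#' @slot colMeans,colSds column statistics of the training correlation matrix.
#' @slot loadings orthonormal eigenvector matrix (n_train x nRetained).
#' @slot eigenvalues all eigenvalues, descending.
#' @slot excitation,emission training wavelength grid.
#' @slot sampleIds training compound ids, in training order.
#' @export
setClass("EEMFeatureExtractor",
  slots = c(task = "integer", rule = "character", nRetained = "integer",
            refVectors = "matrix", colMeans = "numeric", colSds = "numeric",
            loadings = "matrix", eigenvalues = "numeric",
            excitation = "numeric", emission = "numeric",
            sampleIds = "character")
)

setValidity("EEMFeatureExtractor", function(object) {
  msg <- character()
  if (!object@task %in% 1:3) msg <- c(msg, "task must be 1, 2 or 3")
  n <- nrow(object@refVectors)
  if (object@nRetained < 1L || object@nRetained > n)
    msg <- c(msg, "nRetained must be in [1, n_train]")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted in descending order")
  if (any(object@colSds <= 0))
    msg <- c(msg, "column standard deviations must be positive")
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

# ---- classifier model classes (uniform fit/predict contract) ----

#' Virtual parent of all fitted irritancy classifiers
#' @export
setClass("EEMClassifier", representation("VIRTUAL"))

#' Fisher discriminant with Sens+Spec-maximizing threshold
#'
#' @slot w unit-norm discriminant direction, oriented so larger projections
#'   are more irritant-like.
#' @slot threshold decision threshold on the projection.
#' @slot positiveSide `"greater"`: projections above the threshold are IRR.
#' @export
setClass("FisherModel", contains = "EEMClassifier",
  slots = c(w = "numeric", threshold = "numeric", positiveSide = "character"))

#' Weighted kernel k-nearest-neighbour classifier
#'
#' @slot trainX,trainY training features and labels (kept: kNN is lazy).
#' @slot k neighbourhood size.
#' @slot distance `"euclidean"`, `"fisher_transformed"` or `"adaptive"`.
#' @slot kernel `"uniform"` or `"triangular"`.
#' @slot weightNonIrr vote weight of the Non-IRR class (IRR gets 1 - this).
#' @slot whitening whitening matrix for the Fisher-transformed distance
#'   (identity otherwise).
#' @export
setClass("KNNModel", contains = "EEMClassifier",
  slots = c(trainX = "matrix", trainY = "character", k = "integer",
            distance = "character", kernel = "character",
            weightNonIrr = "numeric", whitening = "matrix"))

#' Class-weighted logistic regression model
#' @slot coef coefficients (intercept first) on the kept feature columns.
#' @slot keptCols indices of non-constant feature columns used in the fit.
#' @slot weightNonIrr class weight applied to Non-IRR samples.
#' @export
setClass("LogisticModel", contains = "EEMClassifier",
  slots = c(coef = "numeric", keptCols = "integer", weightNonIrr = "numeric"))

#' Gaussian naive Bayes classifier
#' @slot means,vars class-by-feature matrices of means and (floored) variances.
#' @slot priors named class priors, positive, summing to one.
#' @export
setClass("NaiveBayesModel", contains = "EEMClassifier",
  slots = c(means = "matrix", vars = "matrix", priors = "numeric"))

#' Per-class Gaussian mixture classifier
#' @slot densities list of per-class mixture density fits.
#' @slot priors named class priors (empirical or equal, per prior correction).
#' @export
setClass("GaussianMixtureModel", contains = "EEMClassifier",
  slots = c(densities = "list", priors = "numeric"))

#' Kernel probability-density-function estimation classifier (PDFE)
#'
#' Per-class kernel density with a per-training-point bandwidth set to the
#' distance to its k-th same-class neighbour.
#' @slot points,bandwidths per-class training points and bandwidths.
#' @slot kernel `"gaussian"` or `"triangular"`.
#' @slot priors named class priors.
#' @slot kRadius neighbour count used for the bandwidths.
#' @export
setClass("PDFEModel", contains = "EEMClassifier",
  slots = c(points = "list", bandwidths = "list", kernel = "character",
            priors = "numeric", kRadius = "integer"))

#' Classification tree model
#' @slot fit the underlying fitted tree.
#' @slot minLeaf minimal number of training samples per leaf.
#' @export
setClass("TreeModel", contains = "EEMClassifier",
  slots = c(fit = "ANY", minLeaf = "integer"))
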