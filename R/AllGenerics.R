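#' Predict class labels and scores for feature vectors
#'
#' Uniform prediction contract shared by every fitted classifier. Larger
#' scores always mean "more irritant-like"; the label is consistent with the
#' thresholded score.
#'
#' @param model a fitted classifier (any [EEMClassifier-class] subclass).
#' @param X numeric feature matrix (samples x features) with the same number
#'   of columns as the training features; a bare vector is treated as one row.
#' @return `data.frame` with columns `label` (factor, levels IRR/NonIRR) and
#'   `score` (numeric).
#' @export
setGeneric("predictLabels", function(model, X) standardGeneric("predictLabels"))

#' Class labels of an EEMSet
#' @param x an [EEMSet-class].
#' @return factor of labels with levels `IRR`, `NonIRR`.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Compound identifiers of an EEMSet
#' @param x an [EEMSet-class].
#' @return character vector of compound ids.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Retrieve one compound from an EEMSet
#' @param x an [EEMSet-class].
#' @param i column index or compound id.
#' @return a [CompoundSample-class].
#' @export
setGeneric("getSample", function(x, i) standardGeneric("getSample"))
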