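# EEMSet construction, accessors and sample validation.

# Row-major (emission-major) flattening: within each emission row the index
# runs over excitation. This is the single orientation used everywhere
# (vectorization, assays, masks, the on-disk format).
.flattenImage <- function(M) as.vector(t(M))

.unflattenImage <- function(v, nEmission, nExcitation)
  matrix(v, nrow = nEmission, ncol = nExcitation, byrow = TRUE)

#' Validate a compound sample
#'
#' Checks the type invariants of a [CompoundSample-class] and reports every
#' violation as a human-readable string. It never throws, so malformed
#' samples can be inspected; [EEMSet()] and [loadEEMDataset()] turn a
#' non-empty report into an error.
#'
#' @param sample a [CompoundSample-class].
#' @return character vector of violations; `character(0)` if the sample is
#'   well-formed.
#' @export
validateSample <- function(sample) {
  stopifnot(is(sample, "CompoundSample"))
  id <- sample@compoundId
  out <- character()
  ctl <- sample@control
  cel <- sample@cells
  if (!identical(dim(ctl@intensities), dim(cel@intensities)) ||
      !isTRUE(all.equal(ctl@excitation, cel@excitation)) ||
      !isTRUE(all.equal(ctl@emission, cel@emission))) {
    out <- c(out, sprintf(
      "%s: control and with-cells images must share one wavelength grid (%dx%d vs %dx%d)",
      id, nrow(ctl@intensities), ncol(ctl@intensities),
      nrow(cel@intensities), ncol(cel@intensities)))
  }
  for (cond in c("control", "cells")) {
    M <- slot(sample, cond)@intensities
    if (!all(is.finite(M)))
      out <- c(out, sprintf("%s: %s image has non-finite intensities", id, cond))
    else if (any(M < 0))
      out <- c(out, sprintf("%s: %s image has negative intensities", id, cond))
  }
  out
}

#' Build an EEMSet from compound samples
#'
#' @param samples list of [CompoundSample-class] objects sharing one
#'   wavelength grid. Every sample must pass [validateSample()].
#' @return an [EEMSet-class].
#' @export
EEMSet <- function(samples) {
  if (!length(samples) || !all(vapply(samples, is, TRUE, "CompoundSample")))
    stop("'samples' must be a non-empty list of CompoundSample objects")
  viol <- unlist(lapply(samples, validateSample))
  if (length(viol))
    stop("invalid samples:\n  ", paste(viol, collapse = "\n  "))
  ids <- vapply(samples, slot, "", "compoundId")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ex <- samples[[1]]@control@excitation
  em <- samples[[1]]@control@emission
  for (s in samples[-1]) {
    if (!isTRUE(all.equal(s@control@excitation, ex)) ||
        !isTRUE(all.equal(s@control@emission, em)))
      stop("all samples must share one wavelength grid (offender: ", s@compoundId, ")")
  }
  ctl <- vapply(samples, function(s) .flattenImage(s@control@intensities),
                numeric(length(ex) * length(em)))
  cel <- vapply(samples, function(s) .flattenImage(s@cells@intensities),
                numeric(length(ex) * length(em)))
  colnames(ctl) <- colnames(cel) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(control = ctl, cells = cel),
    colData = S4Vectors::DataFrame(
      label = factor(vapply(samples, slot, "", "label"), levels = .CLASS_LEVELS),
      row.names = ids),
    metadata = list(excitation = ex, emission = em))
  new("EEMSet", se)
}

#' @rdname classLabels
#' @export
setMethod("classLabels", "EEMSet", function(x)
  factor(SummarizedExperiment::colData(x)$label, levels = .CLASS_LEVELS))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "EEMSet", function(x) colnames(x))

#' Wavelength grid accessors
#' @param x an [EEMSet-class].
#' @return numeric vector of wavelengths (nm).
#' @export
eemExcitation <- function(x) S4Vectors::metadata(x)$excitation

#' @rdname eemExcitation
#' @export
eemEmission <- function(x) S4Vectors::metadata(x)$emission

#' @rdname getSample
#' @export
setMethod("getSample", "EEMSet", function(x, i) {
  if (is.character(i)) i <- match(i, colnames(x))
  stopifnot(length(i) == 1L, !is.na(i), i >= 1, i <= ncol(x))
  ex <- eemExcitation(x); em <- eemEmission(x)
  CompoundSample(
    compoundId = colnames(x)[i],
    label = as.character(classLabels(x)[i]),
    control = EEMImage(.unflattenImage(SummarizedExperiment::assay(x, "control")[, i],
                                       length(em), length(ex)), ex, em),
    cells = EEMImage(.unflattenImage(SummarizedExperiment::assay(x, "cells")[, i],
                                     length(em), length(ex)), ex, em))
})

setMethod("show", "EEMImage", function(object) {
  cat(sprintf("EEMImage: %d emission x %d excitation [em %.0f-%.0f nm, ex %.0f-%.0f nm]\n",
              length(object@emission), length(object@excitation),
              min(object@emission), max(object@emission),
              min(object@excitation), max(object@excitation)))
})

setMethod("show", "CompoundSample", function(object) {
  cat(sprintf("CompoundSample '%s' (%s), grid %d x %d\n",
              object@compoundId, object@label,
              length(object@control@emission), length(object@control@excitation)))
})

setMethod("show", "EEMSet", function(object) {
  tab <- table(classLabels(object))
  cat(sprintf("EEMSet: %d compounds (%d IRR / %d NonIRR), grid %d emission x %d excitation\n",
              ncol(object), tab[["IRR"]], tab[["NonIRR"]],
              length(eemEmission(object)), length(eemExcitation(object))))
})

setMethod("show", "EEMFeatureExtractor", function(object) {
  cat(sprintf("EEMFeatureExtractor: task %d, rule %s, %d/%d components retained, %d references\n",
              object@task, object@rule, object@nRetained,
              length(object@eigenvalues), nrow(object@refVectors)))
})
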