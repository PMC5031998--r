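# Text serialization of extractors and masks (delimited text, full
# double precision via %.17g so round trips are numerically exact).

.writeNumMatrix <- function(M, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}

.readNumMatrix <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

.writeKeyValues <- function(x, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste0(names(x), "=", vapply(x, as.character, "")), con, sep = "\n")
  invisible(path)
}

.readKeyValues <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed key=value line: ", lines[bad][1])
  setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
}

#' Serialize a fitted extractor to a directory of text files
#'
#' @param extractor an [EEMFeatureExtractor-class].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
saveExtractor <- function(extractor, directory) {
  stopifnot(is(extractor, "EEMFeatureExtractor"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  .writeKeyValues(list(task = extractor@task, rule = extractor@rule,
                       n_retained = extractor@nRetained,
                       n_train = nrow(extractor@refVectors)),
                  file.path(directory, "meta.txt"))
  writeLines(extractor@sampleIds, file.path(directory, "sample_ids.txt"))
  .writeNumMatrix(cbind(extractor@excitation), file.path(directory, "excitation.txt"))
  .writeNumMatrix(cbind(extractor@emission), file.path(directory, "emission.txt"))
  .writeNumMatrix(cbind(extractor@eigenvalues), file.path(directory, "eigenvalues.txt"))
  .writeNumMatrix(cbind(extractor@colMeans, extractor@colSds),
                  file.path(directory, "column_stats.tsv"))
  .writeNumMatrix(extractor@loadings, file.path(directory, "loadings.tsv"))
  .writeNumMatrix(extractor@refVectors, file.path(directory, "reference_vectors.tsv"))
  invisible(directory)
}

#' Load a serialized extractor
#'
#' @param directory directory written by [saveExtractor()].
#' @return an [EEMFeatureExtractor-class].
#' @export
loadExtractor <- function(directory) {
  metaPath <- file.path(directory, "meta.txt")
  if (!file.exists(metaPath)) stop("no extractor meta.txt in ", directory)
  meta <- .readKeyValues(metaPath)
  stats <- .readNumMatrix(file.path(directory, "column_stats.tsv"))
  new("EEMFeatureExtractor",
      task = as.integer(meta$task), rule = as.character(meta$rule),
      nRetained = as.integer(meta$n_retained),
      refVectors = .readNumMatrix(file.path(directory, "reference_vectors.tsv")),
      colMeans = stats[, 1], colSds = stats[, 2],
      loadings = .readNumMatrix(file.path(directory, "loadings.tsv")),
      eigenvalues = as.numeric(.readNumMatrix(file.path(directory, "eigenvalues.txt"))),
      excitation = as.numeric(.readNumMatrix(file.path(directory, "excitation.txt"))),
      emission = as.numeric(.readNumMatrix(file.path(directory, "emission.txt"))),
      sampleIds = readLines(file.path(directory, "sample_ids.txt")))
}

#' Export masks as EEM matrix files
#'
#' Writes one matrix file per retained component (`mask_1.tsv`, ...) in the
#' dataset interchange format, plus `offsets.txt` and `meta.txt`. Task-3
#' masks are written as two stacked images (the emission axis repeats).
#'
#' @param maskObj result of [computeMasks()].
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
writeMasks <- function(maskObj, directory) {
  stopifnot(inherits(maskObj, "eem_masks"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  em <- if (maskObj$task == 3L) c(maskObj$emission, maskObj$emission) else maskObj$emission
  for (j in seq_along(maskObj$masks))
    writeEEMMatrix(maskObj$masks[[j]], maskObj$excitation, em,
                   file.path(directory, sprintf("mask_%d.tsv", j)))
  .writeNumMatrix(cbind(maskObj$offsets), file.path(directory, "offsets.txt"))
  .writeKeyValues(list(task = maskObj$task, n_masks = length(maskObj$masks)),
                  file.path(directory, "meta.txt"))
  invisible(directory)
}

#' Reload masks written by [writeMasks()]
#'
#' @param directory mask directory.
#' @return object of class `eem_masks`.
#' @export
readMasks <- function(directory) {
  meta <- .readKeyValues(file.path(directory, "meta.txt"))
  task <- as.integer(meta$task)
  n <- as.integer(meta$n_masks)
  files <- file.path(directory, sprintf("mask_%d.tsv", seq_len(n)))
  mats <- lapply(files, readEEMMatrix)
  em <- mats[[1]]$emission
  if (task == 3L) em <- em[seq_len(length(em) / 2)]
  structure(list(masks = lapply(mats, `[[`, "intensities"),
                 offsets = as.numeric(.readNumMatrix(file.path(directory, "offsets.txt"))),
                 task = task, excitation = mats[[1]]$excitation, emission = em),
            class = "eem_masks")
}
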