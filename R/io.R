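# Plain-text interchange format for EEM datasets.
#
# One tab-delimited file per image: the first row holds the excitation
# wavelengths, the first column the emission wavelengths, so each file is
# self-describing. A manifest.csv ties compound ids and class labels to the
# matrix files. Numbers are written with 8 significant digits; the format is
# round-trip stable (save -> load -> save is byte-identical).

.FMT <- "%.8g"

.matrixHeader <- c(
  "# EEM intensity matrix: rows = emission (nm), columns = excitation (nm)",
  "# first data row = excitation axis; first column = emission axis")

#' Write one EEM matrix file
#'
#' @param intensities numeric matrix (rows = emission, columns = excitation).
#' @param excitation,emission wavelength axes (nm).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEEMMatrix <- function(intensities, excitation, emission, path) {
  stopifnot(nrow(intensities) == length(emission),
            ncol(intensities) == length(excitation))
  con <- file(path, "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  fmtRow <- function(cells) paste(cells, collapse = "\t")
  lines <- c(
    .matrixHeader,
    fmtRow(c("emission/excitation", sprintf(.FMT, excitation))),
    vapply(seq_along(emission), function(i)
      fmtRow(c(sprintf(.FMT, emission[i]), sprintf(.FMT, intensities[i, ]))),
      character(1)))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read one EEM matrix file
#'
#' @param path file written by [writeEEMMatrix()].
#' @return list with `intensities`, `excitation`, `emission`.
#' @export
readEEMMatrix <- function(path) {
  if (!file.exists(path)) stop("no such matrix file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("malformed EEM matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ex <- as.numeric(fields[[1]][-1])
  body <- fields[-1]
  em <- as.numeric(vapply(body, `[`, "", 1L))
  M <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  if (anyNA(ex) || anyNA(em))
    stop("unparseable wavelength axis in ", path)
  if (ncol(M) != length(ex))
    stop("ragged rows in ", path)
  list(intensities = unname(M), excitation = ex, emission = em)
}

#' Save an EEMSet as a dataset directory
#'
#' Writes one matrix file per image (`<id>_control.tsv`, `<id>_cells.tsv`)
#' plus `manifest.csv` with columns `compound_id,label,control_file,cells_file`.
#'
#' @param eset an [EEMSet-class].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @seealso [loadEEMDataset()]
#' @export
saveEEMDataset <- function(eset, directory) {
  stopifnot(is(eset, "EEMSet"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  ids <- compoundIds(eset)
  safe <- gsub("[^A-Za-z0-9_.-]", "_", ids)
  if (anyDuplicated(safe)) stop("compound ids collide after filename sanitization")
  ex <- eemExcitation(eset); em <- eemEmission(eset)
  man <- data.frame(
    compound_id = ids,
    label = as.character(classLabels(eset)),
    control_file = paste0(safe, "_control.tsv"),
    cells_file = paste0(safe, "_cells.tsv"),
    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s <- getSample(eset, i)
    writeEEMMatrix(s@control@intensities, ex, em, file.path(directory, man$control_file[i]))
    writeEEMMatrix(s@cells@intensities, ex, em, file.path(directory, man$cells_file[i]))
  }
  con <- file(file.path(directory, "manifest.csv"), "wb")
  write.csv(man, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(directory)
}

#' Load an EEM dataset directory
#'
#' Reads the manifest and every referenced matrix file, validates all type
#' invariants (paired grids equal, intensities finite and non-negative,
#' unique ids) and returns the dataset. A missing matrix file is a hard
#' error naming the offending compound.
#'
#' @param directory dataset directory written by [saveEEMDataset()].
#' @return an [EEMSet-class].
#' @export
loadEEMDataset <- function(directory) {
  manPath <- file.path(directory, "manifest.csv")
  if (!file.exists(manPath)) stop("no manifest.csv in ", directory)
  man <- read.csv(manPath, stringsAsFactors = FALSE)
  need <- c("compound_id", "label", "control_file", "cells_file")
  if (!all(need %in% colnames(man)))
    stop("manifest.csv must have columns ", paste(need, collapse = ","))
  samples <- lapply(seq_len(nrow(man)), function(i) {
    for (f in c(man$control_file[i], man$cells_file[i])) {
      if (!file.exists(file.path(directory, f)))
        stop("compound '", man$compound_id[i], "': missing matrix file ", f)
    }
    ctl <- readEEMMatrix(file.path(directory, man$control_file[i]))
    cel <- readEEMMatrix(file.path(directory, man$cells_file[i]))
    CompoundSample(man$compound_id[i], man$label[i],
      EEMImage(ctl$intensities, ctl$excitation, ctl$emission),
      EEMImage(cel$intensities, cel$excitation, cel$emission))
  })
  EEMSet(samples)
}
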