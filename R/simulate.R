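# Synthetic five-dye EEM generator.
#
# Each image is a sum of bivariate Gaussian dye peaks on the instrument's
# excitation x emission grid plus zero-truncated Gaussian measurement noise.
# Class information enters only through the with-cells image: growing cells
# modulate the dye amplitudes multiplicatively with a class-specific pattern
# (irritants and non-irritants push the dye responses in opposite
# directions), while a compound-specific, class-uninformative "nuisance"
# amplitude vector perturbs both images of a compound equally.

#' Default dye library of the five-dye sensor array
#'
#' Excitation/emission maxima follow the published sensor-array dye list
#' (HPTS, Oregon Green 514, Rhodamine B, Ru(dpp)3 dichloride, thionin
#' acetate). Peak widths and base amplitudes are generator choices: two dyes
#' share nearly identical emission maxima (527 vs 528 nm) and are resolved
#' through their excitation maxima (470 vs 504 nm).
#'
#' @return data.frame with columns `name`, `ex_max`, `em_max`, `ex_width`,
#'   `em_width` (Gaussian sigmas, nm) and `base_amplitude`.
#' @export
defaultDyeLibrary <- function() {
  data.frame(
    name = c("HPTS", "Oregon Green 514", "Rhodamine B",
             "Ru(dpp)3 dichloride", "Thionin acetate"),
    ex_max = c(470, 504, 541, 541, 463),
    em_max = c(527, 528, 576, 628, 637),
    ex_width = c(20, 20, 20, 20, 20),
    em_width = c(25, 25, 25, 25, 25),
    base_amplitude = c(1000, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
}

#' Instrument wavelength grid
#'
#' Evenly spaced axes over the spectrofluorimeter's recorded ranges,
#' excitation 74-691 nm and emission 227-724 nm (the printed lower excitation
#' bound is reproduced as-is; all dye peaks lie well inside the grid, so it
#' only affects empty background). 511 points per axis mirrors the
#' instrument; smaller grids are used for fast tests.
#'
#' @param gridSize points per axis (default 511).
#' @return list with numeric `excitation` and `emission` axes.
#' @export
makeWavelengthGrid <- function(gridSize = 511) {
  stopifnot(gridSize >= 2)
  list(excitation = seq(74, 691, length.out = gridSize),
       emission = seq(227, 724, length.out = gridSize))
}

#' Generator configuration
#'
#' @param nIrr,nNonIrr class sizes (defaults 34 and 28, the study design).
#' @param gridSize points per wavelength axis (default 64 for fast suites;
#'   511 reproduces the instrument resolution).
#' @param dyes dye library data.frame, see [defaultDyeLibrary()].
#' @param cellEffectScale magnitude (log-amplitude units) of the
#'   class-specific dye modulation applied to the with-cells image only;
#'   0 removes all class information.
#' @param nuisanceScale standard deviation (log-amplitude units) of the
#'   compound-specific, class-uninformative amplitude modulation applied to
#'   both images of a compound.
#' @param noiseSd measurement noise standard deviation, intensity units
#'   (dye base amplitude is 1000).
#' @param seed integer master seed; each compound draws from its own
#'   counter-derived substream, so extending a dataset never re-randomizes
#'   earlier compounds.
#' @return validated config list of class `eem_generator_config`.
#' @export
generatorConfig <- function(nIrr = 34, nNonIrr = 28, gridSize = 64,
                            dyes = defaultDyeLibrary(),
                            cellEffectScale = 0.4, nuisanceScale = 0.15,
                            noiseSd = 20, seed = 1) {
  stopifnot(nIrr >= 0, nNonIrr >= 0, nIrr + nNonIrr >= 1, gridSize >= 2,
            cellEffectScale >= 0, nuisanceScale >= 0, noiseSd >= 0,
            is.data.frame(dyes), nrow(dyes) >= 1,
            all(c("ex_max", "em_max", "ex_width", "em_width", "base_amplitude")
                %in% colnames(dyes)),
            all(dyes$ex_width > 0), all(dyes$em_width > 0),
            all(dyes$base_amplitude > 0))
  structure(list(nIrr = as.integer(nIrr), nNonIrr = as.integer(nNonIrr),
                 gridSize = as.integer(gridSize), dyes = dyes,
                 cellEffectScale = cellEffectScale,
                 nuisanceScale = nuisanceScale, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "eem_generator_config")
}

# class-specific cell-response directions (unit norm): irritants boost
# odd-indexed dyes and quench even-indexed ones; non-irritants the reverse.
.classDirection <- function(label, nDyes) {
  base <- rep_len(c(1, -1), nDyes)
  dir <- if (label == "IRR") base else -base
  dir / sqrt(nDyes)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Simulate one EEM image
#'
#' Intensity at (emission, excitation) is the sum over dyes of
#' `amplitude * base_amplitude * exp(-(ex - ex_max)^2 / (2 ex_width^2)) *
#' exp(-(em - em_max)^2 / (2 em_width^2))`, plus Gaussian noise truncated at
#' zero (negative draws are clipped) so intensities stay non-negative.
#' Noise is drawn from the current RNG state: seed the RNG (or use
#' [generateEEMSet()]) for reproducibility.
#'
#' @param dyes dye library data.frame.
#' @param amplitudes non-negative per-dye multipliers, one per dye row.
#' @param excitation,emission wavelength axes (nm).
#' @param noiseSd noise standard deviation (0 for a noise-free image).
#' @return an [EEMImage-class].
#' @export
simulateEEM <- function(dyes, amplitudes, excitation, emission, noiseSd = 0) {
  stopifnot(length(amplitudes) == nrow(dyes))
  if (any(amplitudes < 0)) stop("amplitude multipliers must be non-negative")
  M <- matrix(0, length(emission), length(excitation))
  for (d in seq_len(nrow(dyes))) {
    emG <- exp(-(emission - dyes$em_max[d])^2 / (2 * dyes$em_width[d]^2))
    exG <- exp(-(excitation - dyes$ex_max[d])^2 / (2 * dyes$ex_width[d]^2))
    M <- M + amplitudes[d] * dyes$base_amplitude[d] * (emG %o% exG)
  }
  if (noiseSd > 0)
    M <- pmax(M + matrix(rnorm(length(M), 0, noiseSd), nrow(M)), 0)
  EEMImage(M, excitation, emission)
}

#' Generate a synthetic EEM dataset
#'
#' For each compound, a nuisance log-amplitude vector (sd
#' `nuisanceScale`) is drawn and applied to both images; the with-cells image
#' additionally gets the class-specific modulation
#' `exp(cellEffectScale * direction(class))`. With `cellEffectScale = 0` the
#' control and with-cells images of a compound have identical expected
#' intensities and the dataset carries no class information.
#'
#' @param config an `eem_generator_config`, see [generatorConfig()].
#' @return an [EEMSet-class] with `nIrr + nNonIrr` compounds (IRR first).
#' @export
generateEEMSet <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "eem_generator_config"))
  grid <- makeWavelengthGrid(config$gridSize)
  labels <- rep(c("IRR", "NonIRR"), c(config$nIrr, config$nNonIrr))
  nDyes <- nrow(config$dyes)
  counts <- c(IRR = 0L, NonIRR = 0L)
  samples <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    counts[lab] <- counts[lab] + 1L
    subSeed <- (abs(config$seed) %% 1000003L) * 2011L + i * 7919L
    samples[[i]] <- .withSeed(subSeed %% 2147483629L, {
      nuis <- exp(rnorm(nDyes, 0, config$nuisanceScale))
      cellAmp <- nuis * exp(config$cellEffectScale * .classDirection(lab, nDyes))
      CompoundSample(
        compoundId = sprintf("%s_%02d", lab, counts[lab]),
        label = lab,
        control = simulateEEM(config$dyes, nuis, grid$excitation,
                              grid$emission, config$noiseSd),
        cells = simulateEEM(config$dyes, cellAmp, grid$excitation,
                            grid$emission, config$noiseSd))
    })
  }
  EEMSet(samples)
}

#' Deterministic 6-sample fixture on a 5x5 grid
#'
#' Small integer-valued images defined by closed-form modular arithmetic (no
#' RNG), for exact, hand-checkable unit tests of the feature pipeline.
#' Samples 1-3 are IRR, 4-6 NonIRR.
#'
#' @return an [EEMSet-class] with 6 compounds on a 5x5 grid.
#' @export
tinyFixture <- function() {
  ex <- seq(400, 480, by = 20)
  em <- seq(500, 580, by = 20)
  idx <- expand.grid(i = 1:5, j = 1:5)  # i = emission row, j = excitation col
  samples <- lapply(1:6, function(k) {
    ctl <- matrix(((3 * idx$i + 5 * idx$j + idx$i * idx$j * k) %% 13) + 1, 5, 5)
    cel <- matrix(((2 * idx$i + 7 * idx$j + (idx$i + idx$j) * k + k * k) %% 11) + 1, 5, 5)
    lab <- if (k <= 3) "IRR" else "NonIRR"
    CompoundSample(sprintf("FIX_%d", k), lab,
                   EEMImage(ctl, ex, em), EEMImage(cel, ex, em))
  })
  EEMSet(samples)
}
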