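# Metrics and validation protocols: leave-one-out cross-validation (61+1 in
# the 62-compound design) and the stratified hold-out split (43 training /
# 19 test), across the three classification tasks.

#' Specificity, sensitivity and their sum
#'
#' IRR is the positive class: sensitivity = 100 * TP / (TP + FN) is the
#' percentage of irritants correctly flagged, specificity = 100 * TN /
#' (TN + FP) the percentage of non-irritants correctly cleared, and
#' `sum` their total (chance level 100, maximum 200).
#'
#' @param yTrue,yPred equal-length label vectors (`"IRR"`/`"NonIRR"`).
#' @return named numeric vector `c(specificity, sensitivity, sum)`, percent.
#' @export
confusionMetrics <- function(yTrue, yPred) {
  yTrue <- .asLabelChr(yTrue); yPred <- .asLabelChr(yPred)
  if (length(yTrue) != length(yPred)) stop("label vectors must have equal length")
  if (!all(.CLASS_LEVELS %in% yTrue))
    stop("both classes must be present in yTrue: a metric is undefined otherwise")
  sens <- 100 * sum(yTrue == "IRR" & yPred == "IRR") / sum(yTrue == "IRR")
  spec <- 100 * sum(yTrue == "NonIRR" & yPred == "NonIRR") / sum(yTrue == "NonIRR")
  c(specificity = spec, sensitivity = sens, sum = spec + sens)
}

#' Leave-one-out cross-validation
#'
#' Each compound is tested once by a classifier trained on all others.
#' Two leakage modes are supported: `"strict"` (default) refits the feature
#' extractor inside every fold on the remaining samples, so the held-out
#' compound influences neither feature extraction nor classifier fitting;
#' `"paper_faithful"` fits the extractor once on the full dataset and only
#' the classifier is refitted per fold (the published 61+1 protocol, which
#' leaks the held-out image into the feature space).
#'
#' @param eset an [EEMSet-class] with both classes.
#' @param task classification task, 1-3.
#' @param method registry method name, see [fitClassifier()].
#' @param params method hyperparameters.
#' @param rule,nComponents component selection, see [fitExtractor()].
#' @param leakage `"strict"` or `"paper_faithful"`.
#' @return list with `metrics` (see [confusionMetrics()]) and `predictions`
#'   (one row per compound: id, label, predicted, score, fold).
#' @export
loocv <- function(eset, task, method, params = list(),
                  rule = "fixed", nComponents = 5,
                  leakage = c("strict", "paper_faithful")) {
  stopifnot(is(eset, "EEMSet"))
  leakage <- match.arg(leakage)
  n <- ncol(eset)
  y <- as.character(classLabels(eset))
  if (leakage == "paper_faithful") {
    ext <- fitExtractor(eset, task, rule, nComponents)
    Fall <- extractFeatures(ext, eset)
  }
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    if (leakage == "paper_faithful") {
      Ftr <- Fall[-i, , drop = FALSE]
      Fte <- Fall[i, , drop = FALSE]
    } else {
      ext <- fitExtractor(eset[, -i], task, rule, nComponents)
      Ftr <- extractFeatures(ext, eset[, -i])
      Fte <- extractFeatures(ext, getSample(eset, i))
    }
    model <- fitClassifier(method, Ftr, y[-i], params)
    preds[[i]] <- predictLabels(model, Fte)
  }
  pr <- do.call(rbind, preds)
  out <- data.frame(compound_id = compoundIds(eset), label = y,
                    predicted = as.character(pr$label), score = pr$score,
                    fold = seq_len(n), stringsAsFactors = FALSE)
  list(metrics = confusionMetrics(out$label, out$predicted), predictions = out)
}

#' Stratified training/test split
#'
#' For the study's 34 IRR / 28 Non-IRR design, 9 IRR and 10 Non-IRR
#' compounds are drawn (without replacement, seeded) for the test set,
#' leaving 43 for training; for other class sizes the test set takes
#' `ceiling(0.26 * n_class)` per class. The split is an exact partition.
#'
#' @param eset an [EEMSet-class].
#' @param seed integer seed for the draw.
#' @return list with `training` and `test` [EEMSet-class]s and `testIds`.
#' @export
stratifiedSplit <- function(eset, seed = 1) {
  stopifnot(is(eset, "EEMSet"))
  y <- as.character(classLabels(eset))
  nI <- sum(y == "IRR"); nN <- sum(y == "NonIRR")
  nTest <- if (nI == 34 && nN == 28) c(IRR = 9L, NonIRR = 10L)
           else c(IRR = as.integer(ceiling(0.26 * nI)),
                  NonIRR = as.integer(ceiling(0.26 * nN)))
  if (nI <= nTest[["IRR"]] || nN <= nTest[["NonIRR"]])
    stop("too few samples in a class for a stratified split")
  idx <- .withSeed(seed, c(
    sample(which(y == "IRR"), nTest[["IRR"]]),
    sample(which(y == "NonIRR"), nTest[["NonIRR"]])))
  idx <- sort(idx)
  list(training = eset[, -idx], test = eset[, idx],
       testIds = compoundIds(eset)[idx])
}

.CANONICAL_ORDER <- c("DT", "GM", "3NN", "LDA", "LR", "PDFE")

#' Run the full benchmark across methods, tasks and protocols
#'
#' For the hold-out protocol, features are extracted from the 43 training
#' compounds only; classifiers are fitted on the training features and
#' scored both on the training set ("Training set") and on the unseen test
#' set ("Test set"). The LOOCV protocol reports one aggregated triple per
#' method/task. Rows are ordered DT, GM, 3NN, LDA, LR, PDFE (the table
#' convention); everything is deterministic given `seed`.
#'
#' @param eset an [EEMSet-class].
#' @param methods registry method names.
#' @param tasks subset of 1:3.
#' @param protocols subset of `c("loocv", "holdout")`.
#' @param seed integer seed (drives the hold-out draw).
#' @param leakage LOOCV leakage mode, see [loocv()].
#' @param rule,nComponents component selection, see [fitExtractor()].
#' @param params optional named list of per-method hyperparameter lists.
#' @return data.frame with columns method, task, protocol, specificity,
#'   sensitivity, sum; attributes `seed`, `leakage` and `testIds` record the
#'   protocol metadata needed to reproduce the run.
#' @export
runBenchmark <- function(eset, methods = .CANONICAL_ORDER, tasks = 1:3,
                         protocols = c("loocv", "holdout"), seed = 1,
                         leakage = c("strict", "paper_faithful"),
                         rule = "fixed", nComponents = 5, params = list()) {
  stopifnot(is(eset, "EEMSet"), all(tasks %in% 1:3))
  leakage <- match.arg(leakage)
  protocols <- match.arg(protocols, several.ok = TRUE)
  bad <- setdiff(methods, registryMethods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  methods <- c(intersect(.CANONICAL_ORDER, methods),
               setdiff(methods, .CANONICAL_ORDER))
  split <- if ("holdout" %in% protocols) stratifiedSplit(eset, seed)
  rows <- list()
  cell <- function(expr, method, task, protocol) {
    tryCatch(expr, error = function(e)
      stop(sprintf("benchmark cell failed (method %s, task %d, %s): %s",
                   method, task, protocol, conditionMessage(e)), call. = FALSE))
  }
  for (task in tasks) {
    holdArt <- NULL
    if ("holdout" %in% protocols) {
      ext <- fitExtractor(split$training, task, rule, nComponents)
      holdArt <- list(
        Ftr = extractFeatures(ext, split$training),
        ytr = as.character(classLabels(split$training)),
        Fte = extractFeatures(ext, split$test),
        yte = as.character(classLabels(split$test)))
    }
    for (m in methods) {
      p <- if (!is.null(params[[m]])) params[[m]] else list()
      if ("loocv" %in% protocols) {
        tri <- cell(loocv(eset, task, m, p, rule, nComponents, leakage)$metrics,
                    m, task, "LOOCV")
        rows[[length(rows) + 1]] <- data.frame(method = m, task = task,
          protocol = "LOOCV", t(tri), stringsAsFactors = FALSE)
      }
      if ("holdout" %in% protocols) {
        model <- cell(fitClassifier(m, holdArt$Ftr, holdArt$ytr, p),
                      m, task, "holdout fit")
        for (side in c("Training set", "Test set")) {
          Fx <- if (side == "Training set") holdArt$Ftr else holdArt$Fte
          yx <- if (side == "Training set") holdArt$ytr else holdArt$yte
          tri <- cell(confusionMetrics(yx,
                        as.character(predictLabels(model, Fx)$label)),
                      m, task, side)
          rows[[length(rows) + 1]] <- data.frame(method = m, task = task,
            protocol = side, t(tri), stringsAsFactors = FALSE)
        }
      }
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "seed") <- seed
  attr(rep, "leakage") <- leakage
  if (!is.null(split)) attr(rep, "testIds") <- split$testIds
  rep
}

#' Format a benchmark report for presentation
#'
#' Rounds the metric columns to whole percent (the table convention); the
#' full-precision values stay in the unformatted report.
#'
#' @param report result of [runBenchmark()].
#' @return data.frame with integer-rounded metrics.
#' @export
formatReport <- function(report) {
  for (cl in c("specificity", "sensitivity", "sum"))
    report[[cl]] <- round(report[[cl]])
  report
}
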