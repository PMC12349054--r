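#' Pixel-wise confusion counts
#'
#' Counts true/false positives/negatives between a binary prediction and a
#' binary ground truth, optionally restricted to a region-of-interest mask.
#'
#' @param pred binary (or logical) array/matrix.
#' @param truth binary array of the same shape.
#' @param roi optional binary array; pixels outside it are excluded.
#' @return list with integer `tp`, `tn`, `fp`, `fn` (summing to the number of
#'   evaluated pixels).
#' @export
confusionCounts <- function(pred, truth, roi = NULL) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth)) stop("pred and truth differ in shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusionCounts requires binary inputs")
  keep <- if (is.null(roi)) TRUE else as.logical(roi)
  p <- pred[keep]; t <- truth[keep]
  list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
       fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1))
}

#' Segmentation scores from confusion counts
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' F1 `2TP/(2TP+FP+FN)` and the Dice coefficient, which for binary masks is
#' identically equal to F1. A score whose denominator is zero is reported as
#' `NA` with the `undefined` flag listing the affected metrics, never
#' silently as 0.
#'
#' @param c a list of counts from [confusionCounts()].
#' @return list with `acc`, `se`, `sp`, `f1`, `dice` and `undefined`
#'   (character vector of metrics with empty denominators).
#' @export
segScores <- function(c) {
  n <- c$tp + c$tn + c$fp + c$fn
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  acc <- div(c$tp + c$tn, n, "acc")
  se <- div(c$tp, c$tp + c$fn, "se")
  sp <- div(c$tn, c$tn + c$fp, "sp")
  f1 <- div(2 * c$tp, 2 * c$tp + c$fp + c$fn, "f1")
  list(acc = acc, se = se, sp = sp, f1 = f1, dice = f1, undefined = undef)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation with midranks, which
#' equals the trapezoidal area over all distinct score thresholds: the
#' probability that a random vessel pixel scores higher than a random
#' background pixel, with half credit for ties.
#'
#' @param prob numeric array of scores/probabilities.
#' @param truth binary array of the same shape.
#' @return AUC in `[0, 1]`; `NA` with a warning when `truth` has one class.
#' @export
aucScore <- function(prob, truth) {
  prob <- as.numeric(prob); truth <- as.numeric(truth)
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined: truth contains a single class")
    return(NA_real_)
  }
  r <- rank(prob, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a model over a set of records
#'
#' Runs [predictProb()] on each record, binarizes at `threshold`, and
#' reports per-image and aggregate accuracy, sensitivity, specificity,
#' F1/Dice and AUC.
#'
#' @param model a [VesselNet-class] object.
#' @param records list of records with `image` and `mask`.
#' @param threshold binarization threshold (default 0.5).
#' @return list with `per_image` (data.frame, one row per record) and
#'   `summary` (mean and sd per metric).
#' @export
evaluateModel <- function(model, records, threshold = 0.5) {
  rows <- lapply(records, function(r) {
    pr <- predictProb(model, r$image)
    sc <- segScores(confusionCounts(pr >= threshold, r$mask))
    data.frame(id = r$id %||% NA_character_, Acc = sc$acc, Se = sc$se,
               Sp = sc$sp, F1 = sc$f1, Dice = sc$dice,
               AUC = aucScore(pr, r$mask))
  })
  per <- do.call(rbind, rows)
  num <- per[, c("Acc", "Se", "Sp", "F1", "Dice", "AUC")]
  summary <- list(mean = as.list(colMeans(num, na.rm = TRUE)),
                  sd = as.list(apply(num, 2, stats::sd, na.rm = TRUE)))
  list(per_image = per, summary = summary)
}

#' Write evaluation results as CSV and JSON
#'
#' @param results output of [evaluateModel()].
#' @param csvPath per-image CSV path (columns Acc, Se, Sp, F1, Dice, AUC).
#' @param jsonPath aggregate JSON path (mean and sd per metric).
#' @export
writeMetrics <- function(results, csvPath, jsonPath) {
  utils::write.csv(results$per_image, csvPath, row.names = FALSE)
  jsonlite::write_json(results$summary, jsonPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
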