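## Training loss and evaluation metrics.

#' Joint Dice + binary cross-entropy loss
#'
#' Computes \code{0.5 * BCE + Dice} on logits: BCE is the mean binary
#' cross-entropy of \code{plogis(logits)} against the binary target (evaluated
#' in the numerically stable logit form), and
#' \code{Dice = 1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)} pools all
#' pixels with smoothing \code{eps}.
#'
#' @param logits numeric array of raw network outputs.
#' @param target binary array (values 0/1) of the same shape.
#' @param bceWeight weight of the cross-entropy term (default 0.5).
#' @param diceWeight weight of the Dice term (default 1).
#' @param diceSmooth Dice smoothing constant eps (default 1).
#' @return Non-negative scalar loss.
#' @examples
#' # four pixels, uniform p = 0.5: 0.5 * log(2) + (1 - 3/5)
#' bceDiceLoss(array(0, c(1, 1, 2, 2)), array(c(1, 1, 0, 0), c(1, 1, 2, 2)))
#' @export
bceDiceLoss <- function(logits, target, bceWeight = 0.5, diceWeight = 1.0,
                        diceSmooth = 1.0) {
  if (!identical(dim(logits), dim(target)) &&
      length(logits) != length(target)) {
    stop("logits and target must have the same shape", call. = FALSE)
  }
  if (!all(target %in% c(0, 1))) {
    stop("target must be binary (0/1)", call. = FALSE)
  }
  stopifnot(bceWeight >= 0, diceWeight >= 0)
  z <- as.numeric(logits)
  t <- as.numeric(target)
  bce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  p <- stats::plogis(z)
  dice <- 1 - (2 * sum(p * t) + diceSmooth) / (sum(p) + sum(t) + diceSmooth)
  bceWeight * bce + diceWeight * dice
}

#' Threshold probabilities into a binary mask
#'
#' @param probabilities numeric array with values in [0, 1].
#' @param threshold decision threshold; values \code{>= threshold} map to 1
#'   (the boundary maps to foreground).
#' @return Integer array of 0/1 with the input shape.
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  out <- array(as.integer(probabilities >= threshold), dim(probabilities) %||% length(probabilities))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixelwise confusion counts
#'
#' @param pred,gt binary masks of identical shape.
#' @return Named list with integer counts TP, FP, TN, FN summing to the number
#'   of pixels.
#' @export
confusionCounts <- function(pred, gt) {
  if (length(pred) != length(gt) ||
      (!is.null(dim(pred)) && !is.null(dim(gt)) && !identical(dim(pred), dim(gt)))) {
    stop("pred and gt must have identical shapes", call. = FALSE)
  }
  p <- as.logical(pred)
  g <- as.logical(gt)
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g), FN = sum(!p & g))
}

#' Segmentation metrics from confusion counts
#'
#' IOU = TP / (TP + FP + FN); F1 = 2 Precision Recall / (Precision + Recall);
#' G-mean = sqrt(Sensitivity x Specificity) with Sensitivity = Recall =
#' TP / (TP + FN) and Specificity = TN / (TN + FP). All values are reported on
#' the 0-100 percent scale. When prediction and ground truth are both empty
#' every metric is defined as 100 (and flagged); an empty ground truth with a
#' non-empty prediction gives IOU = F1 = 0.
#'
#' @param counts confusion counts as returned by \code{\link{confusionCounts}}.
#' @return One-row data frame with columns IOU, F1, Precision, Recall,
#'   Specificity, Gmean, flag.
#' @export
metricsFromCounts <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  if (TP + FP + FN == 0) {
    return(data.frame(IOU = 100, F1 = 100, Precision = 100, Recall = 100,
                      Specificity = 100, Gmean = 100, flag = "both-empty",
                      stringsAsFactors = FALSE))
  }
  iou <- TP / (TP + FP + FN)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  specificity <- if (TN + FP > 0) TN / (TN + FP) else 100 / 100
  gmean <- sqrt(recall * specificity)
  data.frame(IOU = 100 * iou, F1 = 100 * f1, Precision = 100 * precision,
             Recall = 100 * recall, Specificity = 100 * specificity,
             Gmean = 100 * gmean, flag = "", stringsAsFactors = FALSE)
}

#' Evaluate paired mask lists
#'
#' Computes per-image metrics from per-image confusion counts and aggregates
#' by the unweighted mean over images (macro average). The micro (pooled
#' pixel) average is attached as attribute \code{"micro"}.
#'
#' @param predictions,groundTruths equal-length lists of binary masks.
#' @return Data frame with one row per image plus a final MEAN row.
#' @export
evaluateDataset <- function(predictions, groundTruths) {
  if (length(predictions) == 0L) stop("empty dataset", call. = FALSE)
  if (length(predictions) != length(groundTruths)) {
    stop("predictions and groundTruths must have equal length", call. = FALSE)
  }
  rows <- vector("list", length(predictions))
  pooled <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in seq_along(predictions)) {
    cc <- confusionCounts(predictions[[i]], groundTruths[[i]])
    pooled <- Map(`+`, pooled, cc)
    rows[[i]] <- cbind(image = as.character(i), metricsFromCounts(cc))
  }
  tab <- do.call(rbind, rows)
  num <- c("IOU", "F1", "Precision", "Recall", "Specificity", "Gmean")
  mean_row <- cbind(image = "MEAN",
                    as.data.frame(as.list(colMeans(tab[, num]))),
                    flag = "")
  out <- rbind(tab, mean_row)
  attr(out, "micro") <- metricsFromCounts(pooled)
  out
}

#' Write a metrics report as CSV
#'
#' @param report data frame from \code{\link{evaluateDataset}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeMetricsCSV <- function(report, path) {
  utils::write.csv(report[, c("image", "IOU", "F1", "Precision", "Recall",
                              "Specificity", "Gmean")],
                   path, row.names = FALSE)
  invisible(path)
}
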