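## TOPSIS multi-criteria model ranking.

#' A models-by-criteria decision matrix
#'
#' @slot values non-negative numeric matrix (models in rows, criteria in
#'   columns), with row and column names.
#' @slot weights criterion weights summing to 1.
#' @slot benefit logical per criterion; TRUE means larger is better.
#' @export
setClass("DecisionMatrix",
  representation(values = "matrix", weights = "numeric", benefit = "logical"))

setValidity("DecisionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 models (rows)")
  if (ncol(v) < 1L) msg <- c(msg, "need at least 1 criterion (column)")
  if (any(v < 0)) msg <- c(msg, "criterion values must be non-negative")
  if (any(colSums(v * v) == 0)) msg <- c(msg, "all-zero criterion column")
  if (length(object@weights) != ncol(v)) msg <- c(msg, "one weight per criterion")
  if (abs(sum(object@weights) - 1) > 1e-8) msg <- c(msg, "weights must sum to 1")
  if (length(object@benefit) != ncol(v)) msg <- c(msg, "one benefit flag per criterion")
  if (length(msg)) msg else TRUE
})

#' Create a decision matrix
#'
#' @param values numeric matrix or data frame of criterion values (models in
#'   rows); row names label the models.
#' @param weights criterion weights; default equal weights.
#' @param benefit logical per criterion, TRUE (default) when larger is better.
#' @return A \linkS4class{DecisionMatrix}.
#' @examples
#' dm <- decisionMatrix(rbind(A = c(F1 = 90, IOU = 80), B = c(85, 75)))
#' topsisScores(dm)
#' @export
decisionMatrix <- function(values, weights = NULL, benefit = NULL) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  if (is.null(rownames(v))) rownames(v) <- paste0("model", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("criterion", seq_len(ncol(v)))
  if (is.null(weights)) weights <- rep(1 / ncol(v), ncol(v))
  if (is.null(benefit)) benefit <- rep(TRUE, ncol(v))
  methods::new("DecisionMatrix", values = v, weights = weights, benefit = benefit)
}

setMethod("show", "DecisionMatrix", function(object) {
  cat(sprintf("DecisionMatrix: %d models x %d criteria\n",
              nrow(object@values), ncol(object@values)))
  print(object@values)
})

#' TOPSIS closeness scores
#'
#' Classic TOPSIS: each criterion column is divided by its Euclidean norm and
#' multiplied by its weight; the ideal (column-wise best) and anti-ideal
#' (column-wise worst) points are taken over the candidate set; each model is
#' scored by its relative closeness \code{d- / (d+ + d-)} where d+ and d- are
#' Euclidean distances to the ideal and anti-ideal. A model that is worst on
#' every criterion scores exactly 0; best on every criterion scores exactly 1.
#' If all rows are identical every distance is zero and all scores are defined
#' as 0.5 (with a warning).
#'
#' @param dm a \linkS4class{DecisionMatrix}.
#' @return Data frame with columns model, score, rank (competition ranking,
#'   1 = best).
#' @export
topsisScores <- function(dm) {
  methods::validObject(dm)
  v <- dm@values
  norms <- sqrt(colSums(v * v))
  r <- sweep(v, 2, norms, "/")
  w <- sweep(r, 2, dm@weights, "*")
  ideal <- ifelse(dm@benefit, apply(w, 2, max), apply(w, 2, min))
  anti <- ifelse(dm@benefit, apply(w, 2, min), apply(w, 2, max))
  dplus <- sqrt(rowSums(sweep(w, 2, ideal, "-")^2))
  dminus <- sqrt(rowSums(sweep(w, 2, anti, "-")^2))
  denom <- dplus + dminus
  score <- ifelse(denom == 0, 0.5, dminus / denom)
  if (any(denom == 0)) {
    warning("identical rows in decision matrix; tied scores set to 0.5")
  }
  data.frame(model = rownames(v), score = as.numeric(score),
             rank = rankFromScores(score), stringsAsFactors = FALSE)
}

#' Competition ranking of scores
#'
#' Descending competition ranking: the best score gets rank 1 and ties share
#' the smaller rank (1, 1, 3, ...).
#'
#' @param scores finite numeric vector.
#' @return Integer ranks.
#' @export
rankFromScores <- function(scores) {
  stopifnot(all(is.finite(scores)))
  vapply(scores, function(s) 1L + sum(scores > s), integer(1))
}

#' Cross-dataset average ranks
#'
#' @param perDatasetRanks named list (one element per dataset) of named rank
#'   vectors over an identical model set.
#' @return Data frame with one column per dataset and a final Average column,
#'   models in rows.
#' @export
averageRankTable <- function(perDatasetRanks) {
  stopifnot(length(perDatasetRanks) >= 1L)
  models <- names(perDatasetRanks[[1L]])
  for (r in perDatasetRanks) {
    if (!setequal(names(r), models)) {
      stop("model sets differ across datasets", call. = FALSE)
    }
  }
  tab <- vapply(perDatasetRanks, function(r) as.numeric(r[models]),
                numeric(length(models)))
  tab <- matrix(tab, nrow = length(models),
                dimnames = list(models, names(perDatasetRanks)))
  data.frame(tab, Average = rowMeans(tab), check.names = FALSE)
}

#' Read a decision matrix from CSV
#'
#' Expects columns \code{model} and one column per criterion (e.g. F1, IOU,
#' Gmean).
#'
#' @param path CSV file path.
#' @param weights,benefit passed to \code{\link{decisionMatrix}}.
#' @return A \linkS4class{DecisionMatrix}.
#' @export
readDecisionMatrixCSV <- function(path, weights = NULL, benefit = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"model" %in% names(tab)) stop("CSV needs a 'model' column", call. = FALSE)
  v <- as.matrix(tab[, setdiff(names(tab), "model"), drop = FALSE])
  rownames(v) <- tab$model
  decisionMatrix(v, weights = weights, benefit = benefit)
}
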