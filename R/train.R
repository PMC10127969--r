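## Training loop, checkpoint evaluation and model comparison reporting.

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture: Adam, batch
#' size 4, initial learning rate 1e-3 cosine-annealed per epoch to 1e-5,
#' flip/crop augmentation, joint 0.5*BCE + Dice loss, best checkpoint chosen
#' by validation IOU.
#'
#' @slot batchSize mini-batch size.
#' @slot lrInit,lrMin initial and final learning rate of the cosine schedule.
#' @slot epochs number of training epochs.
#' @slot bceWeight,diceWeight,diceSmooth loss coefficients.
#' @slot selectionMetric "IOU" or "F1"; maximized on the validation split.
#' @slot evalEvery evaluate the validation split every this many epochs (the
#'   final epoch is always evaluated).
#' @slot hflipProb,vflipProb,cropFraction augmentation parameters.
#' @slot seed training seed (shuffling, augmentation).
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", lrInit = "numeric", lrMin = "numeric",
                 epochs = "integer", bceWeight = "numeric",
                 diceWeight = "numeric", diceSmooth = "numeric",
                 selectionMetric = "character", evalEvery = "integer",
                 hflipProb = "numeric", vflipProb = "numeric",
                 cropFraction = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@lrMin >= object@lrInit) msg <- c(msg, "lrMin must be < lrInit")
  if (!object@selectionMetric %in% c("IOU", "F1")) {
    msg <- c(msg, "selectionMetric must be IOU or F1")
  }
  if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' @param batchSize mini-batch size (default 4).
#' @param lrInit initial learning rate (default 0.001).
#' @param lrMin minimum learning rate of the cosine schedule (default 1e-5).
#' @param epochs training epochs (default 100).
#' @param bceWeight,diceWeight,diceSmooth loss coefficients (0.5, 1, 1).
#' @param selectionMetric validation metric for best-checkpoint selection.
#' @param evalEvery validation frequency in epochs.
#' @param hflipProb,vflipProb,cropFraction augmentation parameters.
#' @param seed training seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(batchSize = 4L, lrInit = 0.001, lrMin = 0.00001,
                        epochs = 100L, bceWeight = 0.5, diceWeight = 1.0,
                        diceSmooth = 1.0, selectionMetric = "IOU",
                        evalEvery = 1L, hflipProb = 0.5, vflipProb = 0.5,
                        cropFraction = c(0.8, 1), seed = 1L) {
  methods::new("TrainConfig", batchSize = as.integer(batchSize),
               lrInit = lrInit, lrMin = lrMin, epochs = as.integer(epochs),
               bceWeight = bceWeight, diceWeight = diceWeight,
               diceSmooth = diceSmooth, selectionMetric = selectionMetric,
               evalEvery = as.integer(evalEvery), hflipProb = hflipProb,
               vflipProb = vflipProb, cropFraction = cropFraction,
               seed = as.integer(seed))
}

#' Cosine-annealed learning rate
#'
#' @param epoch 0-based epoch index.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return The learning rate of that epoch: \code{lrInit} at epoch 0 and
#'   \code{lrMin} at the final epoch.
#' @export
cosineLR <- function(epoch, cfg) {
  Tt <- cfg@epochs
  if (Tt == 1L) return(cfg@lrInit)
  cfg@lrMin + 0.5 * (cfg@lrInit - cfg@lrMin) * (1 + cos(pi * epoch / (Tt - 1)))
}

## One Adam update over parameter environments; state initialized lazily.
adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    if (is.null(state$m[[nm]])) {
      ## moment buffers are private to the optimizer and updated in place
      state$m[[nm]] <- as.numeric(p$grad) * 0
      state$v[[nm]] <- as.numeric(p$grad) * 0
    }
    p$val <- cpp_adam_update(p$val, p$grad, state$m[[nm]], state$v[[nm]],
                             lr, beta1, beta2, bc1, bc2, eps)
  }
  zero_grads(params)
  invisible(NULL)
}

load_split <- function(dataRoot, split) {
  manifest <- jsonlite::read_json(file.path(dataRoot, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- manifest$samples$file[manifest$samples$split == split]
  list(manifest = manifest, files = files)
}

## Read and cache a whole split into memory (desk-scale datasets).
read_split_pairs <- function(dataRoot, split) {
  sp <- load_split(dataRoot, split)
  pairs <- lapply(sp$files, function(f) readPair(dataRoot, split, f))
  names(pairs) <- sp$files
  list(pairs = pairs, manifest = sp$manifest)
}

batch_tensors <- function(pairs, idx, size, mean, sd, augment = NULL,
                          aug_seeds = NULL) {
  B <- length(idx)
  x <- array(0, c(3L, size, size, B))
  y <- array(0, c(1L, size, size, B))
  for (b in seq_len(B)) {
    p <- pairs[[idx[b]]]
    if (!is.null(augment)) {
      p <- augmentPair(p$image, p$mask, augment, aug_seeds[b])
    }
    pp <- preprocessPair(p$image, p$mask, size = size, mean = mean, sd = sd)
    x[, , , b] <- pp$image
    y[1L, , , b] <- pp$mask
  }
  list(x = x, y = y)
}

predict_masks <- function(net, pairs, size, mean, sd, batch = 4L) {
  preds <- vector("list", length(pairs))
  gts <- vector("list", length(pairs))
  idxs <- split(seq_along(pairs), ceiling(seq_along(pairs) / batch))
  for (ii in idxs) {
    bt <- batch_tensors(pairs, ii, size, mean, sd)
    ag_begin(grad = FALSE)
    out <- net_forward(net, nd_input(bt$x), train = FALSE)
    ag_end()
    pr <- stats::plogis(out$val)
    for (b in seq_along(ii)) {
      preds[[ii[b]]] <- binarize(array(pr[1L, , , b], dim(pr)[2:3]))
      gts[[ii[b]]] <- array(bt$y[1L, , , b], dim(bt$y)[2:3])
    }
  }
  list(predictions = preds, groundTruths = gts)
}

#' Train an MBSNet
#'
#' Runs the full recipe: shuffled mini-batches with flip/crop augmentation,
#' preprocessing to the configured input size, forward pass, joint
#' BCE + Dice loss, Adam updates with a per-epoch cosine learning-rate
#' schedule, per-epoch validation, and best-checkpoint retention by the
#' validation selection metric. Fully seeded and deterministic.
#'
#' @param netConfig an \linkS4class{MBSNetConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param dataRoot dataset directory from \code{\link{generateDataset}}.
#' @param checkpointPath where to store the best checkpoint (default: a file
#'   in \code{tempdir()}).
#' @param verbose print per-epoch progress.
#' @return List with \code{checkpoint} (path), \code{history} (per-epoch data
#'   frame with attribute \code{best_epoch}), and \code{net} (final-state
#'   network).
#' @export
trainMBSNet <- function(netConfig, trainCfg, dataRoot,
                        checkpointPath = tempfile(fileext = ".rds"),
                        verbose = FALSE) {
  tr <- read_split_pairs(dataRoot, "train")
  va <- read_split_pairs(dataRoot, "val")
  if (length(tr$pairs) < 1L) stop("empty train split", call. = FALSE)
  if (length(va$pairs) < 1L) stop("empty val split", call. = FALSE)
  size <- netConfig@inputSize[1L]
  norm <- tr$manifest$normalization
  aug <- augmentSpec(trainCfg@hflipProb, trainCfg@vflipProb, trainCfg@cropFraction)

  net <- buildMBSNet(netConfig)
  params <- net_params(net)
  astate <- new.env(parent = emptyenv())
  astate$t <- 0L; astate$m <- list(); astate$v <- list()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(trainCfg@seed)

  hist <- data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                     val_IOU = numeric(), val_F1 = numeric())
  best <- -Inf
  best_epoch <- NA_integer_
  n_tr <- length(tr$pairs)
  for (ep in seq_len(trainCfg@epochs) - 1L) {
    lr <- cosineLR(ep, trainCfg)
    ord <- sample.int(n_tr)
    losses <- numeric()
    for (start in seq(1L, n_tr, by = trainCfg@batchSize)) {
      idx <- ord[start:min(start + trainCfg@batchSize - 1L, n_tr)]
      aug_seeds <- sample.int(.Machine$integer.max - 1L, length(idx))
      bt <- batch_tensors(tr$pairs, idx, size, norm$mean, norm$sd, aug, aug_seeds)
      ag_begin(grad = TRUE)
      out <- net_forward(net, nd_input(bt$x), train = TRUE)
      loss <- op_bce_dice(out, bt$y, trainCfg@bceWeight, trainCfg@diceWeight,
                          trainCfg@diceSmooth)
      if (!is.finite(loss$val)) {
        ag_end()
        stop(sprintf("non-finite loss at epoch %d (lr %.2g)", ep, lr),
             call. = FALSE)
      }
      backward(loss)
      ag_end()
      adam_step(params, astate, lr)
      losses <- c(losses, loss$val)
    }

    do_eval <- (ep %% trainCfg@evalEvery == 0L) || ep == trainCfg@epochs - 1L
    viou <- NA_real_; vf1 <- NA_real_
    if (do_eval) {
      pv <- predict_masks(net, va$pairs, size, norm$mean, norm$sd,
                          trainCfg@batchSize)
      rep_ <- evaluateDataset(pv$predictions, pv$groundTruths)
      mrow <- rep_[rep_$image == "MEAN", ]
      viou <- mrow$IOU; vf1 <- mrow$F1
      sel <- if (trainCfg@selectionMetric == "IOU") viou else vf1
      if (sel > best) {
        best <- sel
        best_epoch <- ep
        saveCheckpoint(net, checkpointPath)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_loss = mean(losses),
                                   val_IOU = viou, val_F1 = vf1))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.6f  loss %.4f  val IOU %s", ep, lr,
                      mean(losses), ifelse(is.na(viou), "-", sprintf("%.2f", viou))))
    }
  }
  attr(hist, "best_epoch") <- best_epoch
  attr(hist, "best_value") <- best
  list(checkpoint = checkpointPath, history = hist, net = net)
}

#' Evaluate a checkpoint on a dataset split
#'
#' @param checkpoint path to a checkpoint from \code{\link{saveCheckpoint}}.
#' @param dataRoot dataset directory.
#' @param split split name.
#' @param outDir optional directory for the per-image metrics CSV and
#'   predicted mask PNGs.
#' @return The metrics report of \code{\link{evaluateDataset}} (per-image rows
#'   plus MEAN). Files whose image and mask sizes disagree are skipped with a
#'   warning and listed in the \code{"failures"} attribute.
#' @export
evaluateCheckpoint <- function(checkpoint, dataRoot, split, outDir = NULL) {
  net <- loadCheckpoint(checkpoint)
  sp <- read_split_pairs(dataRoot, split)
  if (length(sp$pairs) == 0L) stop("empty split", call. = FALSE)
  ## files whose image and mask disagree in size are reported and skipped;
  ## the run continues on the remaining pairs
  ok <- vapply(sp$pairs, function(p) {
    identical(dim(p$image)[1:2], dim(p$mask)[1:2])
  }, logical(1))
  failures <- names(sp$pairs)[!ok]
  for (f in failures) warning("size mismatch between image and mask: ", f)
  sp$pairs <- sp$pairs[ok]
  if (length(sp$pairs) == 0L) stop("no valid image/mask pairs", call. = FALSE)
  size <- net@config@inputSize[1L]
  norm <- sp$manifest$normalization
  pv <- predict_masks(net, sp$pairs, size, norm$mean, norm$sd)
  rep_ <- evaluateDataset(pv$predictions, pv$groundTruths)
  rep_$image <- c(names(sp$pairs), "MEAN")
  attr(rep_, "failures") <- failures
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMetricsCSV(rep_, file.path(outDir, sprintf("metrics_%s.csv", split)))
    for (i in seq_along(pv$predictions)) {
      png::writePNG(pv$predictions[[i]] * 1.0,
                    file.path(outDir, paste0("pred_", names(sp$pairs)[i])))
    }
  }
  rep_
}

#' Compare models by TOPSIS across datasets
#'
#' Builds one F1/IOU/G-mean decision matrix per dataset, scores it with
#' classic TOPSIS, ranks models per dataset, and averages ranks across
#' datasets.
#'
#' @param results data frame with columns dataset, model, F1, IOU, Gmean
#'   (at least two models, identical model sets across datasets).
#' @return List with \code{scores} (per dataset) and \code{rankTable}
#'   (models x datasets with an Average column).
#' @export
reportComparison <- function(results) {
  need <- c("dataset", "model", "F1", "IOU", "Gmean")
  if (!all(need %in% names(results))) {
    stop("results must have columns dataset, model, F1, IOU, Gmean", call. = FALSE)
  }
  datasets <- unique(results$dataset)
  models <- sort(unique(results$model))
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  scores <- list()
  ranks <- list()
  for (ds in datasets) {
    sub <- results[results$dataset == ds, ]
    if (!setequal(sub$model, models)) {
      stop(sprintf("dataset %s does not cover all models", ds), call. = FALSE)
    }
    v <- as.matrix(sub[, c("F1", "IOU", "Gmean")])
    rownames(v) <- sub$model
    sc <- topsisScores(decisionMatrix(v))
    scores[[ds]] <- sc
    ranks[[ds]] <- stats::setNames(sc$rank, sc$model)
  }
  list(scores = scores, rankTable = averageRankTable(ranks))
}
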