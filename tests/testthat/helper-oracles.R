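# Independent oracles and fixtures shared across test files.
# Internal engine functions are reached through the package namespace.

eng <- asNamespace("mbsnet")

# Direct nested-loop 2D convolution on internal (C,H,W,1) arrays; the oracle
# the fast GEMM kernels are checked against.
naive_conv2d <- function(x, w, b, dilation = 1L) {
  Ci <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Co <- dim(w)[1]; k <- dim(w)[3]
  c0 <- (k - 1) / 2
  out <- array(0, c(Co, H, W, 1))
  for (co in seq_len(Co)) for (h in seq_len(H)) for (wq in seq_len(W)) {
    s <- b[co]
    for (ci in seq_len(Ci)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
      hh <- h + dilation * (kh - 1 - c0)
      ww <- wq + dilation * (kw - 1 - c0)
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
        s <- s + w[co, ci, kh, kw] * x[ci, hh, ww, 1]
      }
    }
    out[co, h, wq, 1] <- s
  }
  out
}

# Window-max enumeration oracle for stride-1 window-3 pad-1 max pooling on a
# single-channel (1,H,W,1) map.
naive_maxpool3 <- function(x) {
  H <- dim(x)[2]; W <- dim(x)[3]
  out <- array(0, dim(x))
  for (h in seq_len(H)) for (wq in seq_len(W)) {
    hs <- max(1, h - 1):min(H, h + 1)
    ws <- max(1, wq - 1):min(W, wq + 1)
    out[1, h, wq, 1] <- max(x[1, hs, ws, 1])
  }
  out
}

# Apply a block to an internal-layout array without gradient recording.
run_block <- function(block, x_internal, train = FALSE) {
  eng$ag_begin(grad = FALSE)
  on.exit(eng$ag_end(), add = TRUE)
  eng$mod_forward(block, eng$nd_input(x_internal), train)$val
}

rand_chwn <- function(C, H, W, N = 1L) {
  array(stats::rnorm(C * H * W * N), c(C, H, W, N))
}

# Published five-dataset comparison table (F1, IOU, G-mean and the reported
# TOPSIS column) used as input data for the ranking tests.
published_results <- function() {
  mk <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE,
                dimnames = list(c("UNet", "AttU-Net", "UNet++", "UNeXt", "MBSNet"),
                                c("F1", "IOU", "Gmean", "TOPSIS")))
    m
  }
  list(
    ISIC2018 = mk(87.21, 79.15, 92.54, 0.23829325,
                  85.69, 76.95, 92.27, 0.14954534,
                  83.04, 73.95, 90.08, 0,
                  88.71, 81.22, 93.70, 0.33225513,
                  87.76, 80.17, 92.99, 0.27990629),
    Kvasir   = mk(80.90, 71.99, 89.56, 0.18503661,
                  79.29, 69.73, 89.27, 0.04927065,
                  78.73, 69.26, 88.49, 0,
                  80.79, 72.50, 88.60, 0.19576564,
                  85.29, 77.66, 92.10, 0.5699271),
    BUSI     = mk(63.68, 53.12, 79.92, 0.02332205,
                  66.93, 56.67, 82.51, 0.18599036,
                  67.70, 57.40, 80.93, 0.210357,
                  65.94, 55.22, 79.00, 0.10551958,
                  72.81, 63.21, 82.16, 0.47481101),
    COVID19  = mk(76.78, 65.93, 89.06, 0.26129017,
                  77.01, 66.06, 89.54, 0.27014396,
                  68.61, 56.37, 84.88, 0,
                  75.69, 64.91, 87.26, 0.2220694,
                  76.25, 65.13, 89.59, 0.24649646),
    LGG      = mk(69.03, 59.55, 79.06, 0.25013003,
                  63.26, 54.47, 72.40, 0,
                  68.85, 58.37, 78.97, 0.22191493,
                  69.71, 59.59, 79.84, 0.26303922,
                  69.57, 60.23, 79.10, 0.26491581)
  )
}

# Small dataset where the validation split is an exact copy of the training
# split (the overfitting setup used for the learning checks).
make_overfit_dataset <- function(dir, n = 8L, size = 128L, seed = 42L) {
  cfg <- synthConfig(imageSize = as.integer(size), seed = as.integer(seed))
  generateDataset(cfg, n, split = c(train = 1), dir = dir, overwrite = TRUE)
  dir.create(file.path(dir, "val"), showWarnings = FALSE)
  for (sub in c("images", "masks")) {
    dir.create(file.path(dir, "val", sub), recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(file.path(dir, "train", sub), full.names = TRUE),
              file.path(dir, "val", sub))
  }
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  tr <- m$samples[m$samples$split == "train", ]
  va <- tr
  va$split <- "val"
  m$samples <- rbind(tr, va)
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
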