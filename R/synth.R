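## Synthetic lesion-like image/mask generation, PNG IO, augmentation and
## preprocessing.
##
## Images are H x W x 3 numeric arrays in [0, 1] quantized to 8-bit levels;
## masks are H x W arrays with values in {0, 1}.

#' Configuration of the synthetic lesion generator
#'
#' The generator emulates the shared geometry of single-lesion medical
#' segmentation data: one to a few smooth closed blobs (a circle whose radius
#' is modulated by a low-order random Fourier series), an intensity shift
#' between lesion and background with a blurred boundary, additive Gaussian
#' sensor noise, and optional multiplicative speckle for ultrasound-like
#' texture.
#'
#' @slot imageSize side length in pixels of the square images.
#' @slot nBlobs maximum number of blobs per image (drawn uniformly from
#'   1..nBlobs); between 1 and 3.
#' @slot radiusRange blob base radius as a fraction of the image side,
#'   within (0, 0.5).
#' @slot boundaryRoughness amplitude of the Fourier boundary perturbation.
#' @slot fgContrast intensity shift of the lesion relative to background.
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot speckle enable multiplicative speckle noise.
#' @slot seed base seed of the generator.
#' @export
setClass("SynthConfig",
  representation(imageSize = "integer", nBlobs = "integer",
                 radiusRange = "numeric", boundaryRoughness = "numeric",
                 fgContrast = "numeric", noiseSigma = "numeric",
                 speckle = "logical", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@imageSize < 16L) msg <- c(msg, "imageSize too small")
  if (object@nBlobs < 1L || object@nBlobs > 3L) msg <- c(msg, "nBlobs must be 1-3")
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      any(object@radiusRange >= 0.5) || diff(object@radiusRange) < 0) {
    msg <- c(msg, "radiusRange must be within (0, 0.5)")
  }
  if (object@boundaryRoughness < 0 || object@noiseSigma < 0) {
    msg <- c(msg, "noise parameters must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Create a synthetic generator configuration
#'
#' @param imageSize image side length.
#' @param nBlobs maximum blobs per image (1-3).
#' @param radiusRange blob radius range as a fraction of the image side.
#' @param boundaryRoughness Fourier perturbation amplitude of the boundary.
#' @param fgContrast lesion/background intensity shift.
#' @param noiseSigma additive Gaussian noise sd.
#' @param speckle enable multiplicative speckle.
#' @param seed base seed.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(imageSize = 64L)
#' s <- generateSample(cfg, seed = 7L)
#' range(s$mask)
#' @export
synthConfig <- function(imageSize = 320L, nBlobs = 1L,
                        radiusRange = c(0.12, 0.3), boundaryRoughness = 0.15,
                        fgContrast = 0.35, noiseSigma = 0.05,
                        speckle = FALSE, seed = 1L) {
  methods::new("SynthConfig", imageSize = as.integer(imageSize),
               nBlobs = as.integer(nBlobs), radiusRange = radiusRange,
               boundaryRoughness = boundaryRoughness, fgContrast = fgContrast,
               noiseSigma = noiseSigma, speckle = speckle,
               seed = as.integer(seed))
}

with_local_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

## Separable Gaussian blur with replicate edge padding.
gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mm) {  # along rows (first index)
    H <- nrow(mm)
    idx <- outer(seq_len(H), -r:r, `+`)
    idx[idx < 1L] <- 1L
    idx[idx > H] <- H
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * mm[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

single_blob_mask <- function(size, radiusRange, roughness) {
  cx <- stats::runif(1, 0.3, 0.7) * size
  cy <- stats::runif(1, 0.3, 0.7) * size
  r0 <- stats::runif(1, radiusRange[1], radiusRange[2]) * size
  ax <- stats::runif(1, 0.75, 1.25)  # mild ellipticity
  nh <- 4L
  amp <- roughness * stats::runif(nh, 0.3, 1) / seq(2, 2 + nh - 1)
  ph <- stats::runif(nh, 0, 2 * pi)
  dx <- (matrix(seq_len(size), size, size, byrow = TRUE) - cx) / ax
  dy <- matrix(seq_len(size), size, size) - cy
  th <- atan2(dy, dx)
  rr <- r0 * (1 + Reduce(`+`, lapply(seq_len(nh), function(kk) {
    amp[kk] * cos((kk + 1) * th + ph[kk])
  })))
  (sqrt(dx * dx + dy * dy) <= rr) * 1
}

#' Generate one synthetic image/mask pair
#'
#' Deterministic in \code{(cfg, seed)}: the same pair of arguments always
#' yields byte-identical arrays. Degenerate draws (nearly empty or overly
#' large foreground) are regenerated with a derived sub-seed, with an error
#' after 10 attempts.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param seed sample seed.
#' @return List with \code{image} (H x W x 3 in [0,1], 8-bit quantized),
#'   \code{mask} (H x W in {0,1}), \code{seed} and \code{params}.
#' @export
generateSample <- function(cfg, seed) {
  methods::validObject(cfg)
  size <- cfg@imageSize
  for (try in 0:9) {
    res <- with_local_seed(seed + 97L * try, {
      nb <- sample.int(cfg@nBlobs, 1L)
      mask <- matrix(0, size, size)
      for (b in seq_len(nb)) {
        mask <- pmax(mask, single_blob_mask(size, cfg@radiusRange,
                                            cfg@boundaryRoughness))
      }
      frac <- mean(mask)
      if (frac < 0.005 || frac > 0.6) {
        NULL
      } else {
        soft <- gauss_blur_mat(mask, 1.5)
        bg <- 0.35 + stats::runif(3, -0.05, 0.05)
        fg <- bg + cfg@fgContrast * stats::runif(3, 0.85, 1.15)
        img <- array(0, c(size, size, 3))
        for (ch in 1:3) img[, , ch] <- bg[ch] + (fg[ch] - bg[ch]) * soft
        if (cfg@noiseSigma > 0) {
          img <- img + array(stats::rnorm(length(img), 0, cfg@noiseSigma), dim(img))
        }
        if (cfg@speckle) {
          img <- img * (1 + 0.2 * array(stats::rnorm(length(img)), dim(img)))
        }
        img[img < 0] <- 0
        img[img > 1] <- 1
        img <- round(img * 255) / 255
        list(image = img, mask = mask, seed = seed,
             params = list(nBlobs = nb, foregroundFraction = frac))
      }
    })
    if (!is.null(res)) return(res)
  }
  stop("degenerate blob geometry after 10 attempts; widen radiusRange",
       call. = FALSE)
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{<dir>/<split>/images/*.png} and \code{<dir>/<split>/masks/*.png}
#' (8-bit RGB images, 0/255 grayscale masks) plus \code{manifest.json}
#' recording the configuration, per-sample seeds and the training split's
#' channel mean/sd used for normalization.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param n total number of samples.
#' @param split named fractions (train, val, test) summing to 1.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest, invisibly.
#' @export
generateDataset <- function(cfg, n, split = c(train = 0.7, val = 0.1, test = 0.2),
                            dir, overwrite = FALSE) {
  stopifnot(abs(sum(split) - 1) < 1e-8, n >= 1)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty (use overwrite = TRUE)",
         call. = FALSE)
  }
  counts <- floor(n * split)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  samples <- list()
  i <- 0L
  imgs_train <- list()
  for (sp in names(split)) {
    dir.create(file.path(dir, sp, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, sp, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(counts[[sp]])) {
      i <- i + 1L
      seed_i <- cfg@seed + 131L * i
      s <- generateSample(cfg, seed_i)
      fn <- sprintf("sample_%04d.png", i)
      png::writePNG(s$image, file.path(dir, sp, "images", fn))
      png::writePNG(s$mask, file.path(dir, sp, "masks", fn))
      if (sp == "train") imgs_train[[length(imgs_train) + 1L]] <- s$image
      samples[[length(samples) + 1L]] <-
        list(file = fn, split = sp, seed = seed_i)
    }
  }
  if (length(imgs_train)) {
    pix <- do.call(rbind, lapply(imgs_train, function(im) {
      apply(im, 3, as.vector)
    }))
    norm <- list(mean = colMeans(pix), sd = apply(pix, 2, stats::sd))
  } else {
    norm <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))
  }
  manifest <- list(
    config = list(imageSize = cfg@imageSize, nBlobs = cfg@nBlobs,
                  radiusRange = cfg@radiusRange,
                  boundaryRoughness = cfg@boundaryRoughness,
                  fgContrast = cfg@fgContrast, noiseSigma = cfg@noiseSigma,
                  speckle = cfg@speckle, seed = cfg@seed),
    samples = samples,
    normalization = norm
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read an image/mask pair of a dataset split
#'
#' @param dataRoot dataset directory created by \code{\link{generateDataset}}.
#' @param split split name.
#' @param file file name within the split.
#' @return List with \code{image} (H x W x 3) and \code{mask} (H x W, 0/1).
#' @export
readPair <- function(dataRoot, split, file) {
  img <- png::readPNG(file.path(dataRoot, split, "images", file))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3]
  msk <- png::readPNG(file.path(dataRoot, split, "masks", file))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
  list(image = img, mask = (msk >= 0.5) * 1)
}

#' Data augmentation specification
#'
#' @param hflipProb,vflipProb flip probabilities in [0, 1].
#' @param cropFraction range of the random crop side fraction; \code{c(1, 1)}
#'   disables cropping.
#' @return An augmentation spec list.
#' @export
augmentSpec <- function(hflipProb = 0.5, vflipProb = 0.5,
                        cropFraction = c(0.8, 1)) {
  stopifnot(hflipProb >= 0, hflipProb <= 1, vflipProb >= 0, vflipProb <= 1,
            length(cropFraction) == 2L, cropFraction[1] <= cropFraction[2])
  if (cropFraction[2] > 1) stop("crop larger than image", call. = FALSE)
  structure(list(hflipProb = hflipProb, vflipProb = vflipProb,
                 cropFraction = cropFraction), class = "AugmentationSpec")
}

#' Apply paired geometric augmentation
#'
#' Horizontal flip, vertical flip and random crop (resized back to the
#' original size), applied identically to image and mask; deterministic per
#' seed. The mask stays strictly binary.
#'
#' @param image H x W x 3 array.
#' @param mask H x W binary array.
#' @param spec an \code{\link{augmentSpec}}.
#' @param seed augmentation seed.
#' @return List with augmented \code{image} and \code{mask}.
#' @export
augmentPair <- function(image, mask, spec, seed) {
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]))
  with_local_seed(seed, {
    H <- dim(image)[1L]; W <- dim(image)[2L]
    if (stats::runif(1) < spec$hflipProb) {
      image <- image[, W:1, , drop = FALSE]
      mask <- mask[, W:1, drop = FALSE]
    }
    if (stats::runif(1) < spec$vflipProb) {
      image <- image[H:1, , , drop = FALSE]
      mask <- mask[H:1, , drop = FALSE]
    }
    f <- stats::runif(1, spec$cropFraction[1], spec$cropFraction[2])
    if (f < 1) {
      ch <- max(1L, round(f * H)); cw <- max(1L, round(f * W))
      oy <- sample.int(H - ch + 1L, 1L) - 1L
      ox <- sample.int(W - cw + 1L, 1L) - 1L
      image <- image[oy + seq_len(ch), ox + seq_len(cw), , drop = FALSE]
      mask <- mask[oy + seq_len(ch), ox + seq_len(cw), drop = FALSE]
      image <- resize_image(image, H, W, "bilinear")
      mask <- (resize_image(mask, H, W, "nearest") >= 0.5) * 1
    }
    list(image = image, mask = mask)
  })
}

## Resize an H x W (x C) array with half-pixel-center conventions.
resize_image <- function(x, Ho, Wo, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d2 <- is.null(dim(x)) || length(dim(x)) == 2L
  if (d2) x <- array(x, c(dim(x) %||% length(x), 1L))
  xi <- aperm(x, c(3L, 1L, 2L))
  dim(xi) <- c(dim(xi), 1L)  # (C,H,W,1)
  out <- if (method == "bilinear") {
    cpp_resize_bilinear(xi, as.integer(Ho), as.integer(Wo))
  } else {
    cpp_resize_nearest(xi, as.integer(Ho), as.integer(Wo))
  }
  out <- aperm(array(out, dim(out)[1:3]), c(2L, 3L, 1L))
  if (d2) out <- out[, , 1L] else out
}

#' Preprocess an image/mask pair for the network
#'
#' Bilinear-resizes the image and nearest-resizes the mask to
#' \code{size x size} (half-pixel centers), then normalizes the image per
#' channel as \code{(x - mean) / sd}. The mask is re-binarized after resizing.
#'
#' @param image H x W x 3 array in [0, 1] (or 0-255, which is rescaled).
#' @param mask optional H x W binary array.
#' @param size target side length (default 320).
#' @param mean,sd per-channel normalization constants; defaults 0.5 and 0.25.
#' @return List with \code{image} as a (3, size, size) array and \code{mask}
#'   as a (size, size) binary array (or NULL).
#' @export
preprocessPair <- function(image, mask = NULL, size = 320L,
                           mean = rep(0.5, 3), sd = rep(0.25, 3)) {
  if (max(image) > 1.5) image <- image / 255
  img <- resize_image(image, size, size, "bilinear")
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mean[ch]) / sd[ch]
  out_img <- aperm(img, c(3L, 1L, 2L))
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- (resize_image(mask, size, size, "nearest") >= 0.5) * 1
  }
  list(image = out_img, mask = out_mask)
}
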