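## MBSNet assembly: configuration class, network handle, forward pass,
## complexity accounting and checkpointing.

#' Configuration of an MBSNet network
#'
#' Holds the channel schedule, dilation specification, component toggles and
#' input geometry of an MBSNet. The configuration fully determines the
#' parameter count of the built network.
#'
#' @slot inChannels number of input image channels (3 for RGB).
#' @slot lChannels widths of the five local-branch levels (strictly increasing).
#' @slot gChannels widths of the three global-branch dilated blocks.
#' @slot rateMultiplier dilation rate multiplier r.
#' @slot multiGrid per-block dilation multipliers; effective rates are
#'   \code{rateMultiplier * multiGrid}.
#' @slot useDilated,usePRM,useSE,useSAM,useBranchL,useBranchG,useFCFB component
#'   toggles for the ablation modes; all \code{TRUE} by default.
#' @slot inputSize default (H, W) input geometry; both divisible by 16.
#' @slot seed integer seed used for weight initialization.
#' @export
setClass("MBSNetConfig",
  representation(
    inChannels = "integer", lChannels = "integer", gChannels = "integer",
    rateMultiplier = "integer", multiGrid = "integer",
    useDilated = "logical", usePRM = "logical", useSE = "logical",
    useSAM = "logical", useBranchL = "logical", useBranchG = "logical",
    useFCFB = "logical", inputSize = "integer", seed = "integer"
  )
)

setValidity("MBSNetConfig", function(object) {
  msg <- character()
  if (length(object@lChannels) != 5L || any(diff(object@lChannels) <= 0)) {
    msg <- c(msg, "lChannels must be strictly increasing with length 5")
  }
  if (length(object@gChannels) != 3L) msg <- c(msg, "gChannels must have length 3")
  if (object@rateMultiplier < 1L) msg <- c(msg, "rateMultiplier must be >= 1")
  if (length(object@multiGrid) != 3L || any(object@multiGrid < 1L)) {
    msg <- c(msg, "multiGrid must be 3 positive integers")
  }
  if (length(object@inputSize) != 2L || any(object@inputSize %% 16L != 0L)) {
    msg <- c(msg, "inputSize must be (H, W) with both divisible by 16")
  }
  if (!object@useBranchL && !object@useBranchG) {
    msg <- c(msg, "at least one of branch L and branch G must be enabled")
  }
  if (length(msg)) msg else TRUE
})

#' Create an MBSNet configuration
#'
#' The defaults are the full network: local branch widths 16, 32, 64, 128,
#' 256, global branch widths 16, 32, 64, dilation rates
#' \code{rateMultiplier * multiGrid = 2 * (1, 2, 4) = (2, 4, 8)}, and all
#' components (PRM, SE, SAM, both branches, FCFB) enabled.
#'
#' @param inChannels number of image channels.
#' @param lChannels widths of the five local-branch levels.
#' @param gChannels widths of the three global-branch blocks.
#' @param rateMultiplier dilation rate multiplier r.
#' @param multiGrid per-block dilation multipliers.
#' @param useDilated use dilated convolution in the global-branch blocks.
#' @param usePRM insert a parallel residual mixer after each local conv.
#' @param useSE insert squeeze-and-excitation after each local level.
#' @param useSAM apply the spatial attention module to the global output.
#' @param useBranchL,useBranchG enable the local / global branch.
#' @param useFCFB use feature cross-fusion in the decoder.
#' @param inputSize default (H, W) input geometry.
#' @param seed seed for weight initialization.
#' @return An \linkS4class{MBSNetConfig} object.
#' @examples
#' cfg <- mbsnetConfig(inputSize = c(64L, 64L))
#' dilationRates(cfg)
#' @export
mbsnetConfig <- function(inChannels = 3L,
                         lChannels = c(16L, 32L, 64L, 128L, 256L),
                         gChannels = c(16L, 32L, 64L),
                         rateMultiplier = 2L,
                         multiGrid = c(1L, 2L, 4L),
                         useDilated = TRUE, usePRM = TRUE, useSE = TRUE,
                         useSAM = TRUE, useBranchL = TRUE, useBranchG = TRUE,
                         useFCFB = TRUE,
                         inputSize = c(320L, 320L),
                         seed = 1L) {
  methods::new("MBSNetConfig",
    inChannels = as.integer(inChannels), lChannels = as.integer(lChannels),
    gChannels = as.integer(gChannels),
    rateMultiplier = as.integer(rateMultiplier), multiGrid = as.integer(multiGrid),
    useDilated = useDilated, usePRM = usePRM, useSE = useSE, useSAM = useSAM,
    useBranchL = useBranchL, useBranchG = useBranchG, useFCFB = useFCFB,
    inputSize = as.integer(inputSize), seed = as.integer(seed))
}

#' Effective dilation rates of a configuration
#'
#' @param config an \linkS4class{MBSNetConfig}.
#' @return Integer vector \code{rateMultiplier * multiGrid}, one rate per
#'   global-branch block.
#' @export
dilationRates <- function(config) {
  config@rateMultiplier * config@multiGrid
}

#' An MBSNet network handle
#'
#' Opaque handle over the learnable tensors of a built network, organized by
#' branch and level. Use \code{\link{forward}} for inference,
#' \code{\link{countParameters}} / \code{\link{countMACs}} for complexity, and
#' \code{\link{saveCheckpoint}} / \code{\link{loadCheckpoint}} to persist it.
#'
#' @slot config the \linkS4class{MBSNetConfig} the network was built from.
#' @slot state environment holding modules, parameters and buffers.
#' @export
setClass("MBSNet", representation(config = "MBSNetConfig", state = "environment"))

#' Build an MBSNet from a configuration
#'
#' Assembles the three branches: the five-level local branch (3x3 conv, PRM,
#' SE per level with 2x2 max pooling between levels), the three-block global
#' branch (multi-grid dilated blocks with 2x2 average pooling, fusing the
#' same-level local output before each block, SAM on the final output), and
#' the fusion decoder (skip-connected upsampling of the local stream to 1/4
#' scale, then two feature cross-fusion stages to full resolution and a 1x1
#' logit head). Disabled components are replaced by identities (PRM/SE/SAM),
#' plain convolution (dilated), or drop a branch entirely.
#'
#' @param config an \linkS4class{MBSNetConfig}.
#' @return An \linkS4class{MBSNet} handle.
#' @examples
#' net <- buildMBSNet(mbsnetConfig(inputSize = c(64L, 64L)))
#' countParameters(net)
#' @export
buildMBSNet <- function(config) {
  methods::validObject(config)
  st <- new.env(parent = emptyenv())
  st$mods <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config@seed)

  lc <- config@lChannels
  gc_ <- config@gChannels
  rates <- dilationRates(config)

  add <- function(name, m) st$mods[[name]] <- m

  if (config@useBranchL) {
    prev <- config@inChannels
    for (i in 1:5) {
      add(sprintf("l%d.lead", i), mod_conv_unit(prev, lc[i], 3L))
      add(sprintf("l%d.prm", i), if (config@usePRM) mod_prm(lc[i]) else mod_identity())
      add(sprintf("l%d.se", i), if (config@useSE) mod_se(lc[i], 4L) else mod_identity())
      prev <- lc[i]
    }
  }

  if (config@useBranchG) {
    prev <- config@inChannels
    for (i in 1:3) {
      if (config@useBranchL) {
        add(sprintf("g%d.fuse", i), mod_conv_unit(prev + lc[i], gc_[i], 1L))
        add(sprintf("g%d.block", i),
            mod_dilated_block(gc_[i], gc_[i], rates[i], config@useDilated))
      } else {
        add(sprintf("g%d.block", i),
            mod_dilated_block(prev, gc_[i], rates[i], config@useDilated))
      }
      prev <- gc_[i]
    }
    add("g.sam", if (config@useSAM) mod_sam(gc_[3]) else mod_identity())
  }

  dec_c <- if (config@useBranchL) lc[3] else gc_[3]  # stream width at 1/4 scale
  if (config@useBranchL) {
    add("dec.up4", mod_upconv(lc[5], lc[4]))
    add("dec.merge4", mod_conv_unit(2L * lc[4], lc[4], 3L))
    add("dec.up3", mod_upconv(lc[4], lc[3]))
    add("dec.merge3", mod_conv_unit(2L * lc[3], lc[3], 3L))
  }

  c_half <- dec_c %/% 2L
  c_quarter <- dec_c %/% 4L
  if (config@useBranchL && config@useBranchG) {
    if (config@useFCFB) {
      add("f.fcfb1", mod_fcfb(dec_c, c_half))
      add("f.fcfb2", mod_fcfb(c_half, c_quarter))
    } else {
      add("f.gup1", mod_upconv(dec_c, c_half))
      add("f.gup2", mod_upconv(c_half, c_quarter))
      add("f.lup1", mod_upconv(dec_c, c_half))
      add("f.lup2", mod_upconv(c_half, c_quarter))
    }
    add("head", mod_conv_unit(2L * c_quarter, 1L, 1L, norm = FALSE, act = "none"))
  } else {
    add("f.up1", mod_upconv(dec_c, c_half))
    add("f.up2", mod_upconv(c_half, c_quarter))
    add("head", mod_conv_unit(c_quarter, 1L, 1L, norm = FALSE, act = "none"))
  }

  methods::new("MBSNet", config = config, state = st)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

## Internal forward pass on a (C,H,W,N) node; returns the logits node.
net_forward <- function(net, x, train = FALSE) {
  cfg <- net@config
  mods <- net@state$mods
  f <- function(name, v) mod_forward(mods[[name]], v, train)

  l_out <- vector("list", 5L)
  if (cfg@useBranchL) {
    h <- x
    for (i in 1:5) {
      if (i > 1L) h <- op_maxpool(h, 2L, 2L, 0L)
      h <- f(sprintf("l%d.lead", i), h)
      h <- f(sprintf("l%d.prm", i), h)
      h <- f(sprintf("l%d.se", i), h)
      l_out[[i]] <- h
    }
  }

  g <- NULL
  if (cfg@useBranchG) {
    g <- x
    for (i in 1:3) {
      if (i > 1L) g <- op_avgpool2(g)
      if (cfg@useBranchL) {
        g <- f(sprintf("g%d.fuse", i), op_concat_c(list(g, l_out[[i]])))
      }
      g <- f(sprintf("g%d.block", i), g)
    }
    g <- f("g.sam", g)
  }

  l_dec <- NULL
  if (cfg@useBranchL) {
    d4 <- f("dec.up4", l_out[[5]])
    m4 <- f("dec.merge4", op_concat_c(list(d4, l_out[[4]])))
    d3 <- f("dec.up3", m4)
    l_dec <- f("dec.merge3", op_concat_c(list(d3, l_out[[3]])))
  }

  if (cfg@useBranchL && cfg@useBranchG) {
    if (cfg@useFCFB) {
      s <- mod_forward(mods[["f.fcfb1"]], list(g = g, l = l_dec), train)
      s <- mod_forward(mods[["f.fcfb2"]], s, train)
      merged <- op_concat_c(list(s$g, s$l))
    } else {
      sg <- f("f.gup2", f("f.gup1", g))
      sl <- f("f.lup2", f("f.lup1", l_dec))
      merged <- op_concat_c(list(sg, sl))
    }
  } else {
    stream <- if (cfg@useBranchL) l_dec else g
    merged <- f("f.up2", f("f.up1", stream))
  }
  f("head", merged)
}

#' Run MBSNet inference
#'
#' @param net an \linkS4class{MBSNet} handle.
#' @param images numeric array of shape (n, channels, H, W) with H and W
#'   divisible by 16.
#' @param ... unused.
#' @return Logits array of shape (n, 1, H, W). Apply \code{plogis} and
#'   \code{\link{binarize}} to obtain masks.
#' @export
setGeneric("forward", function(net, images, ...) standardGeneric("forward"))

#' @rdname forward
#' @export
setMethod("forward", "MBSNet", function(net, images, ...) {
  d <- dim(images)
  if (length(d) != 4L || d[2L] != net@config@inChannels) {
    stop(sprintf("expected images of shape (n, %d, H, W)", net@config@inChannels),
         call. = FALSE)
  }
  if (any(d[3:4] %% 16L != 0L)) {
    stop("input H and W must be divisible by 16", call. = FALSE)
  }
  ag_begin(grad = FALSE)
  on.exit(ag_end(), add = TRUE)
  out <- net_forward(net, nd_input(as_internal(images)), train = FALSE)
  as_public(out$val)
})

#' Count learnable parameters
#'
#' @param net an \linkS4class{MBSNet} handle.
#' @return Total number of entries across all learnable tensors (integer-valued
#'   numeric).
#' @export
countParameters <- function(net) {
  sum(vapply(net_params(net), function(p) length(p$val), numeric(1)))
}

net_params <- function(net) {
  out <- list()
  for (nm in names(net@state$mods)) {
    out <- c(out, module_params(net@state$mods[[nm]], paste0(nm, ".")))
  }
  out
}

net_buffers <- function(net) {
  out <- list()
  for (nm in names(net@state$mods)) {
    out <- c(out, module_buffers(net@state$mods[[nm]], paste0(nm, ".")))
  }
  out
}

#' Count multiply-accumulate operations
#'
#' Counts the MACs of convolution and linear layers for a single input of the
#' given size (Cout x H' x W' x Cin x k^2 / groups per convolution);
#' normalization, activation and pooling are not counted.
#'
#' @param net an \linkS4class{MBSNet} handle.
#' @param inputSize (H, W) input geometry; defaults to the configured size.
#' @return Total MACs as a numeric (divide by 1e9 for the G scale).
#' @export
countMACs <- function(net, inputSize = net@config@inputSize) {
  if (any(inputSize %% 16L != 0L)) {
    stop("input H and W must be divisible by 16", call. = FALSE)
  }
  the$macs <- new.env(parent = emptyenv())
  the$macs$total <- 0
  on.exit({ the$macs <- NULL }, add = TRUE)
  ag_begin(grad = FALSE)
  on.exit(ag_end(), add = TRUE)
  x <- nd_input(array(0, c(net@config@inChannels, inputSize[1L], inputSize[2L], 1L)))
  net_forward(net, x, train = FALSE)
  the$macs$total
}

#' @describeIn buildMBSNet display a summary of a built network.
#' @param object an \linkS4class{MBSNet} handle.
#' @export
setMethod("show", "MBSNet", function(object) {
  cfg <- object@config
  cat("MBSNet network\n")
  cat(sprintf("  local branch:  %s (%s)\n",
              if (cfg@useBranchL) paste(cfg@lChannels, collapse = "-") else "off",
              paste0(c("PRM", "SE")[c(cfg@usePRM, cfg@useSE)], collapse = "+")))
  cat(sprintf("  global branch: %s, rates (%s)%s\n",
              if (cfg@useBranchG) paste(cfg@gChannels, collapse = "-") else "off",
              paste(dilationRates(cfg), collapse = ", "),
              if (cfg@useSAM) ", SAM" else ""))
  cat(sprintf("  decoder:       %s\n", if (cfg@useFCFB) "cross-fusion (FCFB)" else "plain"))
  cat(sprintf("  parameters:    %s\n", format(countParameters(object), big.mark = ",")))
})

setMethod("show", "MBSNetConfig", function(object) {
  cat("MBSNetConfig\n")
  cat(sprintf("  lChannels: %s  gChannels: %s\n",
              paste(object@lChannels, collapse = ","),
              paste(object@gChannels, collapse = ",")))
  cat(sprintf("  rates: %s  input: %dx%d  seed: %d\n",
              paste(dilationRates(object), collapse = ","),
              object@inputSize[1], object@inputSize[2], object@seed))
  tg <- c(dilated = object@useDilated, prm = object@usePRM, se = object@useSE,
          sam = object@useSAM, branchL = object@useBranchL,
          branchG = object@useBranchG, fcfb = object@useFCFB)
  cat("  toggles:", paste(names(tg)[tg], collapse = " "), "\n")
})

## ----------------------------------------------------------- checkpointing ----

#' Save / load a network checkpoint
#'
#' A checkpoint is a single file holding the serialized configuration, all
#' parameter tensors and all batch-norm buffers by hierarchical name; a
#' save/load round trip restores the network bit-exactly.
#'
#' @param net an \linkS4class{MBSNet} handle.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the restored \linkS4class{MBSNet}.
#' @export
saveCheckpoint <- function(net, path) {
  ps <- net_params(net)
  bs <- net_buffers(net)
  obj <- list(
    config = net@config,
    params = lapply(ps, function(p) p$val),
    buffers = lapply(bs, function(b) list(running_mean = b$running_mean,
                                          running_var = b$running_var))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  net <- buildMBSNet(obj$config)
  ps <- net_params(net)
  stopifnot(identical(sort(names(ps)), sort(names(obj$params))))
  for (nm in names(obj$params)) ps[[nm]]$val <- obj$params[[nm]]
  bs <- net_buffers(net)
  for (nm in names(obj$buffers)) {
    bs[[nm]]$running_mean <- obj$buffers[[nm]]$running_mean
    bs[[nm]]$running_var <- obj$buffers[[nm]]$running_var
  }
  net
}
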