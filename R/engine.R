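## Reverse-mode differentiation engine.
##
## Feature maps use the internal layout (C, H, W, N) so that per-channel
## statistics are row operations and per-position channel statistics are
## column operations on the natural matrix view `matrix(x, nrow = C)`.
## The public API of the package presents arrays as (N, C, H, W); conversion
## happens at the block/network boundary (see as_internal/as_public).
##
## A forward pass in training mode records every operation on a tape; each
## taped node keeps the values its backward closure needs. backward() walks
## the tape in reverse and accumulates gradients into parameter environments.

the <- new.env(parent = emptyenv())
the$grad_on <- FALSE
the$tape <- NULL
the$macs <- NULL   # when non-NULL, conv/linear ops add their MAC counts

ag_begin <- function(grad = TRUE) {
  the$grad_on <- grad
  the$tape <- new.env(parent = emptyenv())
  the$tape$nodes <- vector("list", 256L)
  the$tape$n <- 0L
  invisible(NULL)
}

ag_end <- function() {
  the$grad_on <- FALSE
  the$tape <- NULL
  invisible(NULL)
}

tape_push <- function(nd) {
  tp <- the$tape
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  invisible(NULL)
}

## Create a graph node. Outside grad mode nodes are plain lists (no tape).
emit <- function(val, parents = list(), backfn = NULL, param = NULL) {
  if (!the$grad_on) return(list(val = val))
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  nd$grad <- NULL
  tape_push(nd)
  nd
}

nd_input <- function(val) list(val = val)

nd_param <- function(p) emit(p$val, param = p)

acc_grad <- function(node, g) {
  if (!is.environment(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

backward <- function(loss_node) {
  stopifnot(is.environment(loss_node))
  loss_node$grad <- 1
  tp <- the$tape
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backfn)) {
      gs <- nd$backfn(nd$grad)
      ps <- nd$parents
      for (j in seq_along(ps)) if (!is.null(gs[[j]])) acc_grad(ps[[j]], gs[[j]])
    }
    if (!is.null(nd$param)) {
      p <- nd$param
      p$grad <- if (is.null(p$grad)) nd$grad else p$grad + nd$grad
    }
    tp$nodes[[i]] <- NULL  # free activations as soon as they are consumed
  }
  invisible(NULL)
}

## ------------------------------------------------------------ parameters ----

new_param <- function(val, name = "") {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$name <- name
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---------------------------------------------------------------- layout ----

as_internal <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  aperm(x, c(2L, 3L, 4L, 1L))  # (N,C,H,W) -> (C,H,W,N)
}

as_public <- function(x) aperm(x, c(4L, 1L, 2L, 3L))  # (C,H,W,N) -> (N,C,H,W)

chw_dims <- function(v) {
  d <- dim(v)
  list(C = d[1L], H = d[2L], W = d[3L], N = d[4L])
}

## -------------------------------------------------------------- conv ops ----

count_macs_add <- function(m) {
  if (!is.null(the$macs)) the$macs$total <- the$macs$total + m
  invisible(NULL)
}

op_conv <- function(x, pw, pb, dilation = 1L) {
  d <- chw_dims(x$val)
  wd <- dim(pw$val)
  if (wd[2L] != d$C) {
    stop(sprintf("channel mismatch: expected %d input channels, received %d",
                 wd[2L], d$C), call. = FALSE)
  }
  val <- cpp_conv2d_fw(x$val, pw$val, pb$val, as.integer(dilation))
  count_macs_add(as.numeric(wd[1L]) * d$H * d$W * wd[2L] * wd[3L] * wd[4L])
  if (!the$grad_on) return(list(val = val))
  nw <- nd_param(pw); nb <- nd_param(pb)
  xval <- x$val; wval <- pw$val
  want_gx <- is.environment(x)  # leaf inputs do not need a gradient
  emit(val, parents = list(x, nw, nb), backfn = function(g) {
    r <- cpp_conv2d_bw(xval, wval, g, as.integer(dilation), want_gx)
    list(r$gx, r$gw, r$gb)
  })
}

op_dwconv <- function(x, pw, pb) {
  d <- chw_dims(x$val)
  val <- cpp_dwconv_fw(x$val, pw$val, pb$val)
  count_macs_add(as.numeric(d$C) * d$H * d$W * 9)
  if (!the$grad_on) return(list(val = val))
  nw <- nd_param(pw); nb <- nd_param(pb)
  xval <- x$val; wval <- pw$val
  emit(val, parents = list(x, nw, nb), backfn = function(g) {
    r <- cpp_dwconv_bw(xval, wval, g)
    list(r$gx, r$gw, r$gb)
  })
}

## Fused convolution + batch norm + ReLU/identity: one kernel call per
## direction instead of three tape nodes. Semantics identical to
## op_conv |> op_batchnorm |> op_relu.
op_conv_bn_act <- function(x, pw, pb, pg, pbeta, buf, train, relu, dilation = 1L) {
  d <- chw_dims(x$val)
  wd <- dim(pw$val)
  if (wd[2L] != d$C) {
    stop(sprintf("channel mismatch: expected %d input channels, received %d",
                 wd[2L], d$C), call. = FALSE)
  }
  z <- cpp_conv2d_fw(x$val, pw$val, pb$val, as.integer(dilation))
  count_macs_add(as.numeric(wd[1L]) * d$H * d$W * wd[2L] * wd[3L] * wd[4L])
  if (train) {
    st <- cpp_bn_stats(z)
    mu <- st$mu
    v <- st$var
    buf$running_mean <- (1 - buf$momentum) * buf$running_mean + buf$momentum * mu
    buf$running_var <- (1 - buf$momentum) * buf$running_var + buf$momentum * v
  } else {
    mu <- buf$running_mean
    v <- buf$running_var
  }
  invstd <- 1 / sqrt(v + buf$eps)
  a <- pg$val * invstd
  s <- pbeta$val - a * mu
  y <- cpp_affine_act(z, a, s, relu)
  if (!the$grad_on) return(list(val = y))
  nw <- nd_param(pw); nb <- nd_param(pb)
  ng <- nd_param(pg); nbe <- nd_param(pbeta)
  xval <- x$val; wval <- pw$val; gamma <- pg$val
  want_gx <- is.environment(x)
  emit(y, parents = list(x, nw, nb, ng, nbe), backfn = function(g) {
    r <- cpp_cbr_bw(g, z, xval, wval, gamma, mu, invstd, a, s,
                    as.integer(dilation), train, relu, want_gx)
    list(r$gx, r$gw, r$gb, r$dgamma, r$dbeta)
  })
}

## ----------------------------------------------------------- pooling ops ----

op_maxpool <- function(x, k, stride, pad) {
  r <- cpp_maxpool_fw(x$val, as.integer(k), as.integer(stride), as.integer(pad))
  if (!the$grad_on) return(list(val = r$out))
  xdim <- dim(x$val)
  amax <- r$argmax
  emit(r$out, parents = list(x), backfn = function(g) {
    list(cpp_maxpool_bw(g, amax, as.integer(xdim)))
  })
}

op_avgpool2 <- function(x) {
  val <- cpp_avgpool2_fw(x$val)
  if (!the$grad_on) return(list(val = val))
  xdim <- dim(x$val)
  emit(val, parents = list(x), backfn = function(g) {
    list(cpp_avgpool2_bw(g, as.integer(xdim)))
  })
}

op_up2 <- function(x) {
  d <- chw_dims(x$val)
  val <- cpp_resize_bilinear(x$val, 2L * d$H, 2L * d$W)
  if (!the$grad_on) return(list(val = val))
  xdim <- dim(x$val)
  emit(val, parents = list(x), backfn = function(g) {
    list(cpp_resize_bilinear_bw(g, as.integer(xdim)))
  })
}

## ---------------------------------------------------------- normalization ----

## Batch normalization over (H, W, N) per channel. Buffers live in `buf`
## (running_mean, running_var, momentum 0.1, eps 1e-5); biased batch variance.
op_batchnorm <- function(x, pg, pb, buf, train) {
  if (train) {
    st <- cpp_bn_stats(x$val)
    mu <- st$mu
    v <- st$var
    buf$running_mean <- (1 - buf$momentum) * buf$running_mean + buf$momentum * mu
    buf$running_var <- (1 - buf$momentum) * buf$running_var + buf$momentum * v
  } else {
    mu <- buf$running_mean
    v <- buf$running_var
  }
  invstd <- 1 / sqrt(v + buf$eps)
  y <- cpp_bn_apply(x$val, pg$val, pb$val, mu, invstd)
  if (!the$grad_on) return(list(val = y))
  ng <- nd_param(pg); nb <- nd_param(pb)
  gamma <- pg$val
  xval <- x$val
  emit(y, parents = list(x, ng, nb), backfn = function(g) {
    r <- cpp_bn_bw(xval, gamma, mu, invstd, g, train)
    list(r$gx, r$dgamma, r$dbeta)
  })
}

## Layer normalization over the channel axis at every spatial position.
op_layernorm_c <- function(x, pg, pb, eps = 1e-5) {
  r <- cpp_ln_fw(x$val, pg$val, pb$val, eps)
  if (!the$grad_on) return(list(val = r$out))
  ng <- nd_param(pg); nb <- nd_param(pb)
  xval <- x$val; gamma <- pg$val
  emit(r$out, parents = list(x, ng, nb), backfn = function(g) {
    b <- cpp_ln_bw(xval, gamma, r$mu, r$invstd, g)
    list(b$gx, b$dgamma, b$dbeta)
  })
}

## ------------------------------------------------------------ activations ----

op_relu <- function(x) {
  val <- cpp_relu_fw(x$val)
  if (!the$grad_on) return(list(val = val))
  emit(val, parents = list(x), backfn = function(g) list(cpp_relu_bw(val, g)))
}

op_gelu <- function(x) {
  val <- cpp_gelu_fw(x$val)
  if (!the$grad_on) return(list(val = val))
  xv <- x$val
  emit(val, parents = list(x), backfn = function(g) list(cpp_gelu_bw(xv, g)))
}

op_sigmoid <- function(x) {
  val <- cpp_sigmoid_fw(x$val)
  if (!the$grad_on) return(list(val = val))
  emit(val, parents = list(x), backfn = function(g) list(g * val * (1 - val)))
}

## --------------------------------------------------------- shape plumbing ----

op_add <- function(a, b) {
  stopifnot(identical(dim(a$val), dim(b$val)))
  val <- a$val + b$val
  if (!the$grad_on) return(list(val = val))
  emit(val, parents = list(a, b), backfn = function(g) list(g, g))
}

## x: (C,H,W,N); s: (1,H,W,N) broadcast-added over channels.
op_add_spatial <- function(x, s) {
  d <- chw_dims(x$val)
  val <- x$val + rep(as.vector(s$val), each = d$C)
  dim(val) <- dim(x$val)
  if (!the$grad_on) return(list(val = val))
  sdim <- dim(s$val)
  emit(val, parents = list(x, s), backfn = function(g) {
    gs <- colSums(matrix(g, nrow = d$C))
    dim(gs) <- sdim
    list(g, gs)
  })
}

## Per-channel multiplicative gate g: (C,N) applied to x: (C,H,W,N).
op_scale_channels <- function(x, gate) {
  val <- cpp_scale_channels_fw(x$val, gate$val)
  if (!the$grad_on) return(list(val = val))
  xval <- x$val
  gval <- gate$val
  emit(val, parents = list(x, gate), backfn = function(g) {
    r <- cpp_scale_channels_bw(xval, gval, g)
    list(r$gx, matrix(r$gg, nrow = dim(xval)[1L]))
  })
}

## Global average pool to a (C, N) matrix.
op_gap <- function(x) {
  d <- chw_dims(x$val)
  val <- matrix(cpp_gap_fw(x$val), nrow = d$C)
  if (!the$grad_on) return(list(val = val))
  xdim <- dim(x$val)
  emit(val, parents = list(x), backfn = function(g) {
    hw <- d$H * d$W
    gx <- vapply(seq_len(d$N), function(n) rep(g[, n] / hw, times = hw),
                 numeric(d$C * hw))
    dim(gx) <- xdim
    list(gx)
  })
}

## Dense layer on (In, N) column vectors.
op_linear <- function(x, pw, pb) {
  val <- pw$val %*% x$val + pb$val
  count_macs_add(as.numeric(nrow(pw$val)) * ncol(pw$val))
  if (!the$grad_on) return(list(val = val))
  nw <- nd_param(pw); nb <- nd_param(pb)
  xval <- x$val; wval <- pw$val
  emit(val, parents = list(x, nw, nb), backfn = function(g) {
    list(crossprod(wval, g), g %*% t(xval), rowSums(g))
  })
}

## Column-wise softmax on a (C, N) matrix.
op_softmax_cols <- function(x) {
  z <- x$val
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  val <- e / rep(colSums(e), each = nrow(e))
  if (!the$grad_on) return(list(val = val))
  emit(val, parents = list(x), backfn = function(g) {
    s <- colSums(g * val)
    list(val * (g - rep(s, each = nrow(val))))
  })
}

## Concatenate two maps along the channel axis.
op_concat_c <- function(xs) {
  stopifnot(length(xs) == 2L)
  ca <- dim(xs[[1L]]$val)[1L]
  cb <- dim(xs[[2L]]$val)[1L]
  out <- cpp_concat2(xs[[1L]]$val, xs[[2L]]$val)
  if (!the$grad_on) return(list(val = out))
  emit(out, parents = xs, backfn = function(g) {
    r <- cpp_split2(g, ca, cb)
    list(r$a, r$b)
  })
}

## Attention-weighted channel sum: V (C,H,W,N) and a (C,N) -> (1,H,W,N).
op_chan_weighted_sum <- function(v, a) {
  d <- chw_dims(v$val)
  val <- array(0, c(1L, d$H, d$W, d$N))
  for (n in seq_len(d$N)) {
    val[1L, , , n] <- colSums(matrix(v$val[, , , n], nrow = d$C) * as.vector(a$val[, n]))
  }
  if (!the$grad_on) return(list(val = val))
  vval <- v$val; aval <- a$val
  emit(val, parents = list(v, a), backfn = function(g) {
    gv <- array(0, dim(vval))
    ga <- matrix(0, d$C, d$N)
    for (n in seq_len(d$N)) {
      gsn <- as.vector(g[1L, , , n])
      gv[, , , n] <- rep(gsn, each = d$C) * as.vector(aval[, n])
      ga[, n] <- matrix(vval[, , , n], nrow = d$C) %*% gsn
    }
    list(gv, ga)
  })
}

## ------------------------------------------------------------------ loss ----

## Joint loss: bce_weight * BCE(sigmoid(logits), target) + dice_weight * Dice.
## BCE is computed from logits in the numerically stable form; Dice pools all
## pixels of the batch. Returns a scalar node.
op_bce_dice <- function(logits, target, bce_weight = 0.5, dice_weight = 1.0,
                        dice_smooth = 1.0) {
  z <- logits$val
  t <- target
  npix <- length(z)
  bce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  p <- stats::plogis(z)
  sp <- sum(p); sg <- sum(t); spg <- sum(p * t)
  denom <- sp + sg + dice_smooth
  dice <- 1 - (2 * spg + dice_smooth) / denom
  val <- bce_weight * bce + dice_weight * dice
  if (!the$grad_on) return(list(val = val))
  emit(val, parents = list(logits), backfn = function(g) {
    dbce <- (p - t) / npix
    ddice_dp <- -(2 * t * denom - (2 * spg + dice_smooth)) / denom^2
    dz <- bce_weight * dbce + dice_weight * ddice_dp * p * (1 - p)
    list(g * dz)
  })
}
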