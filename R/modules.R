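## Network building blocks, assembled from engine ops.
##
## A module is an environment with:
##   $type      block kind (for show/debugging)
##   $params    named list of parameter environments
##   $buffers   named list of buffer environments (batch-norm running stats)
##   $children  named list of sub-modules
##   $fwd       function(m, x, train) -> node   (or (m, a, b, train) for FCFB)
## Weight initialization is Kaiming-uniform and draws from the R RNG, so a
## set.seed() before construction makes builds reproducible.

new_module <- function(type, fwd, params = list(), buffers = list(),
                       children = list(), meta = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$fwd <- fwd
  m$params <- params
  m$buffers <- buffers
  m$children <- children
  m$meta <- meta
  m
}

mod_forward <- function(m, x, train = FALSE) m$fwd(m, x, train)

## Recursively collect parameter environments, named by path.
module_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children)) {
    out <- c(out, module_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

module_buffers <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$buffers)) out[[paste0(prefix, nm)]] <- m$buffers[[nm]]
  for (nm in names(m$children)) {
    out <- c(out, module_buffers(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

## ---------------------------------------------------------------- init ----

init_conv_w <- function(co, ci, k) {
  fan_in <- ci * k * k
  bound <- sqrt(6 / fan_in)
  array(stats::runif(co * ci * k * k, -bound, bound), c(co, ci, k, k))
}

init_bias <- function(n, fan_in) {
  bound <- 1 / sqrt(fan_in)
  stats::runif(n, -bound, bound)
}

new_bn_buf <- function(C) {
  b <- new.env(parent = emptyenv())
  b$running_mean <- numeric(C)
  b$running_var <- rep(1, C)
  b$momentum <- 0.1
  b$eps <- 1e-5
  b
}

## ------------------------------------------------- conv + norm + act unit ----

mod_conv_unit <- function(ci, co, k, dilation = 1L, norm = TRUE,
                          act = c("relu", "gelu", "none")) {
  act <- match.arg(act)
  if (dilation < 1) stop("dilation must be >= 1", call. = FALSE)
  if (!k %in% c(1L, 3L)) stop("kernel must be 1 or 3", call. = FALSE)
  params <- list(
    w = new_param(init_conv_w(co, ci, k)),
    b = new_param(init_bias(co, ci * k * k))
  )
  buffers <- list()
  if (norm) {
    params$gamma <- new_param(rep(1, co))
    params$beta <- new_param(numeric(co))
    buffers$bn <- new_bn_buf(co)
  }
  new_module("conv_unit", params = params, buffers = buffers,
             meta = list(ci = ci, co = co, k = k, dilation = dilation,
                         norm = norm, act = act),
             fwd = function(m, x, train) {
    if (m$meta$norm && m$meta$act %in% c("relu", "none")) {
      return(op_conv_bn_act(x, m$params$w, m$params$b, m$params$gamma,
                            m$params$beta, m$buffers$bn, train,
                            relu = m$meta$act == "relu", m$meta$dilation))
    }
    y <- op_conv(x, m$params$w, m$params$b, m$meta$dilation)
    if (m$meta$norm) {
      y <- op_batchnorm(y, m$params$gamma, m$params$beta, m$buffers$bn, train)
    }
    switch(m$meta$act, relu = op_relu(y), gelu = op_gelu(y), none = y)
  })
}

## Depthwise 3x3 with layer normalization over channels and GELU.
mod_dw_unit <- function(C) {
  new_module("dw_unit",
             params = list(
               w = new_param(array(stats::runif(C * 9, -sqrt(6 / 9), sqrt(6 / 9)),
                                   c(C, 3L, 3L))),
               b = new_param(init_bias(C, 9)),
               gamma = new_param(rep(1, C)),
               beta = new_param(numeric(C))
             ),
             meta = list(C = C),
             fwd = function(m, x, train) {
    y <- op_dwconv(x, m$params$w, m$params$b)
    y <- op_layernorm_c(y, m$params$gamma, m$params$beta)
    op_gelu(y)
  })
}

## --------------------------------------------------------------- identity ----

mod_identity <- function() {
  new_module("identity", fwd = function(m, x, train) x)
}

## -------------------------------------------------- parallel residual mixer ----

## Two parallel paths over a C-channel map: a stride-1 window-3 max-pool path
## refined by a 1x1 conv, and a 1x1 conv -> depthwise 3x3 (LN + GELU) path.
## Their concatenation (2C) is fused by a 3x3 conv back to C and added to the
## input, so the output shape equals the input shape exactly.
mod_prm <- function(C) {
  new_module("prm",
             children = list(
               pool_conv = mod_conv_unit(C, C, 1L),
               pre_dw = mod_conv_unit(C, C, 1L),
               dw = mod_dw_unit(C),
               fuse = mod_conv_unit(2L * C, C, 3L)
             ),
             meta = list(C = C),
             fwd = function(m, x, train) {
    a <- mod_forward(m$children$pool_conv, op_maxpool(x, 3L, 1L, 1L), train)
    b <- mod_forward(m$children$dw, mod_forward(m$children$pre_dw, x, train), train)
    y <- mod_forward(m$children$fuse, op_concat_c(list(a, b)), train)
    op_add(y, x)
  })
}

## ------------------------------------------------------ squeeze-and-excite ----

mod_se <- function(C, reduction = 4L) {
  if (reduction > C) stop("SE reduction exceeds channel count", call. = FALSE)
  if (C %% reduction != 0) stop("channels must be divisible by the SE reduction",
                                call. = FALSE)
  Cr <- C %/% reduction
  new_module("se",
             params = list(
               w1 = new_param(matrix(stats::runif(Cr * C, -sqrt(6 / C), sqrt(6 / C)), Cr, C)),
               b1 = new_param(init_bias(Cr, C)),
               w2 = new_param(matrix(stats::runif(C * Cr, -sqrt(6 / Cr), sqrt(6 / Cr)), C, Cr)),
               b2 = new_param(init_bias(C, Cr))
             ),
             meta = list(C = C, reduction = reduction),
             fwd = function(m, x, train) {
    g <- op_gap(x)
    h <- op_relu(op_linear(g, m$params$w1, m$params$b1))
    s <- op_sigmoid(op_linear(h, m$params$w2, m$params$b2))
    op_scale_channels(x, s)
  })
}

## -------------------------------------------------- spatial attention (SAM) ----

## Channel-softmax global context: a = softmax_C(f2(GELU(f1(GAP(x))))) weights
## the channels of a 1x1 value projection V; their weighted sum is a single
## spatial context map added residually to every channel.
mod_sam <- function(C) {
  Cr <- max(1L, C %/% 4L)
  new_module("sam",
             params = list(
               w1 = new_param(matrix(stats::runif(Cr * C, -sqrt(6 / C), sqrt(6 / C)), Cr, C)),
               b1 = new_param(init_bias(Cr, C)),
               w2 = new_param(matrix(stats::runif(C * Cr, -sqrt(6 / Cr), sqrt(6 / Cr)), C, Cr)),
               b2 = new_param(init_bias(C, Cr)),
               wv = new_param(init_conv_w(C, C, 1L)),
               bv = new_param(init_bias(C, C))
             ),
             meta = list(C = C),
             fwd = function(m, x, train) {
    g <- op_gap(x)
    a <- op_softmax_cols(op_linear(op_gelu(op_linear(g, m$params$w1, m$params$b1)),
                                   m$params$w2, m$params$b2))
    v <- op_conv(x, m$params$wv, m$params$bv, 1L)
    s <- op_chan_weighted_sum(v, a)
    op_add_spatial(x, s)
  })
}

## Returns the channel attention vector (C, N) only; used by tests.
sam_attention <- function(m, x) {
  g <- op_gap(x)
  a <- op_softmax_cols(op_linear(op_gelu(op_linear(g, m$params$w1, m$params$b1)),
                                 m$params$w2, m$params$b2))
  a$val
}

## --------------------------------------------------- dilated conv block ----

## 1x1 conv -> dilated 3x3 at `rate` -> 1x1 conv, each BN + ReLU.
mod_dilated_block <- function(ci, co, rate, dilated = TRUE) {
  if (rate < 1) stop("dilation rate must be >= 1", call. = FALSE)
  new_module("dilated_block",
             children = list(
               f1 = mod_conv_unit(ci, co, 1L),
               fg = mod_conv_unit(co, co, 3L, dilation = if (dilated) as.integer(rate) else 1L),
               f2 = mod_conv_unit(co, co, 1L)
             ),
             meta = list(ci = ci, co = co, rate = rate, dilated = dilated),
             fwd = function(m, x, train) {
    mod_forward(m$children$f2,
                mod_forward(m$children$fg,
                            mod_forward(m$children$f1, x, train), train), train)
  })
}

## ------------------------------------------------------- upsampling units ----

## 3x3 conv (BN + ReLU) then bilinear x2 (half-pixel centers).
mod_upconv <- function(ci, co) {
  new_module("upconv",
             children = list(conv = mod_conv_unit(ci, co, 3L)),
             meta = list(ci = ci, co = co),
             fwd = function(m, x, train) {
    op_up2(mod_forward(m$children$conv, x, train))
  })
}

## 1x1 channel projection (BN + ReLU) then bilinear x2.
mod_projup <- function(ci, co) {
  new_module("projup",
             children = list(conv = mod_conv_unit(ci, co, 1L)),
             meta = list(ci = ci, co = co),
             fwd = function(m, x, train) {
    op_up2(mod_forward(m$children$conv, x, train))
  })
}

## ------------------------------------------------- feature cross-fusion ----

## Both streams are upsampled x2 with halved channels; each output is the
## channel-projected upsample of its own stream plus the conv-upsample of the
## other stream ("cross-added").
mod_fcfb <- function(ci, co) {
  new_module("fcfb",
             children = list(
               proj_g = mod_projup(ci, co),
               proj_l = mod_projup(ci, co),
               up_g = mod_upconv(ci, co),
               up_l = mod_upconv(ci, co)
             ),
             meta = list(ci = ci, co = co),
             fwd = function(m, x, train) {
    yg <- x$g; yl <- x$l
    if (!identical(dim(yg$val), dim(yl$val))) {
      stop("FCFB inputs must have identical shapes", call. = FALSE)
    }
    og <- op_add(mod_forward(m$children$proj_g, yg, train),
                 mod_forward(m$children$up_l, yl, train))
    ol <- op_add(mod_forward(m$children$proj_l, yl, train),
                 mod_forward(m$children$up_g, yg, train))
    list(g = og, l = ol)
  })
}
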