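## Public surface for the individual network blocks.
##
## Blocks are constructed with fresh (seeded) weights and applied to arrays in
## the public (n, channel, height, width) layout. They are the same module
## objects the assembled network uses.

#' Construct network blocks
#'
#' Constructors for the reusable MBSNet blocks, applied with
#' \code{\link{blockForward}}. Weights are initialized from the current R RNG
#' state; call \code{set.seed()} first for reproducible weights.
#'
#' \describe{
#'   \item{convUnit}{convolution + optional batch norm + activation; padding
#'     \code{dilation * (kernel - 1) / 2} preserves the spatial dimensions.}
#'   \item{prmBlock}{parallel residual mixer: stride-1 window-3 max-pool path
#'     and 1x1 -> depthwise 3x3 (layer norm + GELU) path, concatenated, fused
#'     by a 3x3 convolution and added to the input.}
#'   \item{seBlock}{squeeze-and-excitation channel gate.}
#'   \item{samBlock}{spatial attention: channel-softmax global context weights
#'     a 1x1 value projection into a single spatial map added residually.}
#'   \item{dilatedBlock}{1x1 -> dilated 3x3 at \code{rate} -> 1x1, each with
#'     batch norm + ReLU.}
#'   \item{upconvBlock}{3x3 convolution (BN + ReLU) then bilinear x2 upsampling
#'     with half-pixel centers.}
#'   \item{fcfbBlock}{feature cross-fusion: both streams are upsampled x2 at
#'     halved width; each output adds the other stream's conv-upsample
#'     (apply with \code{\link{fcfbForward}}).}
#' }
#'
#' @param inChannels,outChannels,channels channel counts.
#' @param kernel kernel size, 1 or 3.
#' @param dilation dilation factor (>= 1).
#' @param norm apply batch normalization.
#' @param activation one of "relu", "gelu", "none".
#' @param reduction SE bottleneck reduction ratio.
#' @param rate dilation rate of the block's middle convolution.
#' @return A block object.
#' @examples
#' set.seed(1)
#' blk <- prmBlock(8L)
#' x <- array(rnorm(8 * 16 * 16), c(1, 8, 16, 16))
#' dim(blockForward(blk, x))
#' @name blocks
NULL

#' @rdname blocks
#' @export
convUnit <- function(inChannels, outChannels, kernel = 3L, dilation = 1L,
                     norm = TRUE, activation = c("relu", "gelu", "none")) {
  mod_conv_unit(as.integer(inChannels), as.integer(outChannels),
                as.integer(kernel), as.integer(dilation), norm,
                match.arg(activation))
}

#' @rdname blocks
#' @export
prmBlock <- function(channels) mod_prm(as.integer(channels))

#' @rdname blocks
#' @export
seBlock <- function(channels, reduction = 4L) {
  mod_se(as.integer(channels), as.integer(reduction))
}

#' @rdname blocks
#' @export
samBlock <- function(channels) mod_sam(as.integer(channels))

#' @rdname blocks
#' @export
dilatedBlock <- function(inChannels, outChannels, rate) {
  mod_dilated_block(as.integer(inChannels), as.integer(outChannels),
                    as.integer(rate))
}

#' @rdname blocks
#' @export
upconvBlock <- function(inChannels, outChannels) {
  mod_upconv(as.integer(inChannels), as.integer(outChannels))
}

#' @rdname blocks
#' @export
fcfbBlock <- function(inChannels, outChannels = inChannels %/% 2L) {
  mod_fcfb(as.integer(inChannels), as.integer(outChannels))
}

#' Apply a block to a feature map
#'
#' @param block a block built by one of the \link{blocks} constructors.
#' @param x numeric array (n, channels, H, W); all entries must be finite.
#' @param train use batch statistics (TRUE) or running statistics (FALSE) in
#'   any batch-norm layer.
#' @return The block output as an (n, channels', H', W') array.
#' @export
blockForward <- function(block, x, train = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  if (!all(is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  ag_begin(grad = FALSE)
  on.exit(ag_end(), add = TRUE)
  out <- mod_forward(block, nd_input(as_internal(x)), train)
  as_public(out$val)
}

#' Apply a feature cross-fusion block
#'
#' @param block an \code{\link{fcfbBlock}}.
#' @param yg,yl global- and local-stream feature maps of identical shape
#'   (n, channels, H, W).
#' @param train batch-norm mode as in \code{\link{blockForward}}.
#' @return List with elements \code{g} and \code{l}: the cross-fused outputs at
#'   doubled spatial size and the block's configured output width.
#' @export
fcfbForward <- function(block, yg, yl, train = FALSE) {
  stopifnot(length(dim(yg)) == 4L, length(dim(yl)) == 4L)
  ag_begin(grad = FALSE)
  on.exit(ag_end(), add = TRUE)
  out <- mod_forward(block, list(g = nd_input(as_internal(yg)),
                                 l = nd_input(as_internal(yl))), train)
  list(g = as_public(out$g$val), l = as_public(out$l$val))
}

#' Channel-attention vector of a SAM block
#'
#' @param block a \code{\link{samBlock}}.
#' @param x input array (n, channels, H, W).
#' @return Matrix (n, channels) of softmax channel weights; each row sums to 1.
#' @export
samAttention <- function(block, x) {
  ag_begin(grad = FALSE)
  on.exit(ag_end(), add = TRUE)
  t(sam_attention(block, nd_input(as_internal(x))))
}

#' Zero all learnable weights of a block or network
#'
#' Sets every learnable tensor (convolution and linear weights and biases,
#' normalization gains and offsets) to zero. Residual blocks (PRM, SAM) become
#' exact identities in this state.
#'
#' @param x a block or an \linkS4class{MBSNet} handle.
#' @return The modified object, invisibly.
#' @export
zeroWeights <- function(x) {
  ps <- if (methods::is(x, "MBSNet")) net_params(x) else module_params(x)
  for (p in ps) p$val <- p$val * 0
  invisible(x)
}
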