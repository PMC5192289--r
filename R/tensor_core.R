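# Layer primitives. Feature-map stacks are column-major arrays dim (H, W, C);
# kernel banks are dim (kh, kw, Cin, Cout). Every forward op is a pure
# function of its arguments; backward ops take the cached forward inputs.

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-D array (H, W, C) or a matrix")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}

#' Valid (unpadded) 2-D convolution, cross-correlation orientation
#'
#' Slides each kernel over the input with the given stride and no padding, so
#' an `H x W` input and `kh x kw` kernels give `(H-kh)/stride+1` output rows.
#' Kernels are not flipped: this is the cross-correlation orientation used
#' throughout CNN practice (learned kernels make the two equivalent up to
#' reparameterization).
#'
#' @param input 3-D array `(H, W, Cin)` (a matrix is promoted to one channel).
#' @param kernels 4-D array `(kh, kw, Cin, Cout)`.
#' @param bias numeric vector of length `Cout`, one bias per output map.
#' @param stride positive integer step of the kernel (default 1).
#' @return 3-D array `(Ho, Wo, Cout)` of pre-activation values.
#' @examples
#' x <- array(rnorm(36), dim = c(6, 6, 1))
#' k <- array(rnorm(18), dim = c(3, 3, 1, 2))
#' dim(conv_forward(x, k, c(0, 0)))  # 4 4 2
#' @export
conv_forward <- function(input, kernels, bias, stride = 1L) {
  input <- as_feature_map(input)
  if (!is.array(kernels) || length(dim(kernels)) != 4L)
    stop("kernels must be a 4-D array (kh, kw, Cin, Cout)")
  dk <- dim(kernels)
  din <- dim(input)
  if (dk[3] != din[3])
    stop(sprintf("kernel in_channels (%d) do not match input channels (%d)",
                 dk[3], din[3]))
  if (length(bias) != dk[4])
    stop("bias length must equal the number of output maps")
  if (stride < 1L) stop("stride must be >= 1")
  if (din[1] < dk[1] || din[2] < dk[2])
    stop("input spatial dims smaller than kernel")
  if ((din[1] - dk[1]) %% stride != 0L || (din[2] - dk[2]) %% stride != 0L)
    stop(sprintf("non-integer output dimension for input %dx%d, kernel %dx%d, stride %d",
                 din[1], din[2], dk[1], dk[2], stride))
  .conv_forward_cpp(input, kernels, as.numeric(bias), as.integer(stride))
}

#' Backward pass of the valid convolution
#'
#' @param dout upstream gradient, shaped like the forward output.
#' @param input,kernels,stride the cached forward arguments.
#' @return list with `dinput`, `dkernels`, `dbias`.
#' @export
conv_backward <- function(dout, input, kernels, stride = 1L) {
  if (is.null(input) || is.null(kernels))
    stop("conv_backward requires the cached forward input and kernels")
  input <- as_feature_map(input)
  dout <- as_feature_map(dout)
  .conv_backward_cpp(dout, input, kernels, as.integer(stride))
}

#' Rectified linear activation
#'
#' Elementwise `max(0, x)`; idempotent and shape-preserving.
#'
#' @param x numeric array of any shape.
#' @return array of the same shape with negatives clamped to zero.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' Backward pass of ReLU
#'
#' Passes the upstream gradient where the forward input was strictly
#' positive; the kink at 0 takes the subgradient 0.
#'
#' @param dout upstream gradient, shaped like `x`.
#' @param x the cached forward input.
#' @export
relu_backward <- function(dout, x) {
  if (is.null(x)) stop("relu_backward requires the cached forward input")
  dout * (x > 0)
}

#' 2x2 stride-2 max pooling (the downsampling layer)
#'
#' Halves both spatial dimensions, each output being the maximum of a
#' non-overlapping 2x2 window (`Y = max(X)`). Returns the per-window argmax
#' so the backward pass can route gradients to the selected positions; ties
#' go to the first occurrence in row-major window order.
#'
#' @param input 3-D array `(H, W, C)` with even `H` and `W`.
#' @return list with `output` (dim `(H/2, W/2, C)`) and `argmax` (1-based
#'   linear indices into `input`).
#' @export
maxpool_forward <- function(input) {
  input <- as_feature_map(input)
  .maxpool_forward_cpp(input)
}

#' Backward pass of max pooling
#'
#' Scatters each upstream gradient entry onto the recorded argmax position,
#' so the total gradient mass is conserved exactly.
#'
#' @param dout upstream gradient, shaped like the pooled output.
#' @param argmax the index record from [maxpool_forward()].
#' @param input_dim dim of the forward input.
#' @export
maxpool_backward <- function(dout, argmax, input_dim) {
  if (is.null(argmax)) stop("maxpool_backward requires the forward argmax record")
  .maxpool_backward_cpp(as_feature_map(dout), argmax, as.integer(input_dim))
}

#' Fully connected affine map
#'
#' Returns `W x + b`. Any nonlinearity is applied separately so the final
#' layer can feed its logits straight into the softmax.
#'
#' @param x numeric input vector.
#' @param weights matrix `(out, in)`.
#' @param bias numeric vector of length `out`.
#' @export
fc_forward <- function(x, weights, bias) {
  x <- as.numeric(x)
  if (ncol(weights) != length(x))
    stop(sprintf("fc weight columns (%d) do not match input length (%d)",
                 ncol(weights), length(x)))
  if (nrow(weights) != length(bias))
    stop("fc bias length must equal weight rows")
  as.numeric(weights %*% x + bias)
}

#' Backward pass of the fully connected layer
#'
#' @param dout upstream gradient w.r.t. the layer output.
#' @param x,weights cached forward input and weights.
#' @return list with `dx`, `dweights`, `dbias`.
#' @export
fc_backward <- function(dout, x, weights) {
  if (is.null(x) || is.null(weights))
    stop("fc_backward requires the cached forward input and weights")
  dout <- as.numeric(dout)
  list(dx = as.numeric(crossprod(weights, dout)),
       dweights = tcrossprod(dout, as.numeric(x)),
       dbias = dout)
}

#' Numerically stable softmax
#'
#' Subtracts the maximum logit before exponentiating, so the output is
#' invariant to adding a constant to all logits and never overflows.
#'
#' @param logits finite numeric vector.
#' @return probability vector of the same length; entries in (0,1), sum 1.
#' @export
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop("softmax requires finite logits")
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Cross-entropy loss for a single example
#'
#' `-log p(correct class)`, with the probability clamped to `[1e-12, 1]` so
#' a confidently wrong prediction yields a large finite loss.
#'
#' @param probs probability vector ordered (nodule, nonnodule).
#' @param label class label: 1 = nodule, 0 = nonnodule.
#' @export
cross_entropy_loss <- function(probs, label) {
  stopifnot(label %in% c(0L, 1L))
  p <- probs[if (label == 1) 1L else 2L]
  -log(min(max(p, 1e-12), 1))
}

#' Combined softmax + cross-entropy gradient
#'
#' The gradient of the cross-entropy of a softmax output with respect to the
#' logits collapses to `probs - one_hot(label)`.
#'
#' @param probs softmax output ordered (nodule, nonnodule).
#' @param label class label: 1 = nodule, 0 = nonnodule.
#' @return gradient w.r.t. the logits.
#' @export
softmax_ce_backward <- function(probs, label) {
  stopifnot(label %in% c(0L, 1L))
  onehot <- if (label == 1) c(1, 0) else c(0, 1)
  as.numeric(probs) - onehot
}
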