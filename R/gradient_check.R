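# Central-difference verification of the analytic backward passes. The
# numeric side never calls any backward code, so it is an independent oracle
# for the hand-derived gradients.

num_grad <- function(f, x, eps) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_dev <- function(analytic, numeric, eps) {
  denom <- pmax(abs(analytic), abs(numeric), eps)
  max(abs(analytic - numeric) / denom)
}

#' Verify a layer's analytic gradients against central differences
#'
#' Projects the layer output onto a fixed random direction to obtain a scalar
#' loss, computes its gradient w.r.t. every input and parameter both
#' analytically (the layer's backward pass) and by central differences, and
#' returns the worst relative deviation
#' `|analytic - numeric| / max(|analytic|, |numeric|, eps)`.
#'
#' For `maxpool` and `relu` the inputs must sit away from ties/kinks (the
#' caller perturbs them); at a tie the derivative does not exist and a finite
#' difference straddling it is meaningless.
#'
#' @param kind one of `"conv"`, `"maxpool"`, `"relu"`, `"fc"`, `"softmax_ce"`.
#' @param input layer input: 3-D array for conv/pool/relu, numeric vector for
#'   fc and softmax_ce (logits).
#' @param params layer parameters: `list(kernels, bias, stride)` for conv,
#'   `list(weights, bias)` for fc, `list(label)` for softmax_ce.
#' @param eps central-difference step and deviation floor.
#' @return the maximum relative deviation over all checked coordinates.
#' @export
numeric_gradient_check <- function(kind, input, params = NULL, eps = 1e-5) {
  stopifnot(eps > 0)
  kind <- match.arg(kind, c("conv", "maxpool", "relu", "fc", "softmax_ce"))
  if (kind == "softmax_ce") {
    label <- params$label
    f <- function(z) cross_entropy_loss(softmax(z), label)
    analytic <- softmax_ce_backward(softmax(input), label)
    return(max_rel_dev(analytic, num_grad(f, input, eps), eps))
  }
  if (kind == "fc") {
    proj <- rnorm(length(params$bias))
    f_in <- function(x) sum(proj * fc_forward(x, params$weights, params$bias))
    bk <- fc_backward(proj, input, params$weights)
    dev <- max_rel_dev(bk$dx, num_grad(f_in, as.numeric(input), eps), eps)
    f_w <- function(w) sum(proj * fc_forward(input, w, params$bias))
    dev <- max(dev, max_rel_dev(bk$dweights, num_grad(f_w, params$weights, eps), eps))
    f_b <- function(b) sum(proj * fc_forward(input, params$weights, b))
    return(max(dev, max_rel_dev(bk$dbias, num_grad(f_b, params$bias, eps), eps)))
  }
  input <- as_feature_map(input)
  if (kind == "relu") {
    out <- relu(input)
    proj <- array(rnorm(length(out)), dim = dim(out))
    f <- function(x) sum(proj * relu(x))
    analytic <- relu_backward(proj, input)
    return(max_rel_dev(analytic, num_grad(f, input, eps), eps))
  }
  if (kind == "maxpool") {
    fw <- maxpool_forward(input)
    proj <- array(rnorm(length(fw$output)), dim = dim(fw$output))
    f <- function(x) sum(proj * maxpool_forward(x)$output)
    analytic <- maxpool_backward(proj, fw$argmax, dim(input))
    return(max_rel_dev(analytic, num_grad(f, input, eps), eps))
  }
  # conv: check input, kernels and bias
  stride <- if (is.null(params$stride)) 1L else params$stride
  out <- conv_forward(input, params$kernels, params$bias, stride)
  proj <- array(rnorm(length(out)), dim = dim(out))
  bk <- conv_backward(proj, input, params$kernels, stride)
  f_in <- function(x) sum(proj * conv_forward(x, params$kernels, params$bias, stride))
  dev <- max_rel_dev(bk$dinput, num_grad(f_in, input, eps), eps)
  f_k <- function(k) sum(proj * conv_forward(input, k, params$bias, stride))
  dev <- max(dev, max_rel_dev(bk$dkernels, num_grad(f_k, params$kernels, eps), eps))
  f_b <- function(b) sum(proj * conv_forward(input, params$kernels, b, stride))
  max(dev, max_rel_dev(bk$dbias, num_grad(f_b, params$bias, eps), eps))
}

#' End-to-end gradient check of a full network
#'
#' Computes the cross-entropy loss gradient of the whole network analytically
#' via backpropagation, then re-derives a random sample of parameter (and
#' input-pixel) coordinates by central differences. Checking a subsample
#' keeps the cost linear in `n_coords` rather than in the ~10^5 parameters
#' of the default network, while still touching every layer.
#'
#' @param config a [network_config()].
#' @param params a [init_parameters()] parameter set.
#' @param patch input patch matrix (values in `[0,1]`).
#' @param label class label 0/1.
#' @param n_coords number of parameter coordinates to sample per tensor.
#' @param eps central-difference step.
#' @return maximum relative deviation over all sampled coordinates.
#' @export
network_gradient_check <- function(config, params, patch, label,
                                   n_coords = 12L, eps = 1e-5) {
  fw <- nn_forward(config, params, patch)
  grads <- nn_backward(config, params, fw$cache, label)
  loss_at <- function(p) {
    cross_entropy_loss(nn_forward(config, p, patch)$probs, label)
  }
  dev <- 0
  for (li in seq_along(params)) {
    layer <- params[[li]]
    if (is.null(layer)) next
    for (tensor in c("kernels", "weights", "bias")) {
      w <- layer[[tensor]]
      if (is.null(w)) next
      ii <- if (length(w) <= n_coords) seq_along(w) else
        sample(length(w), n_coords)
      for (i in ii) {
        pp <- params; pm <- params
        pp[[li]][[tensor]][i] <- w[i] + eps
        pm[[li]][[tensor]][i] <- w[i] - eps
        numeric <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        analytic <- grads[[li]][[if (tensor == "bias") "dbias" else
          if (tensor == "kernels") "dkernels" else "dweights"]][i]
        dev <- max(dev, abs(analytic - numeric) /
                     max(abs(analytic), abs(numeric), eps))
      }
    }
  }
  dev
}
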