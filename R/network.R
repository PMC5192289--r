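# Network assembly: declarative layer stack, shape inference, parameter
# initialization, and the forward/backward passes over a whole patch.

#' Describe one layer of the network
#'
#' @param kind `"conv"`, `"maxpool"`, `"fc"` or `"softmax"`.
#' @param feature_maps number of output maps (conv only).
#' @param node_count number of output nodes (fc only).
#' @param kernel_size square kernel/window side (conv and maxpool).
#' @param stride kernel step.
#' @param activation `"relu"` or `"none"`, applied after the affine step of
#'   conv/fc layers.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(kind, feature_maps = NULL, node_count = NULL,
                       kernel_size = NULL, stride = NULL,
                       activation = c("relu", "none")) {
  kind <- match.arg(kind, c("conv", "maxpool", "fc", "softmax"))
  activation <- match.arg(activation)
  if (kind == "conv") {
    stopifnot(feature_maps >= 1, kernel_size >= 1, stride >= 1)
  } else if (kind == "maxpool") {
    if (is.null(kernel_size)) kernel_size <- 2L
    if (is.null(stride)) stride <- 2L
    if (kernel_size != 2L || stride != 2L)
      stop("maxpool layers use a 2x2 window with stride 2")
    activation <- "none"
  } else if (kind == "fc") {
    stopifnot(node_count >= 1)
  } else {
    activation <- "none"
  }
  structure(list(kind = kind, feature_maps = feature_maps,
                 node_count = node_count, kernel_size = kernel_size,
                 stride = stride, activation = activation),
            class = "layer_spec")
}

#' Assemble a network configuration
#'
#' @param input_size side of the square single-channel input patch (32 or 64).
#' @param layers ordered list of [layer_spec()] objects; the last must be a
#'   softmax over a final 2-node fc layer.
#' @return a `network_config` object.
#' @export
network_config <- function(input_size, layers) {
  stopifnot(input_size %in% c(32L, 64L))
  if (!length(layers) || layers[[length(layers)]]$kind != "softmax")
    stop("the final layer must be softmax")
  fc_layers <- Filter(function(l) l$kind == "fc", layers)
  if (!length(fc_layers) || fc_layers[[length(fc_layers)]]$node_count != 2L)
    stop("the last fc layer must have exactly 2 output nodes (nodule, nonnodule)")
  cfg <- structure(list(input_size = as.integer(input_size), layers = layers),
                   class = "network_config")
  infer_shapes(cfg)  # validates every intermediate dimension
  cfg
}

#' The default 32x32 nodule-recognition network
#'
#' Two 5x5 stride-1 convolutional layers (8 then 16 feature maps), each
#' followed by 2x2 stride-2 max pooling, then fully connected layers of 150,
#' 100, 50 and 2 nodes feeding a softmax over (nodule, nonnodule). ReLU
#' follows both convolutions and the first three fc layers; the 2-node layer
#' emits raw logits.
#'
#' The first-layer map count is exposed as a knob because smaller map counts
#' (e.g. 6) are a common capacity setting for this architecture family.
#'
#' @param conv1_maps,conv2_maps feature-map counts of the two conv layers.
#' @return a `network_config` with 9 layers.
#' @export
default_config_32 <- function(conv1_maps = 8L, conv2_maps = 16L) {
  network_config(32L, list(
    layer_spec("conv", feature_maps = conv1_maps, kernel_size = 5L, stride = 1L),
    layer_spec("maxpool"),
    layer_spec("conv", feature_maps = conv2_maps, kernel_size = 5L, stride = 1L),
    layer_spec("maxpool"),
    layer_spec("fc", node_count = 150L),
    layer_spec("fc", node_count = 100L),
    layer_spec("fc", node_count = 50L),
    layer_spec("fc", node_count = 2L, activation = "none"),
    layer_spec("softmax")
  ))
}

layer_out_dim <- function(spec, din) {
  if (spec$kind == "conv") {
    if (din[3] < 1) stop("conv layer cannot follow a flattened fc layer")
    ho <- (din[1] - spec$kernel_size) / spec$stride + 1
    wo <- (din[2] - spec$kernel_size) / spec$stride + 1
    if (ho != floor(ho) || wo != floor(wo) || ho < 1 || wo < 1)
      stop(sprintf("conv layer: non-integer or non-positive output dim from input %dx%d",
                   din[1], din[2]))
    c(ho, wo, spec$feature_maps)
  } else if (spec$kind == "maxpool") {
    if (din[1] %% 2 != 0 || din[2] %% 2 != 0)
      stop(sprintf("maxpool layer: odd input dims %dx%d", din[1], din[2]))
    c(din[1] / 2, din[2] / 2, din[3])
  } else if (spec$kind == "fc") {
    c(spec$node_count, 1, 0)  # flattened from here on
  } else {
    din
  }
}

#' Activation count after every layer
#'
#' Walks the configured stack and returns the flattened unit count after each
#' layer, starting from the input. For the default 32x32 network this is
#' 1024, 6272, 1568, 1600, 400, 150, 100, 50, 2, 2.
#'
#' @param config a [network_config()].
#' @return named integer vector, `input` first then one entry per layer.
#' @export
infer_shapes <- function(config) {
  din <- c(config$input_size, config$input_size, 1)
  counts <- c(input = prod(din[1:2]) * max(din[3], 1))
  for (i in seq_along(config$layers)) {
    spec <- config$layers[[i]]
    din <- tryCatch(layer_out_dim(spec, din), error = function(e)
      stop(sprintf("layer %d (%s): %s", i, spec$kind, conditionMessage(e)),
           call. = FALSE))
    n <- if (din[3] == 0) din[1] else prod(din)
    counts <- c(counts, stats::setNames(n, paste0(spec$kind, i)))
  }
  counts
}

# spatial/vector shape entering each layer; used by init and forward
layer_input_dims <- function(config) {
  din <- c(config$input_size, config$input_size, 1)
  dims <- vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    dims[[i]] <- din
    din <- layer_out_dim(config$layers[[i]], din)
  }
  dims
}

#' Initialize network parameters
#'
#' Weights are drawn from a fan-scaled uniform distribution with bound
#' `sqrt(6 / (fan_in + fan_out))` (Glorot/Xavier scaling); biases and the
#' momentum velocity buffers start at zero. Fully reproducible from the seed.
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed.
#' @param scheme `"glorot_uniform"` (default) or `"zero"` (test use only:
#'   symmetric logits give exactly (0.5, 0.5)).
#' @return a `parameter_set`: one entry per layer, `NULL` for layers without
#'   parameters, otherwise kernels/weights, bias, and matching `v_*`
#'   velocity buffers.
#' @export
init_parameters <- function(config, seed = 1L,
                            scheme = c("glorot_uniform", "zero")) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  dims <- layer_input_dims(config)
  params <- vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    spec <- config$layers[[i]]
    if (spec$kind == "conv") {
      din <- dims[[i]]
      kd <- c(spec$kernel_size, spec$kernel_size, din[3], spec$feature_maps)
      fan_in <- spec$kernel_size^2 * din[3]
      fan_out <- spec$kernel_size^2 * spec$feature_maps
      bound <- sqrt(6 / (fan_in + fan_out))
      k <- if (scheme == "zero") array(0, kd) else
        array(runif(prod(kd), -bound, bound), kd)
      params[[i]] <- list(kernels = k, bias = numeric(kd[4]),
                          v_kernels = array(0, kd), v_bias = numeric(kd[4]))
    } else if (spec$kind == "fc") {
      din <- dims[[i]]
      n_in <- if (din[3] == 0) din[1] else prod(din)
      n_out <- spec$node_count
      bound <- sqrt(6 / (n_in + n_out))
      w <- if (scheme == "zero") matrix(0, n_out, n_in) else
        matrix(runif(n_out * n_in, -bound, bound), n_out, n_in)
      params[[i]] <- list(weights = w, bias = numeric(n_out),
                          v_weights = matrix(0, n_out, n_in),
                          v_bias = numeric(n_out))
    }
  }
  structure(params, class = "parameter_set", config_shapes = infer_shapes(config))
}

#' Forward pass over one patch
#'
#' Runs the patch through the configured stack and returns the softmax
#' probability pair ordered (nodule, nonnodule) together with the cached
#' intermediate activations needed by [nn_backward()].
#'
#' @param config a [network_config()].
#' @param params a matching `parameter_set`.
#' @param patch square matrix of normalized intensities in `[0,1]`, side
#'   `config$input_size`.
#' @return list with `probs` (named numeric pair) and `cache`.
#' @export
nn_forward <- function(config, params, patch) {
  if (is.list(patch) && !is.null(patch$pixels)) patch <- patch$pixels
  patch <- as.matrix(patch)
  if (nrow(patch) != config$input_size || ncol(patch) != config$input_size)
    stop(sprintf("patch is %dx%d but the network expects %dx%d",
                 nrow(patch), ncol(patch), config$input_size, config$input_size))
  if (min(patch) < -1e-8 || max(patch) > 1 + 1e-8)
    stop("patch intensities must be normalized to [0,1]")
  x <- array(patch, dim = c(dim(patch), 1L))
  flat <- FALSE
  cache <- vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    spec <- config$layers[[i]]
    if (spec$kind == "conv") {
      pre <- conv_forward(x, params[[i]]$kernels, params[[i]]$bias, spec$stride)
      out <- if (spec$activation == "relu") relu(pre) else pre
      cache[[i]] <- list(input = x, pre = pre)
      x <- out
    } else if (spec$kind == "maxpool") {
      fw <- maxpool_forward(x)
      cache[[i]] <- list(argmax = fw$argmax, input_dim = dim(x))
      x <- fw$output
    } else if (spec$kind == "fc") {
      unflat_dim <- NULL
      if (!flat) { unflat_dim <- dim(x); x <- as.numeric(x); flat <- TRUE }
      pre <- fc_forward(x, params[[i]]$weights, params[[i]]$bias)
      out <- if (spec$activation == "relu") relu(pre) else pre
      cache[[i]] <- list(input = x, pre = pre, unflatten = unflat_dim)
      x <- out
    } else { # softmax
      probs <- softmax(x)
      cache[[i]] <- list(probs = probs)
      x <- probs
    }
  }
  list(probs = stats::setNames(as.numeric(x), c("nodule", "nonnodule")),
       cache = cache)
}

#' Backward pass (backpropagation) over one patch
#'
#' Propagates the softmax + cross-entropy gradient `probs - one_hot(label)`
#' back through the cached stack.
#'
#' @param config,params as in [nn_forward()].
#' @param cache the cache returned by [nn_forward()] for the same patch.
#' @param label class label: 1 = nodule, 0 = nonnodule.
#' @return list parallel to `params` with `dkernels`/`dweights`/`dbias`.
#' @export
nn_backward <- function(config, params, cache, label) {
  if (is.null(cache)) stop("nn_backward requires the forward cache")
  n <- length(config$layers)
  grads <- vector("list", n)
  d <- NULL
  for (i in rev(seq_len(n))) {
    spec <- config$layers[[i]]
    if (spec$kind == "softmax") {
      d <- softmax_ce_backward(cache[[i]]$probs, label)
    } else if (spec$kind == "fc") {
      if (spec$activation == "relu") d <- relu_backward(d, cache[[i]]$pre)
      bk <- fc_backward(d, cache[[i]]$input, params[[i]]$weights)
      grads[[i]] <- list(dweights = bk$dweights, dbias = bk$dbias)
      d <- bk$dx
      if (!is.null(cache[[i]]$unflatten)) d <- array(d, dim = cache[[i]]$unflatten)
    } else if (spec$kind == "maxpool") {
      d <- maxpool_backward(d, cache[[i]]$argmax, cache[[i]]$input_dim)
    } else { # conv
      if (spec$activation == "relu") d <- relu_backward(d, cache[[i]]$pre)
      bk <- conv_backward(d, cache[[i]]$input, params[[i]]$kernels, spec$stride)
      grads[[i]] <- list(dkernels = bk$dkernels, dbias = bk$dbias)
      d <- bk$dinput
    }
  }
  grads
}

#' Turn output probabilities into a class label
#'
#' Argmax over the (nodule, nonnodule) pair; an exact tie is called
#' nonnodule, the conservative choice for a false-positive-reduction stage.
#'
#' @param probs probability pair ordered (nodule, nonnodule).
#' @return integer label: 1 = nodule, 0 = nonnodule.
#' @export
predict_class <- function(probs) {
  if (probs[1] > probs[2]) 1L else 0L
}
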