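# Independent brute-force oracles, written against the mathematical
# definitions only; they never call the package's layer implementations.

conv_oracle <- function(input, kernels, bias, stride = 1L) {
  din <- dim(input); dk <- dim(kernels)
  ho <- (din[1] - dk[1]) %/% stride + 1L
  wo <- (din[2] - dk[2]) %/% stride + 1L
  out <- array(0, dim = c(ho, wo, dk[4]))
  for (co in seq_len(dk[4])) for (r in seq_len(ho)) for (cl in seq_len(wo)) {
    acc <- bias[co]
    for (ci in seq_len(din[3])) for (i in seq_len(dk[1])) for (j in seq_len(dk[2]))
      acc <- acc + input[(r - 1L) * stride + i, (cl - 1L) * stride + j, ci] *
        kernels[i, j, ci, co]
    out[r, cl, co] <- acc
  }
  out
}

maxpool_oracle <- function(input) {
  din <- dim(input)
  out <- array(0, dim = c(din[1] %/% 2L, din[2] %/% 2L, din[3]))
  for (c in seq_len(din[3])) for (r in seq_len(din[1] %/% 2L))
    for (cl in seq_len(din[2] %/% 2L))
      out[r, cl, c] <- max(input[(2L * r - 1L):(2L * r), (2L * cl - 1L):(2L * cl), c])
  out
}

# a small, quickly trainable network for end-to-end tests on 32x32 patches
tiny_config_32 <- function() {
  network_config(32L, list(
    layer_spec("conv", feature_maps = 4L, kernel_size = 5L, stride = 1L),
    layer_spec("maxpool"),
    layer_spec("fc", node_count = 24L),
    layer_spec("fc", node_count = 2L, activation = "none"),
    layer_spec("softmax")
  ))
}

# random feature-map stack with entries bounded away from pool/ReLU ties
jittered_stack <- function(dims, gap = 1e-3) {
  n <- prod(dims)
  array(seq_len(n) * gap + rnorm(n), dim = dims)
}
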