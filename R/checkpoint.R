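# Self-describing checkpoint container.
#
# Byte layout (all multi-byte values little-endian):
#   bytes 0..9   : ASCII magic "NODCNNCKPT"
#   bytes 10..13 : int32 format version (currently 1)
#   bytes 14..17 : int32 header length L
#   bytes 18..   : L bytes of UTF-8 JSON: the network config plus, per
#                  parameterized layer, the tensor names and dims in file order
#   then         : the tensors as raw float64 arrays, column-major, in the
#                  order listed in the header
#
# Only weights and biases are stored; momentum velocity buffers are training
# state and are re-zeroed on load.

CKPT_MAGIC <- "NODCNNCKPT"
CKPT_VERSION <- 1L

config_to_list <- function(config) {
  list(input_size = config$input_size,
       layers = lapply(config$layers, function(l)
         l[c("kind", "feature_maps", "node_count", "kernel_size", "stride",
             "activation")]))
}

config_from_list <- function(x) {
  layers <- lapply(x$layers, function(l)
    layer_spec(l$kind,
               feature_maps = if (is.null(l$feature_maps)) NULL else as.integer(l$feature_maps),
               node_count = if (is.null(l$node_count)) NULL else as.integer(l$node_count),
               kernel_size = if (is.null(l$kernel_size)) NULL else as.integer(l$kernel_size),
               stride = if (is.null(l$stride)) NULL else as.integer(l$stride),
               activation = l$activation))
  network_config(as.integer(x$input_size), layers)
}

#' Save a network checkpoint
#'
#' Writes the configuration and all weights/biases to a self-describing
#' binary container (format documented in the package source); the
#' save-load round trip is bit-exact.
#'
#' @param config a [network_config()].
#' @param params the matching `parameter_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(config, params, path) {
  tensors <- list(); meta <- list()
  for (i in seq_along(params)) {
    layer <- params[[i]]
    if (is.null(layer)) next
    for (nm in intersect(c("kernels", "weights", "bias"), names(layer))) {
      tensors[[length(tensors) + 1L]] <- layer[[nm]]
      meta[[length(meta) + 1L]] <- list(layer = i, tensor = nm,
                                        dim = if (is.null(dim(layer[[nm]])))
                                          length(layer[[nm]]) else dim(layer[[nm]]))
    }
  }
  header <- jsonlite::toJSON(list(config = config_to_list(config),
                                  tensors = meta),
                             auto_unbox = TRUE, digits = NA, null = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(CKPT_MAGIC, con, nchars = nchar(CKPT_MAGIC), eos = NULL)
  writeBin(CKPT_VERSION, con, size = 4L, endian = "little")
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (t in tensors)
    writeBin(as.numeric(t), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a network checkpoint
#'
#' Validates the magic bytes, format version and payload length before
#' reconstructing the configuration and parameters; a truncated or corrupt
#' file raises an error without returning partial state.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return list with `config` and `params` (velocities zeroed).
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(CKPT_MAGIC), useBytes = TRUE)
  if (!identical(magic, CKPT_MAGIC))
    stop("not a noduleCNN checkpoint (bad magic bytes)")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(version, CKPT_VERSION))
    stop(sprintf("unsupported checkpoint format version %s", version))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || is.na(hlen) || hlen <= 0L) stop("corrupt checkpoint header")
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) != hlen) stop("truncated checkpoint header")
  header <- jsonlite::fromJSON(rawToChar(hraw), simplifyVector = FALSE)
  config <- config_from_list(header$config)
  params <- init_parameters(config, seed = 0L, scheme = "zero")
  for (m in header$tensors) {
    dims <- as.integer(unlist(m$dim))
    n <- prod(dims)
    vals <- readBin(con, "numeric", n, size = 8L, endian = "little")
    if (length(vals) != n)
      stop(sprintf("truncated checkpoint: tensor %s of layer %d incomplete",
                   m$tensor, m$layer))
    params[[m$layer]][[m$tensor]] <-
      if (length(dims) > 1L) array(vals, dims) else vals
  }
  if (length(readBin(con, "raw", 1L)) != 0L)
    stop("trailing bytes after checkpoint payload")
  list(config = config, params = params)
}
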