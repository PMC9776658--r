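#' Four-stream model configuration
#'
#' Describes the four-stream 3D CNN: a shared input of size
#' `height x width x depth x channels` (default 128 x 128 x 4 x 3, the four
#' fused RGB images of a 16-frame window), split into one stream per fused
#' image. Each stream applies three convolution blocks (conv -> batchnorm ->
#' relu, each followed by a max-pool) and a global average pool; stream
#' descriptors are concatenated and classified by two fully connected blocks
#' and a final 4-way softmax. Successive conv layers double their filter
#' count (64, 128, 256) while successive FC layers halve their width
#' (64, 32) before the class layer — an expand-and-shrink design. Since each
#' kernel's depth always equals the incoming channel count, every "3D"
#' convolution acts as a full-channel 2D convolution; shapes are still
#' reported in the H x W x D x C convention.
#'
#' @param input_shape Integer c(height, width, depth, channels).
#' @param branch_conv_filters Filter counts of the per-stream conv layers.
#' @param conv_kernels List of c(kh, kw) kernel sizes, one per conv layer
#'   (kernel depth is implied by the incoming channel count).
#' @param conv_strides List of c(sh, sw) strides, one per conv layer.
#' @param pool_windows List of c(ph, pw) max-pool windows, one per block.
#' @param pool_strides List of c(sh, sw) max-pool strides, one per block.
#' @param fc_widths Fully connected widths; the last entry is the number of
#'   classes.
#' @param n_branches Number of streams (one per fused image).
#' @return An object of class `fall4s_config`.
#' @export
#' @examples
#' cfg <- model_config()
#' cfg$branch_conv_filters
model_config <- function(input_shape = c(128L, 128L, 4L, 3L),
                         branch_conv_filters = c(64L, 128L, 256L),
                         conv_kernels = list(c(4L, 4L), c(3L, 3L), c(3L, 3L)),
                         conv_strides = list(c(2L, 2L), c(2L, 2L), c(1L, 1L)),
                         pool_windows = list(c(3L, 3L), c(3L, 3L), c(2L, 2L)),
                         pool_strides = list(c(2L, 2L), c(2L, 2L), c(1L, 1L)),
                         fc_widths = c(64L, 32L, 4L),
                         n_branches = 4L) {
  nb <- length(branch_conv_filters)
  if (nb < 1) stop_config("need at least one conv block")
  if (length(conv_kernels) != nb || length(conv_strides) != nb ||
      length(pool_windows) != nb || length(pool_strides) != nb)
    stop_config("conv_kernels, conv_strides, pool_windows, pool_strides must ",
                "have one entry per conv block")
  if (nb > 1 && any(branch_conv_filters[-1] != 2L * branch_conv_filters[-nb]))
    stop_config("filter counts must double across successive conv layers")
  nf <- length(fc_widths)
  if (nf >= 3 && any(fc_widths[2:(nf - 1)] * 2L != fc_widths[1:(nf - 2)]))
    stop_config("hidden FC widths must halve across successive layers")
  if (n_branches < 1) stop_config("n_branches must be >= 1")
  if (length(input_shape) != 4)
    stop_config("input_shape must be c(height, width, depth, channels)")
  if (input_shape[3] < n_branches)
    stop_config("input depth must cover all branches")
  structure(list(input_shape = as.integer(input_shape),
                 branch_conv_filters = as.integer(branch_conv_filters),
                 conv_kernels = lapply(conv_kernels, as.integer),
                 conv_strides = lapply(conv_strides, as.integer),
                 pool_windows = lapply(pool_windows, as.integer),
                 pool_strides = lapply(pool_strides, as.integer),
                 fc_widths = as.integer(fc_widths),
                 n_branches = as.integer(n_branches)),
            class = "fall4s_config")
}

## valid (no padding) output side: floor((in - k)/stride) + 1
conv_out_side <- function(side, k, s) (side - k) %/% s + 1L

layer_record <- function(name, kind, branch, shape, params) {
  data.frame(name = name, kind = kind, branch = branch,
             out_h = shape[1], out_w = shape[2], out_d = shape[3],
             out_c = shape[4], params = params, stringsAsFactors = FALSE)
}

## Per-branch spatial trace and channel trace for a config.
branch_trace <- function(config) {
  h <- config$input_shape[1]; w <- config$input_shape[2]
  ch <- config$input_shape[4]
  rows <- list()
  for (i in seq_along(config$branch_conv_filters)) {
    k <- config$conv_kernels[[i]]; s <- config$conv_strides[[i]]
    f <- config$branch_conv_filters[i]
    h2 <- conv_out_side(h, k[1], s[1]); w2 <- conv_out_side(w, k[2], s[2])
    if (h2 < 1 || w2 < 1)
      stop_config("conv layer ", i, " produces non-positive spatial size")
    rows[[length(rows) + 1]] <- list(kind = "conv", index = i, in_c = ch,
                                     out_c = f, h = h2, w = w2,
                                     kernel = k, stride = s)
    h <- h2; w <- w2; ch <- f
    p <- config$pool_windows[[i]]; ps <- config$pool_strides[[i]]
    h2 <- conv_out_side(h, p[1], ps[1]); w2 <- conv_out_side(w, p[2], ps[2])
    if (h2 < 1 || w2 < 1)
      stop_config("pool layer ", i, " produces non-positive spatial size")
    rows[[length(rows) + 1]] <- list(kind = "pool", index = i, in_c = ch,
                                     out_c = ch, h = h2, w = w2,
                                     kernel = p, stride = ps)
    h <- h2; w <- w2
  }
  rows
}

#' Build the introspectable layer graph of the four-stream network
#'
#' Enumerates every layer of the model in order — input, the per-stream
#' splitting layers, each stream's conv/batchnorm/relu blocks with their
#' max-pools and global average pool, the concatenation layer, the fully
#' connected blocks, and the softmax/classification head — with each
#' layer's output shape (in the H x W x D x C convention) and learnable
#' parameter count. All convolutions and pools use valid (no) padding, and
#' each conv kernel spans the full incoming channel depth. Under the default
#' configuration the graph has 67 layers and the per-stream spatial trace is
#' 128 -> 63 -> 31 -> 15 -> 7 -> 5 -> 4 before the global average pool.
#'
#' @param config A [model_config()].
#' @return An object of class `fall4s_graph`: list with `layers` (data frame
#'   of layer records), `total_params`, `concat_width` and the `config`.
#' @export
#' @examples
#' g <- build_model()
#' nrow(g$layers)      # 67
#' g$total_params
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "fall4s_config"))
  trace <- branch_trace(config)
  in_sh <- config$input_shape
  recs <- list(layer_record("input", "input", "shared", in_sh, 0L))
  for (b in seq_len(config$n_branches)) {
    recs[[length(recs) + 1]] <- layer_record(
      sprintf("split_b%d", b), "split", as.character(b),
      c(in_sh[1], in_sh[2], 1L, in_sh[4]), 0L)
  }
  last_c <- NA_integer_
  for (b in seq_len(config$n_branches)) {
    for (tr in trace) {
      sh <- c(tr$h, tr$w, 1L, tr$out_c)
      if (tr$kind == "conv") {
        i <- tr$index
        p_conv <- prod(tr$kernel) * tr$in_c * tr$out_c + tr$out_c
        recs[[length(recs) + 1]] <- layer_record(
          sprintf("conv%d_b%d", i, b), "conv", as.character(b), sh, p_conv)
        recs[[length(recs) + 1]] <- layer_record(
          sprintf("bn%d_b%d", i, b), "batchnorm", as.character(b), sh,
          2L * tr$out_c)
        recs[[length(recs) + 1]] <- layer_record(
          sprintf("relu%d_b%d", i, b), "relu", as.character(b), sh, 0L)
      } else {
        recs[[length(recs) + 1]] <- layer_record(
          sprintf("pool%d_b%d", tr$index, b), "maxpool", as.character(b),
          sh, 0L)
      }
      last_c <- tr$out_c
    }
    recs[[length(recs) + 1]] <- layer_record(
      sprintf("gap_b%d", b), "gap", as.character(b),
      c(1L, 1L, 1L, last_c), 0L)
  }
  concat_width <- config$n_branches * last_c
  if (config$n_branches > 1) {
    recs[[length(recs) + 1]] <- layer_record(
      "concat", "concat", "shared", c(1L, 1L, 1L, concat_width), 0L)
  }
  width <- concat_width
  nf <- length(config$fc_widths)
  for (i in seq_len(nf)) {
    out <- config$fc_widths[i]
    recs[[length(recs) + 1]] <- layer_record(
      sprintf("fc%d", i), "fc", "shared", c(1L, 1L, 1L, out),
      width * out + out)
    if (i < nf) {
      recs[[length(recs) + 1]] <- layer_record(
        sprintf("fc_bn%d", i), "batchnorm", "shared", c(1L, 1L, 1L, out),
        2L * out)
      recs[[length(recs) + 1]] <- layer_record(
        sprintf("fc_relu%d", i), "relu", "shared", c(1L, 1L, 1L, out), 0L)
    }
    width <- out
  }
  n_classes <- config$fc_widths[nf]
  recs[[length(recs) + 1]] <- layer_record(
    "softmax", "softmax", "shared", c(1L, 1L, 1L, n_classes), 0L)
  recs[[length(recs) + 1]] <- layer_record(
    "classification", "classification", "shared",
    c(1L, 1L, 1L, n_classes), 0L)
  layers <- do.call(rbind, recs)
  rownames(layers) <- NULL
  structure(list(layers = layers,
                 total_params = sum(layers$params),
                 concat_width = concat_width,
                 config = config),
            class = "fall4s_graph")
}

#' Recompute and verify layer output shapes
#'
#' Re-derives every layer's output shape from the configuration using the
#' valid-padding rule `out = floor((in - kernel)/stride) + 1` per spatial
#' dimension and checks it against the shapes stored in the graph.
#'
#' @param graph A `fall4s_graph`.
#' @return The graph with shapes verified (and filled, if absent).
#' @export
propagate_shapes <- function(graph) {
  stopifnot(inherits(graph, "fall4s_graph"))
  fresh <- build_model(graph$config)
  stored <- graph$layers[, c("out_h", "out_w", "out_d", "out_c")]
  if (!isTRUE(all.equal(stored, fresh$layers[, c("out_h", "out_w",
                                                 "out_d", "out_c")])))
    stop("stored shapes inconsistent with the shape rules")
  graph$layers <- fresh$layers
  graph
}

#' Spatial side trace of one stream
#'
#' The per-stream spatial side lengths from the input through each conv and
#' pool layer (128, 63, 31, 15, 7, 5, 4 under the default configuration).
#'
#' @param graph A `fall4s_graph`.
#' @return Integer vector of side lengths.
#' @export
spatial_trace <- function(graph) {
  stopifnot(inherits(graph, "fall4s_graph"))
  L <- graph$layers
  b1 <- L[L$branch == "1" & L$kind %in% c("conv", "maxpool"), ]
  c(graph$config$input_shape[1], b1$out_h)
}

#' Total learnable parameter count
#'
#' Sums the learnables of every layer: convolution kernels and biases
#' (`kh*kw*in_c*out_c + out_c`), fully connected weights and biases
#' (`in*out + out`), and batchnorm scale/shift pairs (`2*channels`).
#'
#' @param graph A `fall4s_graph`.
#' @return Integer total.
#' @export
count_parameters <- function(graph) {
  stopifnot(inherits(graph, "fall4s_graph"))
  sum(graph$layers$params)
}

#' Parameter count in millions, truncated to one decimal
#'
#' @param graph A `fall4s_graph`.
#' @return Numeric, e.g. 1.5 for the default model.
#' @export
params_millions <- function(graph) {
  floor(count_parameters(graph) / 1e6 * 10) / 10
}

#' @export
print.fall4s_graph <- function(x, ...) {
  cat(format_model_table(x), sep = "\n")
  invisible(x)
}

#' Plain-text architecture table
#'
#' One row per layer with kind, stream, output shape (H x W x D x C) and
#' learnable parameter count, followed by the layer and parameter totals.
#'
#' @param graph A `fall4s_graph`.
#' @return Character vector of table lines.
#' @export
format_model_table <- function(graph) {
  L <- graph$layers
  shp <- sprintf("%d x %d x %d x %d", L$out_h, L$out_w, L$out_d, L$out_c)
  lines <- sprintf("%-16s %-14s %-7s %-22s %10d",
                   L$name, L$kind, L$branch, shp, L$params)
  header <- sprintf("%-16s %-14s %-7s %-22s %10s",
                    "Layer", "Kind", "Stream", "Feature map", "Params")
  c(header, strrep("-", nchar(header)), lines,
    strrep("-", nchar(header)),
    sprintf("Layers: %d   Parameters: %d (%.1f M truncated)",
            nrow(L), graph$total_params, params_millions(graph)))
}

#' Export the layer graph as JSON
#'
#' @param graph A `fall4s_graph`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(graph, path) {
  jsonlite::write_json(
    list(layers = graph$layers,
         total_params = graph$total_params,
         concat_width = graph$concat_width),
    path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
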