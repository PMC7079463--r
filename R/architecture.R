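# Declarative network specifications for the two-stage spike segmentation
# approach, plus a weight-free shape-tracing oracle.
#
# LPNet: 3 encoder blocks (two 3x3 conv -> ReLU -> batch-norm, then 2x2
# max-pool) widening through base_widths, a bottleneck of 3 hourglasses with
# one scale-up and one scale-down between them, and 3 decoder blocks that
# mirror the encoder (stride-2 3x3 transpose conv, concatenation with the
# pre-pool encoder feature map, two 3x3 conv -> ReLU -> batch-norm), ending
# in a 3x3 conv to one channel with a sigmoid spike-probability head.
# GMRNet: identical but with an empty bottleneck and a single-channel input.

#' Network specification for the local patch network (LPNet)
#'
#' Builds the declarative layer specification of the patch-level
#' encoder--decoder segmentation network with a stacked-hourglass bottleneck.
#' At the default widths and patch size the traced shapes reproduce the
#' standard layer tables of the architecture (see [shape_trace()]).
#'
#' @param base_widths Integer triple of encoder channel widths, by depth.
#' @param patch_size Input patch side length in pixels; must be divisible by
#'   8 (three 2x2 poolings) and at least 64 so the hourglass interior can
#'   pool three times.
#' @param in_channels Number of input channels (3 for RGB patches).
#' @return A `network_spec` object.
#' @seealso [gmrnet_spec()], [shape_trace()], [build_network()]
#' @export
#' @examples
#' spec <- lpnet_spec(base_widths = c(4, 8, 16), patch_size = 64)
#' shape_trace(spec)
lpnet_spec <- function(base_widths = c(16L, 64L, 128L), patch_size = 256L,
                       in_channels = 3L) {
  new_network_spec("LPNet", base_widths, patch_size, in_channels,
                   has_bottleneck = TRUE)
}

#' Network specification for the global mask refinement network (GMRNet)
#'
#' Same encoder/decoder architecture as [lpnet_spec()] but without the
#' hourglass bottleneck; its input is the merged patch-level probability map
#' resized to `patch_size` x `patch_size`, as a single channel.
#'
#' @inheritParams lpnet_spec
#' @return A `network_spec` object with an empty bottleneck.
#' @export
gmrnet_spec <- function(base_widths = c(16L, 64L, 128L), patch_size = 256L,
                        in_channels = 1L) {
  new_network_spec("GMRNet", base_widths, patch_size, in_channels,
                   has_bottleneck = FALSE)
}

new_network_spec <- function(name, base_widths, patch_size, in_channels,
                             has_bottleneck) {
  base_widths <- as.integer(base_widths)
  patch_size <- as.integer(patch_size)
  if (length(base_widths) != 3L || any(base_widths < 1L)) {
    abort("`base_widths` must be three positive channel counts.")
  }
  if (patch_size %% 8L != 0L) {
    abort(sprintf("`patch_size` (%d) must be divisible by 8.", patch_size))
  }
  if (has_bottleneck && patch_size < 64L) {
    abort("LPNet needs `patch_size` >= 64 for the hourglass interior.")
  }
  structure(
    list(
      name = name,
      input_shape = c(patch_size, patch_size, as.integer(in_channels)),
      base_widths = base_widths,
      patch_size = patch_size,
      in_channels = as.integer(in_channels),
      has_bottleneck = has_bottleneck,
      n_hourglass = if (has_bottleneck) 3L else 0L
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %s: input %s, widths %s, %d hourglass(es), %s parameters\n",
    x$name, paste(x$input_shape, collapse = "x"),
    paste(x$base_widths, collapse = "/"), x$n_hourglass,
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

# Flat table of every parameterised layer, consumed both by the parameter
# counter and by the model builder so the two can never disagree.
# Residual module (bottleneck block): 1x1 (C) -> 3x3 (C) -> 1x1 (2C) with an
# identity or 1x1-projection skip; the hourglass carries 4 such modules down,
# 4 up, one per skip branch (3), and a final 1x1 projection back to C.
spec_layer_table <- function(spec) {
  w <- spec$base_widths
  rows <- list()
  add <- function(id, kind, k, cin, cout) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, kind = kind, kernel = k, in_channels = cin, out_channels = cout
    )
  }
  add_rm <- function(id, cin, mid) {
    add(paste0(id, "/reduce"), "conv", 1L, cin, mid)
    add(paste0(id, "/body"), "conv", 3L, mid, mid)
    add(paste0(id, "/expand"), "conv", 1L, mid, 2L * mid)
    if (cin != 2L * mid) add(paste0(id, "/skip_proj"), "conv", 1L, cin, 2L * mid)
  }
  cin <- spec$in_channels
  for (i in 1:3) {
    add(sprintf("enc%d/conv1", i), "conv", 3L, cin, w[i])
    add(sprintf("enc%d/bn1", i), "bn", NA_integer_, w[i], w[i])
    add(sprintf("enc%d/conv2", i), "conv", 3L, w[i], w[i])
    add(sprintf("enc%d/bn2", i), "bn", NA_integer_, w[i], w[i])
    cin <- w[i]
  }
  if (spec$has_bottleneck) {
    C <- w[3]
    for (h in 1:3) {
      hid <- sprintf("hourglass%d", h)
      add_rm(sprintf("%s/down1", hid), C, C)
      for (j in 2:4) add_rm(sprintf("%s/down%d", hid, j), 2L * C, C)
      for (j in 1:3) add_rm(sprintf("%s/skip%d", hid, j), 2L * C, C)
      for (j in 1:4) add_rm(sprintf("%s/up%d", hid, j), 2L * C, C)
      add(sprintf("%s/proj", hid), "conv", 1L, 2L * C, C)
    }
  }
  tin <- c(w[3], w[3], w[2])
  tout <- c(w[3], w[2], w[2])
  dwidth <- c(w[3], w[2], w[1])
  skipw <- c(w[3], w[2], w[1])
  for (i in 1:3) {
    add(sprintf("dec%d/tconv", i), "tconv", 3L, tin[i], tout[i])
    add(sprintf("dec%d/conv1", i), "conv", 3L, tout[i] + skipw[i], dwidth[i])
    add(sprintf("dec%d/bn1", i), "bn", NA_integer_, dwidth[i], dwidth[i])
    add(sprintf("dec%d/conv2", i), "conv", 3L, dwidth[i], dwidth[i])
    add(sprintf("dec%d/bn2", i), "bn", NA_integer_, dwidth[i], dwidth[i])
  }
  add("head/conv", "conv", 3L, w[1], 1L)
  dplyr::bind_rows(rows)
}

#' Count trainable parameters of a network specification
#'
#' Closed-form weight and bias count from the layer table: `k^2 * cin * cout
#' + cout` per (transpose) convolution and `2 * c` per batch-normalisation
#' layer (scale and shift). Equals the number of scalar parameters held by
#' the model that [build_network()] realises from the same spec.
#'
#' @param spec A `network_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  tab <- spec_layer_table(spec)
  per <- ifelse(
    tab$kind == "bn",
    2L * tab$out_channels,
    tab$kernel^2 * tab$in_channels * tab$out_channels + tab$out_channels
  )
  sum(per)
}

#' Trace tensor shapes through a network specification
#'
#' Pure shape arithmetic, no weights: stride-1 3x3 convolutions with padding
#' 1 preserve height and width, 2x2 max-pooling halves them, stride-2
#' transpose convolutions double them, hourglasses preserve them, and
#' concatenation sums channels. At the default LPNet/GMRNet specification the
#' emitted rows reproduce the architecture's published encoder, hourglass,
#' and decoder layer tables cell by cell.
#'
#' @param spec A `network_spec`.
#' @param input_shape Optional `c(height, width, channels)` override; defaults
#'   to the spec's own input shape.
#' @return A tibble with columns `stage`, `layer`, `height`, `width`,
#'   `channels`, ordered as the data flows.
#' @export
shape_trace <- function(spec, input_shape = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  shp <- if (is.null(input_shape)) spec$input_shape else as.integer(input_shape)
  if (length(shp) != 3L || any(shp < 1L)) {
    abort("`input_shape` must be c(height, width, channels).")
  }
  if (shp[3] != spec$in_channels) {
    abort(sprintf("enc1/conv1: expected %d input channels, got %d.",
                  spec$in_channels, shp[3]))
  }
  w <- spec$base_widths
  rows <- list()
  emit <- function(stage, layer, s) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = stage, layer = layer,
      height = s[1], width = s[2], channels = s[3]
    )
  }
  s <- shp
  emit("input", "input", s)
  skips <- list()
  for (i in 1:3) {
    st <- sprintf("encoder_block_%d", i)
    emit(st, "input", s)
    s <- c(s[1], s[2], w[i])
    emit(st, "output", s)
    skips[[i]] <- s
    emit(st, "pool_input", s)
    if (s[1] %% 2L != 0L || s[2] %% 2L != 0L) {
      abort(sprintf("%s/pool: spatial dims %dx%d not divisible by 2.",
                    st, s[1], s[2]))
    }
    s <- c(s[1] %/% 2L, s[2] %/% 2L, s[3])
    emit(st, "pool_output", s)
  }
  if (spec$has_bottleneck) {
    for (h in 1:3) {
      st <- sprintf("hourglass_%d", h)
      emit(st, "input", s)
      emit(st, "output", s) # hourglass preserves shape
      if (h == 1L) {
        s <- c(2L * s[1], 2L * s[2], s[3])
        emit(st, "after_scale_up", s)
      } else if (h == 2L) {
        s <- c(s[1] %/% 2L, s[2] %/% 2L, s[3])
        emit(st, "after_scale_down", s)
      }
    }
  }
  tout <- c(w[3], w[2], w[2])
  dwidth <- c(w[3], w[2], w[1])
  for (i in 1:3) {
    st <- sprintf("decoder_block_%d", i)
    emit(st, "tconv_input", s)
    s <- c(2L * s[1], 2L * s[2], tout[i])
    emit(st, "tconv_output", s)
    emit(st, "input", s) # as tabulated: the upsampled map entering the block
    sk <- skips[[4L - i]]
    if (!all(s[1:2] == sk[1:2])) {
      abort(sprintf("%s/concat: %dx%d does not match skip %dx%d.",
                    st, s[1], s[2], sk[1], sk[2]))
    }
    s <- c(s[1], s[2], s[3] + sk[3])
    emit(st, "after_concat", s)
    s <- c(s[1], s[2], dwidth[i])
    emit(st, "output", s)
  }
  s <- c(s[1], s[2], 1L)
  emit("head", "output", s)
  dplyr::bind_rows(rows)
}

#' @export
tidy.network_spec <- function(x, ...) shape_trace(x)

#' @export
glance.network_spec <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    input_height = x$input_shape[1],
    input_width = x$input_shape[2],
    input_channels = x$input_shape[3],
    n_hourglass = x$n_hourglass,
    n_parameters = count_parameters(x)
  )
}
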