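# Realising a network_spec as a trainable model and running it.

build_rm <- function(cin, mid) {
  rm <- new.env(parent = emptyenv())
  rm$reduce <- new_conv(cin, mid, 1L)
  rm$body <- new_conv(mid, mid, 3L)
  rm$expand <- new_conv(mid, 2L * mid, 1L)
  rm$proj <- if (cin != 2L * mid) new_conv(cin, 2L * mid, 1L) else NULL
  rm
}

build_hourglass <- function(C) {
  hg <- new.env(parent = emptyenv())
  hg$down <- c(list(build_rm(C, C)), lapply(2:4, function(i) build_rm(2L * C, C)))
  hg$skip <- lapply(1:3, function(i) build_rm(2L * C, C))
  hg$up <- lapply(1:4, function(i) build_rm(2L * C, C))
  hg$proj <- new_conv(2L * C, C, 1L)
  hg
}

rm_layers <- function(rm) {
  ls <- list(rm$reduce, rm$body, rm$expand)
  if (!is.null(rm$proj)) ls <- c(ls, list(rm$proj))
  ls
}

hg_layers <- function(hg) {
  unlist(lapply(c(hg$down, hg$skip, hg$up), rm_layers), use.names = FALSE,
         recursive = FALSE) |> c(list(hg$proj))
}

#' Build a trainable model from a network specification
#'
#' Instantiates every layer of the spec with He-normal initial weights drawn
#' reproducibly from `seed`, without touching the global RNG stream. The
#' realised layer shapes equal the [shape_trace()] arithmetic, and the total
#' number of scalar parameters equals [count_parameters()].
#'
#' @param spec A `network_spec` from [lpnet_spec()] or [gmrnet_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `spike_network` model handle (a mutable environment).
#' @export
#' @examples
#' net <- build_network(gmrnet_spec(c(2, 3, 4), patch_size = 16), seed = 1)
#' p <- predict_network(net, array(runif(16 * 16), c(16, 16, 1, 1)))
#' range(p)
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$base_widths
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  withr::with_seed(as.integer(seed), {
    cin <- spec$in_channels
    model$enc <- lapply(1:3, function(i) {
      blk <- new.env(parent = emptyenv())
      blk$conv1 <- new_conv(cin, w[i], 3L)
      blk$bn1 <- new_bn(w[i])
      blk$conv2 <- new_conv(w[i], w[i], 3L)
      blk$bn2 <- new_bn(w[i])
      cin <<- w[i]
      blk
    })
    model$hg <- if (spec$has_bottleneck) {
      lapply(1:3, function(h) build_hourglass(w[3]))
    } else {
      list()
    }
    tin <- c(w[3], w[3], w[2])
    tout <- c(w[3], w[2], w[2])
    dwidth <- c(w[3], w[2], w[1])
    skipw <- c(w[3], w[2], w[1])
    model$dec <- lapply(1:3, function(i) {
      blk <- new.env(parent = emptyenv())
      blk$tconv <- new_conv(tin[i], tout[i], 3L)
      blk$conv1 <- new_conv(tout[i] + skipw[i], dwidth[i], 3L)
      blk$bn1 <- new_bn(dwidth[i])
      blk$conv2 <- new_conv(dwidth[i], dwidth[i], 3L)
      blk$bn2 <- new_bn(dwidth[i])
      blk
    })
    model$head <- new_conv(w[1], 1L, 3L)
  })
  layers <- list()
  for (blk in model$enc) layers <- c(layers, list(blk$conv1, blk$bn1, blk$conv2, blk$bn2))
  for (hg in model$hg) layers <- c(layers, hg_layers(hg))
  for (blk in model$dec) layers <- c(layers, list(blk$tconv, blk$conv1, blk$bn1, blk$conv2, blk$bn2))
  layers <- c(layers, list(model$head))
  model$layers <- layers
  model$params <- unlist(lapply(layers, layer_params), recursive = FALSE)
  class(model) <- "spike_network"
  model
}

#' @export
print.spike_network <- function(x, ...) {
  cat(sprintf("<spike_network> %s (%s scalar parameters)\n", x$spec$name,
              format(n_model_parameters(x), big.mark = ",")))
  invisible(x)
}

# Number of scalars actually held by the built model (cross-check for
# count_parameters()).
n_model_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

rm_forward <- function(tape, x, rm) {
  a <- op_relu(tape, op_conv(tape, x, rm$reduce))
  b <- op_relu(tape, op_conv(tape, a, rm$body))
  cc <- op_conv(tape, b, rm$expand)
  s <- if (is.null(rm$proj)) x else op_conv(tape, x, rm$proj)
  op_relu(tape, op_add(tape, cc, s))
}

hg_forward <- function(tape, x, hg) {
  e1 <- rm_forward(tape, x, hg$down[[1]])
  p1 <- op_maxpool(tape, e1)
  e2 <- rm_forward(tape, p1, hg$down[[2]])
  p2 <- op_maxpool(tape, e2)
  e3 <- rm_forward(tape, p2, hg$down[[3]])
  p3 <- op_maxpool(tape, e3)
  e4 <- rm_forward(tape, p3, hg$down[[4]])
  u1 <- rm_forward(tape, op_add(tape, op_upsample2(tape, e4),
                                rm_forward(tape, e3, hg$skip[[1]])), hg$up[[1]])
  u2 <- rm_forward(tape, op_add(tape, op_upsample2(tape, u1),
                                rm_forward(tape, e2, hg$skip[[2]])), hg$up[[2]])
  u3 <- rm_forward(tape, op_add(tape, op_upsample2(tape, u2),
                                rm_forward(tape, e1, hg$skip[[3]])), hg$up[[3]])
  op_conv(tape, rm_forward(tape, u3, hg$up[[4]]), hg$proj)
}

enc_block_forward <- function(tape, x, blk, train) {
  h <- op_bn(tape, op_relu(tape, op_conv(tape, x, blk$conv1)), blk$bn1, train)
  op_bn(tape, op_relu(tape, op_conv(tape, h, blk$conv2)), blk$bn2, train)
}

# `x` is [H, W, C, N]; internally the engine runs channels-first and the
# returned tensor is [1, H, W, N].
net_forward <- function(model, x, train = FALSE, tape = NULL) {
  stopifnot(length(dim(x)) == 4L)
  h <- new_tensor(aperm(x, c(3, 1, 2, 4)))
  h$leaf <- TRUE
  skips <- vector("list", 3L)
  for (i in 1:3) {
    h <- enc_block_forward(tape, h, model$enc[[i]], train)
    skips[[i]] <- h
    h <- op_maxpool(tape, h)
  }
  if (model$spec$has_bottleneck) {
    h <- hg_forward(tape, h, model$hg[[1]])
    h <- op_upsample2(tape, h)
    h <- hg_forward(tape, h, model$hg[[2]])
    h <- op_maxpool(tape, h)
    h <- hg_forward(tape, h, model$hg[[3]])
  }
  for (i in 1:3) {
    blk <- model$dec[[i]]
    h <- op_tconv(tape, h, blk$tconv)
    h <- op_concat(tape, h, skips[[4L - i]])
    h <- op_bn(tape, op_relu(tape, op_conv(tape, h, blk$conv1)), blk$bn1, train)
    h <- op_bn(tape, op_relu(tape, op_conv(tape, h, blk$conv2)), blk$bn2, train)
  }
  op_sigmoid(tape, op_conv(tape, h, model$head))
}

#' Run a built network on a batch of inputs
#'
#' @param model A `spike_network` from [build_network()].
#' @param x Input array `[height, width, channels, batch]`, or
#'   `[height, width, channels]` for a single sample. Images are expected on
#'   the `[0, 1]` scale.
#' @return Spike-probability array of the same spatial size with one channel,
#'   `[height, width, 1, batch]`; values in `[0, 1]`.
#' @export
predict_network <- function(model, x) {
  stopifnot(inherits(model, "spike_network"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  out <- net_forward(model, x, train = FALSE, tape = NULL)
  aperm(out$value, c(2, 3, 1, 4))
}

#' Serialise model weights to a plain-text-free R list
#'
#' Returns the spec and a flat list of parameter arrays (plus batch-norm
#' running statistics) so a model can be rebuilt exactly with
#' [restore_network()]. Kept as plain R objects so callers choose the
#' on-disk format.
#'
#' @param model A `spike_network`.
#' @return A list with elements `spec`, `params`, `running`.
#' @export
network_state <- function(model) {
  list(
    spec = model$spec,
    params = lapply(model$params, function(p) p$value),
    running = lapply(model$layers, function(l) {
      if (l$kind == "bn") list(rmean = l$rmean, rvar = l$rvar) else NULL
    })
  )
}

#' Rebuild a model from a saved state
#'
#' @param state A list produced by [network_state()].
#' @return A `spike_network` with the stored weights.
#' @export
restore_network <- function(state) {
  model <- build_network(state$spec, seed = 0L)
  stopifnot(length(model$params) == length(state$params))
  for (i in seq_along(state$params)) {
    stopifnot(length(model$params[[i]]$value) == length(state$params[[i]]))
    model$params[[i]]$value <- state$params[[i]]
  }
  for (i in seq_along(model$layers)) {
    if (!is.null(state$running[[i]])) {
      model$layers[[i]]$rmean <- state$running[[i]]$rmean
      model$layers[[i]]$rvar <- state$running[[i]]$rvar
    }
  }
  model
}
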