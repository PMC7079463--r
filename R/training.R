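# Data splitting, the pixel-wise binary cross-entropy loss, single-network
# training with Adam, and the two-stage modular training procedure
# (patch network first, then the refinement network on its merged outputs).

#' Training configuration
#'
#' The reference regime is Adam with learning rate 5e-4, 200 epochs, batch
#' size 32 and pixel-wise binary cross-entropy; every field is configurable
#' so CPU-scale variants (fewer epochs, smaller batches, a faster learning
#' rate) can be run.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs Number of passes over the data (>= 0; 0 leaves the model
#'   untouched).
#' @param batch_size Samples per gradient step (>= 1).
#' @param threshold Probability cut used downstream of the trained model.
#' @param seed Seed for shuffling (and any other training randomness).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 200L,
                         batch_size = 32L, threshold = 0.5, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (epochs < 0L) abort("`epochs` must be >= 0.")
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  structure(
    list(
      optimizer = "adam", loss = "binary_cross_entropy",
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), threshold = threshold,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Split plants into training and validation sets
#'
#' The split unit is the plant, never the image, so all three views of a
#' plant travel together and no view of a validation plant leaks into
#' training. The training set gets `floor(train_fraction * n)` plants.
#'
#' @param plant_ids Vector of plant identifiers (>= 2).
#' @param train_fraction Fraction of plants assigned to training.
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List with elements `train` and `validation`, disjoint and
#'   jointly exhaustive.
#' @export
#' @examples
#' split_dataset(paste0("p", 1:200), seed = 1) # 170 / 30
split_dataset <- function(plant_ids, train_fraction = 0.85, seed = 1L) {
  n <- length(plant_ids)
  if (n < 2L) abort("need at least 2 plants to split.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_train <- floor(train_fraction * n)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(
    train = plant_ids[sort(perm[seq_len(n_train)])],
    validation = plant_ids[sort(perm[(n_train + 1L):n])]
  )
}

#' Pixel-wise binary cross-entropy
#'
#' Mean over all pixels of `-(t log p + (1 - t) log(1 - p))`, each pixel
#' contributing uniformly; predictions are clipped to `[eps, 1 - eps]`.
#'
#' @param predicted Probabilities, any numeric array.
#' @param target Binary targets of the same shape.
#' @param eps Clipping constant.
#' @return Scalar loss (>= 0).
#' @export
#' @examples
#' bce_loss(array(0.5, c(2, 2)), array(c(0, 1, 0, 1), c(2, 2))) # log(2)
bce_loss <- function(predicted, target, eps = 1e-7) {
  if (!identical(dim(predicted), dim(target)) &&
      length(predicted) != length(target)) {
    abort("`predicted` and `target` shapes differ.")
  }
  p <- pmin(pmax(predicted, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# Gradient of the mean BCE w.r.t. the (sigmoid) probabilities.
bce_grad <- function(predicted, target, eps = 1e-7) {
  p <- pmin(pmax(predicted, eps), 1 - eps)
  (p - target) / (p * (1 - p)) / length(target)
}

as_batch_array <- function(x, channels) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (length(d) == 2L) d <- c(d, 1L)
    arr <- array(0, c(d[1], d[2], d[3], length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    return(arr)
  }
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Train a network on paired rasters
#'
#' Runs Adam on the pixel-wise binary cross-entropy for `config$epochs`
#' epochs with seeded shuffling. Inputs are expected on the `[0, 1]` scale.
#'
#' @param model A `spike_network`.
#' @param inputs `[H, W, C, N]` array (or list of `[H, W, C]` arrays).
#' @param targets `[H, W, 1, N]` array (or list of `[H, W]` binary
#'   matrices).
#' @param config A [train_config()].
#' @return A `spike_training`: the trained `model` (also modified in
#'   place), a per-epoch `history` tibble, and the config.
#' @export
train_network <- function(model, inputs, targets, config) {
  stopifnot(inherits(model, "spike_network"), inherits(config, "train_config"))
  x <- as_batch_array(inputs, model$spec$in_channels)
  y <- as_batch_array(targets, 1L)
  n <- dim(x)[4]
  if (n == 0L) abort("empty training set.")
  if (dim(y)[4] != n) abort("inputs and targets disagree in sample count.")
  losses <- numeric(config$epochs)
  if (config$epochs > 0L) {
    withr::with_seed(config$seed, {
      opt <- new_adam(model$params, config$learning_rate)
      for (ep in seq_len(config$epochs)) {
        perm <- sample.int(n)
        tot <- 0
        for (start in seq(1L, n, by = config$batch_size)) {
          idx <- perm[start:min(start + config$batch_size - 1L, n)]
          xb <- x[, , , idx, drop = FALSE]
          yb <- aperm(y[, , , idx, drop = FALSE], c(3, 1, 2, 4))
          tape <- new_tape()
          out <- net_forward(model, xb, train = TRUE, tape = tape)
          l <- bce_loss(out$value, yb)
          if (!is.finite(l)) {
            abort(sprintf("non-finite loss at epoch %d; lower the learning rate.", ep))
          }
          run_backward(tape, out, bce_grad(out$value, yb))
          adam_step(opt)
          tot <- tot + l * length(idx)
        }
        losses[ep] <- tot / n
      }
    })
  }
  structure(
    list(model = model,
         history = tibble::tibble(epoch = seq_len(config$epochs), loss = losses),
         config = config),
    class = "spike_training"
  )
}

#' @export
print.spike_training <- function(x, ...) {
  if (nrow(x$history) == 0L) {
    cat("<spike_training> 0 epochs (model untouched)\n")
  } else {
    cat(sprintf("<spike_training> %d epochs, loss %.4f -> %.4f\n",
                nrow(x$history), x$history$loss[1],
                x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}

#' @export
tidy.spike_training <- function(x, ...) x$history

#' @export
glance.spike_training <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    initial_loss = if (nrow(h)) h$loss[1] else NA_real_,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_
  )
}

#' @export
autoplot.spike_training <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Two-stage modular training: patch network, then refinement network
#'
#' Stage 1 trains the patch network (LPNet) on the overlapping tiles of the
#' scenes versus the matching mask tiles. Stage 2 freezes it, reconstructs
#' one merged full-size probability map per scene from its patch
#' predictions, resizes the merged map (bilinear, kept continuous) and the
#' ground-truth mask (nearest) to the refinement network's input size, and
#' trains GMRNet on those pairs -- so the refinement stage consumes exactly
#' the stage-1 outputs and never sees the truth on its input side.
#'
#' @param scenes List of `scene_sample`s (or lists with `image` and `mask`).
#' @param lpnet,gmrnet Built `spike_network` models to train in place.
#' @param lp_config,gmr_config [train_config()]s for the two stages.
#' @param step Tile step in pixels.
#' @return A `multistage_fit`: trained `lpnet` and `gmrnet`, both training
#'   histories, and the tile/step bookkeeping (`n_patches`, `n_merged`).
#' @export
multistage_train <- function(scenes, lpnet, gmrnet, lp_config, gmr_config,
                             step = 100L) {
  if (length(scenes) == 0L) abort("`scenes` must be non-empty.")
  p <- lpnet$spec$patch_size
  imgs <- list(); msks <- list()
  for (s in scenes) {
    d <- dim(s$image)
    grid <- plan_grid(d[1], d[2], p, step)
    imgs <- c(imgs, extract_patches(s$image / 255, grid))
    msks <- c(msks, extract_patches(s$mask, grid))
  }
  lp_fit <- train_network(lpnet, imgs, msks, lp_config)
  g <- gmrnet$spec$patch_size
  n <- length(scenes)
  gx <- array(0, c(g, g, 1, n))
  gy <- array(0, c(g, g, 1, n))
  for (i in seq_len(n)) {
    s <- scenes[[i]]
    d <- dim(s$image)
    grid <- plan_grid(d[1], d[2], p, step)
    merged <- merge_patches(predict_patch_maps(lpnet, s$image, grid,
                                               lp_config$batch_size), grid)
    gx[, , 1, i] <- resize_map(merged, g, g, mode = "bilinear")
    gy[, , 1, i] <- resize_map(s$mask, g, g, mode = "nearest")
  }
  gmr_fit <- train_network(gmrnet, gx, gy, gmr_config)
  structure(
    list(lpnet = lpnet, gmrnet = gmrnet,
         lp_history = lp_fit$history, gmr_history = gmr_fit$history,
         n_patches = length(imgs), n_merged = n, step = as.integer(step)),
    class = "multistage_fit"
  )
}

#' @export
print.multistage_fit <- function(x, ...) {
  cat(sprintf("<multistage_fit> %d patches -> LPNet; %d merged maps -> GMRNet\n",
              x$n_patches, x$n_merged))
  invisible(x)
}

#' @export
tidy.multistage_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$lp_history, network = "LPNet"),
    dplyr::mutate(x$gmr_history, network = "GMRNet")
  )
}
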