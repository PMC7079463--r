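# End-to-end synthetic experiment: generate plants, train both stages,
# evaluate segmentation and counting on held-out plants. This is the
# CPU-scale counterpart of the full 200-plant protocol and the entry point
# the acceptance checks exercise.

#' Run the full pipeline on synthetic plants
#'
#' Generates `n_plants` synthetic plants (three views each, spike counts
#' drawn from `n_spikes_range`), splits them by plant into training and
#' held-out sets, runs the two-stage training, then evaluates pixel-level
#' segmentation metrics and the three-view maximum-count rule on the
#' held-out plants.
#'
#' @param n_plants Number of plants to simulate (three scenes each).
#' @param base_config A [scene_config()] describing the scenes; its
#'   `n_spikes` is overridden per plant.
#' @param n_spikes_range Inclusive integer range of per-plant spike counts.
#' @param widths Channel widths for both networks.
#' @param patch_size,step Tile geometry for the patch network; `patch_size`
#'   is also the refined-mask size.
#' @param lp_epochs,gmr_epochs,learning_rate,lp_batch_size,gmr_batch_size
#'   Training schedule for the two stages (the refinement stage sees far
#'   fewer samples, so it defaults to a smaller batch for more updates).
#' @param train_fraction Fraction of plants used for training (by plant).
#' @param connectivity,min_area Particle-counting settings on refined masks.
#' @param threshold Probability cut for the refined mask.
#' @param seed Master seed; every random draw derives from it.
#' @return A `spike_experiment` with the trained models, per-image
#'   segmentation metrics on the held-out plants, per-plant counts for every
#'   plant (the counting stage has no trained parameters), and their
#'   summaries.
#' @export
run_spike_experiment <- function(n_plants = 14L,
                                 base_config = scene_config_cpu(),
                                 n_spikes_range = c(4L, 8L),
                                 widths = c(4L, 8L, 16L),
                                 patch_size = 64L, step = 32L,
                                 lp_epochs = 20L, gmr_epochs = 30L,
                                 learning_rate = 3e-3,
                                 lp_batch_size = 16L, gmr_batch_size = 4L,
                                 train_fraction = 0.85,
                                 connectivity = 8L, min_area = 2L,
                                 threshold = 0.5, seed = 1L) {
  seed <- as.integer(seed)
  plant_ids <- sprintf("plant_%02d", seq_len(n_plants))
  draws <- withr::with_seed(seed, list(
    n_spikes = sample(seq(n_spikes_range[1], n_spikes_range[2]),
                      n_plants, replace = TRUE),
    plant_seeds = sample.int(.Machine$integer.max - 1L, n_plants)
  ))
  plants <- purrr::map(seq_len(n_plants), function(i) {
    cfg <- base_config
    cfg$n_spikes <- draws$n_spikes[i]
    validate_scene_config(cfg)
    generate_plant_views(cfg, seed = draws$plant_seeds[i], plant_id = plant_ids[i])
  })
  names(plants) <- plant_ids

  split <- split_dataset(plant_ids, train_fraction, seed = seed)
  train_scenes <- unlist(plants[split$train], recursive = FALSE,
                         use.names = FALSE)

  lpnet <- build_network(lpnet_spec(widths, patch_size, 3L), seed = seed)
  gmrnet <- build_network(gmrnet_spec(widths, patch_size, 1L), seed = seed + 1L)
  fit <- multistage_train(
    train_scenes, lpnet, gmrnet,
    lp_config = train_config(learning_rate, lp_epochs, lp_batch_size,
                             threshold, seed = seed + 2L),
    gmr_config = train_config(learning_rate, gmr_epochs, gmr_batch_size,
                              threshold, seed = seed + 3L),
    step = step
  )

  g <- gmrnet$spec$patch_size
  seg_rows <- list()
  count_rows <- list()
  for (pid in plant_ids) {
    held_out <- pid %in% split$validation
    masks <- vector("list", 3L)
    for (v in 1:3) {
      s <- plants[[pid]][[v]]
      res <- segment_image(s$image, lpnet, gmrnet, step = step,
                           threshold = threshold)
      if (held_out) {
        truth <- resize_map(s$mask, g, g, mode = "nearest")
        m <- segmentation_metrics(pixel_confusion(res$refined_mask, truth))
        seg_rows[[length(seg_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(plant_id = pid, view_angle = s$view_angle), m
        )
      }
      masks[[v]] <- res$refined_mask
    }
    pc <- count_spikes_plant(masks, connectivity, min_area)
    count_rows[[length(count_rows) + 1L]] <- tibble::tibble(
      plant_id = pid,
      held_out = held_out,
      true_count = plants[[pid]][[1]]$true_count,
      predicted_count = pc$final_count
    )
  }
  seg <- dplyr::bind_rows(seg_rows)
  counts <- dplyr::bind_rows(count_rows)
  structure(
    list(
      lpnet = lpnet, gmrnet = gmrnet, fit = fit,
      split = split, plants = plants,
      segmentation = seg,
      mean_f1 = mean(seg$f1),
      counts = counts,
      count_agreement = mean(counts$predicted_count == counts$true_count),
      settings = list(
        n_plants = n_plants, widths = widths, patch_size = patch_size,
        step = step, lp_epochs = lp_epochs, gmr_epochs = gmr_epochs,
        learning_rate = learning_rate, lp_batch_size = lp_batch_size,
        gmr_batch_size = gmr_batch_size, connectivity = connectivity,
        min_area = min_area, threshold = threshold, seed = seed
      )
    ),
    class = "spike_experiment"
  )
}

#' @export
print.spike_experiment <- function(x, ...) {
  cat(sprintf(
    "<spike_experiment> %d plants (%d held out): mean pixel F1 %.3f, exact-count agreement %.0f%%\n",
    x$settings$n_plants, length(x$split$validation),
    x$mean_f1, 100 * x$count_agreement
  ))
  invisible(x)
}

#' @export
tidy.spike_experiment <- function(x, ...) x$segmentation

#' @export
glance.spike_experiment <- function(x, ...) {
  tibble::tibble(
    n_plants = x$settings$n_plants,
    n_validation_plants = length(x$split$validation),
    mean_f1 = x$mean_f1,
    mean_ji = mean(x$segmentation$ji),
    count_agreement = x$count_agreement
  )
}

#' Evaluate trained models across illumination levels
#'
#' Applies gamma correction at each level to every scene, re-runs the full
#' segmentation pipeline, and averages the pixel metrics per level
#' (gamma = 1 being the unmodified scenes).
#'
#' @param lpnet,gmrnet Trained `spike_network` models.
#' @param scenes List of `scene_sample`s to evaluate on.
#' @param gammas Gamma levels; defaults to [default_gamma_levels()] plus 1.
#' @param step,threshold As in [segment_image()].
#' @return Tibble with one row per gamma level: the averaged pixel metrics.
#' @export
illumination_sweep <- function(lpnet, gmrnet, scenes,
                               gammas = sort(c(1, default_gamma_levels())),
                               step = 32L, threshold = 0.5) {
  g <- gmrnet$spec$patch_size
  purrr::map_dfr(gammas, function(gam) {
    pairs <- purrr::map(scenes, function(s) {
      img <- if (gam == 1) s$image else apply_gamma(s$image, gam)
      res <- segment_image(img, lpnet, gmrnet, step = step,
                           threshold = threshold)
      list(predicted = res$refined_mask,
           truth = resize_map(s$mask, g, g, mode = "nearest"))
    })
    dplyr::bind_cols(tibble::tibble(gamma = gam),
                     evaluate_dataset(pairs)$average)
  })
}

# ---- plotting ----------------------------------------------------------

raster_tibble <- function(img) {
  if (length(dim(img)) == 2L) {
    img <- array(rep(img * 255, 3L), c(dim(img), 3L))
  }
  H <- dim(img)[1]; W <- dim(img)[2]
  tibble::tibble(
    row = rep(seq_len(H), times = W),
    col = rep(seq_len(W), each = H),
    fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3], maxColorValue = 255)
  )
}

plot_raster <- function(img, title) {
  df <- raster_tibble(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.scene_sample <- function(object, which = c("image", "mask"), ...) {
  which <- match.arg(which)
  if (which == "image") {
    plot_raster(object$image, sprintf("%s @ %d°", object$plant_id,
                                      object$view_angle))
  } else {
    plot_raster(object$mask, sprintf("%s @ %d° (mask)", object$plant_id,
                                     object$view_angle))
  }
}

#' @export
autoplot.segmentation_result <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$refined_map)), times = ncol(object$refined_map)),
    col = rep(seq_len(ncol(object$refined_map)), each = nrow(object$refined_map)),
    probability = as.vector(object$refined_map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Refined spike-probability map", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spike_experiment <- function(object, ...) {
  df <- object$counts
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_count,
                                   y = .data$predicted_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_count(colour = "steelblue") +
    ggplot2::labs(x = "true spike count", y = "predicted spike count",
                  title = "Three-view maximum count vs ground truth") +
    ggplot2::theme_minimal()
}
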