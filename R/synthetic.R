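# Synthetic single-plant scenes with known spike masks and counts.
#
# A scene is a uniform grey background, a green stem with a few green leaf
# strokes, and n_spikes textured golden elliptical blobs (the spikes); the
# ground-truth mask marks exactly the spike pixels. This emulates the
# imaging-cabinet situation the method targets -- one plant per image on a
# uniform background, spikes chromatically and texturally distinct from
# foliage -- while staying fully synthetic and seedable.

#' Configuration of a synthetic plant scene
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_spikes Number of spikes on the plant (>= 0).
#' @param spike_axis_range Length-2 range (pixels) for the ellipse
#'   semi-major axis; the semi-minor axis is drawn as roughly half of it.
#' @param overlap_probability Chance, per spike after the first, that it is
#'   deliberately placed touching an existing spike (reproducing the linked-
#'   object undercount failure mode); 0 guarantees pairwise separation.
#' @param n_leaves Number of leaf strokes.
#' @param background_intensity Background grey level, 0--255.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise (applied per channel, then clipped and rounded).
#' @param spike_color,foliage_color RGB triples (0--255) for spikes and for
#'   stem/leaves; keeping their hues apart guarantees a learnable signal.
#' @param min_separation Minimum center-to-center clearance (pixels) beyond
#'   the two semi-major axes when spikes must not touch.
#' @param visible_probability Per-spike, per-view visibility used by
#'   [generate_plant_views()] for the views that are not the reference view.
#' @param seed Default seed used when the generating functions are called
#'   without one.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_height = 1656L, image_width = 1356L,
                         n_spikes = 8L,
                         spike_axis_range = c(40, 80),
                         overlap_probability = 0,
                         n_leaves = 6L,
                         background_intensity = 205,
                         noise_sd = 4,
                         spike_color = c(210, 175, 60),
                         foliage_color = c(60, 140, 50),
                         min_separation = 6,
                         visible_probability = 0.85,
                         seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_spikes = as.integer(n_spikes),
    spike_axis_range = as.numeric(spike_axis_range),
    overlap_probability = as.numeric(overlap_probability),
    n_leaves = as.integer(n_leaves),
    background_intensity = as.numeric(background_intensity),
    noise_sd = as.numeric(noise_sd),
    spike_color = as.numeric(spike_color),
    foliage_color = as.numeric(foliage_color),
    min_separation = as.numeric(min_separation),
    visible_probability = as.numeric(visible_probability),
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

#' Small-canvas preset for CPU-scale runs
#'
#' 96 x 96 scenes sized for 64 px patches with a 32 px step (a 2 x 2 tile
#' grid): the smallest canvas on which every structural element of the
#' pipeline -- overlapping tiles, clamped offsets, merging, multi-view
#' counting -- is still exercised, while a pure-R training run stays fast.
#'
#' @param ... Overrides passed on to [scene_config()].
#' @export
scene_config_cpu <- function(...) {
  defaults <- list(
    image_height = 96L, image_width = 96L,
    n_spikes = 5L, spike_axis_range = c(4.5, 7),
    n_leaves = 3L, min_separation = 8, noise_sd = 4
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

validate_scene_config <- function(cfg) {
  if (cfg$n_spikes < 0L) abort("`n_spikes` must be >= 0.")
  if (cfg$overlap_probability < 0 || cfg$overlap_probability > 1) {
    abort("`overlap_probability` must lie in [0, 1].")
  }
  if (length(cfg$spike_axis_range) != 2L ||
      any(cfg$spike_axis_range < 2) || diff(cfg$spike_axis_range) < 0) {
    abort("`spike_axis_range` must be an increasing range with minimum >= 2.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  need <- 4 * (cfg$spike_axis_range[2] + cfg$min_separation)
  if (cfg$image_height < max(32, need) || cfg$image_width < max(32, need)) {
    abort(sprintf(
      "canvas %dx%d too small for spikes with semi-axis up to %.0f px (need >= %.0f).",
      cfg$image_height, cfg$image_width, cfg$spike_axis_range[2], max(32, need)
    ))
  }
  invisible(cfg)
}

# ---- low-level rasterisation ------------------------------------------

paint_pixels <- function(img, px, color) {
  if (nrow(px) == 0L) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  lin <- (px[, 2] - 1L) * H + px[, 1]
  for (ch in 1:3) img[lin + (ch - 1L) * H * W] <- color[[ch]]
  img
}

ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  r <- ceiling(max(a, b))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  dy <- rep(ys - cy, times = length(xs))
  dx <- rep(xs - cx, each = length(ys))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u * u + v * v <= 1
  cbind(row = rep(ys, times = length(xs))[keep],
        col = rep(xs, each = length(ys))[keep])
}

stroke_pixels <- function(pts, radius, H, W) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  rows <- outer(round(pts[, 1]), off$dy, `+`)
  cols <- outer(round(pts[, 2]), off$dx, `+`)
  keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  px <- unique(cbind(row = as.integer(rows[keep]), col = as.integer(cols[keep])))
  px
}

# ---- layout and rendering ---------------------------------------------

sample_spike_layout <- function(cfg) {
  H <- cfg$image_height; W <- cfg$image_width
  ax <- cfg$spike_axis_range
  placed <- list()
  for (i in seq_len(cfg$n_spikes)) {
    ok <- FALSE
    for (try in 1:500) {
      a <- runif(1, ax[1], ax[2])
      b <- a * runif(1, 0.45, 0.6)
      theta <- pi / 2 + rnorm(1, 0, 0.35) # near-vertical, like real ears
      margin <- a + 2
      cy <- runif(1, margin, 0.70 * H)
      cx <- runif(1, margin, W - margin)
      attach_prev <- length(placed) > 0 && runif(1) < cfg$overlap_probability
      if (attach_prev) {
        j <- sample(length(placed), 1L)
        ang <- runif(1, 0, 2 * pi)
        d <- (a + placed[[j]]$a) * runif(1, 0.45, 0.75)
        cy <- placed[[j]]$cy + d * sin(ang)
        cx <- placed[[j]]$cx + d * cos(ang)
        if (cy < margin || cy > H - margin || cx < margin || cx > W - margin) next
        ok <- TRUE
      } else {
        clear <- TRUE
        for (p in placed) {
          if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) <=
              a + p$a + cfg$min_separation) {
            clear <- FALSE
            break
          }
        }
        ok <- clear
      }
      if (ok) {
        placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, a = a, b = b,
                                              theta = theta)
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place %d spikes on a %dx%d canvas; enlarge the canvas or shrink `spike_axis_range`.",
        cfg$n_spikes, H, W
      ))
    }
  }
  placed
}

# RNG must already be set by the caller.
render_scene <- function(cfg, layout, visible, plant_id, view_angle) {
  H <- cfg$image_height; W <- cfg$image_width
  img <- array(cfg$background_intensity, c(H, W, 3))
  # stem
  x0 <- W / 2 + runif(1, -0.05, 0.05) * W
  tt <- seq(0, 1, length.out = 2L * H)
  stem <- cbind(H - tt * 0.8 * H, x0 + sin(tt * pi) * runif(1, -0.03, 0.03) * W)
  img <- paint_pixels(img, stroke_pixels(stem, max(1.2, H / 80), H, W),
                      cfg$foliage_color)
  # leaves: arcs leaving the stem
  for (l in seq_len(cfg$n_leaves)) {
    t0 <- runif(1, 0.15, 0.7)
    y0 <- H - t0 * 0.8 * H
    side <- sample(c(-1, 1), 1)
    len <- runif(1, 0.2, 0.4) * min(H, W)
    s <- seq(0, 1, length.out = max(40L, as.integer(len * 2)))
    pts <- cbind(y0 - s * len * runif(1, 0.1, 0.5) + s^2 * len * 0.35,
                 x0 + side * s * len)
    col <- pmin(pmax(cfg$foliage_color + rnorm(3, 0, 12), 0), 255)
    img <- paint_pixels(img, stroke_pixels(pts, max(1, H / 110), H, W), col)
  }
  # spikes (drawn last so foliage never occludes them)
  mask <- matrix(0L, H, W)
  centroids <- list()
  for (i in seq_along(layout)) {
    if (!visible[i]) next
    sp <- layout[[i]]
    px <- ellipse_pixels(sp$cy, sp$cx, sp$a, sp$b, sp$theta, H, W)
    tex <- runif(nrow(px), 0.78, 1.12) # speckle so spikes are textured
    lin <- (px[, 2] - 1L) * H + px[, 1]
    for (ch in 1:3) {
      img[lin + (ch - 1L) * H * W] <-
        pmin(pmax(cfg$spike_color[ch] * tex, 0), 255)
    }
    mask[lin] <- 1L
    centroids[[length(centroids) + 1L]] <-
      tibble::tibble(spike = i, row = sp$cy, col = sp$cx)
  }
  if (cfg$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))
  structure(
    list(
      image = img,
      mask = mask,
      true_count = length(layout),
      n_visible = sum(visible),
      spike_centroids = if (length(centroids)) {
        dplyr::bind_rows(centroids)
      } else {
        tibble::tibble(spike = integer(), row = numeric(), col = numeric())
      },
      view_angle = view_angle,
      plant_id = plant_id
    ),
    class = "scene_sample"
  )
}

#' @export
print.scene_sample <- function(x, ...) {
  cat(sprintf("<scene_sample> %s @ %d deg: %dx%d, %d/%d spikes visible\n",
              x$plant_id, x$view_angle, dim(x$mask)[1], dim(x$mask)[2],
              x$n_visible, x$true_count))
  invisible(x)
}

#' Generate one synthetic plant scene
#'
#' Deterministic for a fixed `(config, seed)` pair. With
#' `overlap_probability = 0` the mask has exactly `n_spikes` connected
#' foreground components (8-connectivity).
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; defaults to the config's own.
#' @param plant_id Identifier stored with the sample.
#' @param view_angle Nominal view angle in degrees.
#' @return A `scene_sample`: `image` `[H, W, 3]` on 0--255, binary `mask`
#'   `[H, W]` (1 = spike), `true_count`, `spike_centroids`, `view_angle`,
#'   `plant_id`.
#' @export
#' @examples
#' s <- generate_scene(scene_config_cpu(n_spikes = 3), seed = 7)
#' s$true_count
generate_scene <- function(config, seed = config$seed, plant_id = "plant_1",
                           view_angle = 0L) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  withr::with_seed(as.integer(seed), {
    layout <- sample_spike_layout(config)
    render_scene(config, layout, rep(TRUE, length(layout)), plant_id, view_angle)
  })
}

#' Generate the three side views of one plant
#'
#' All three views (0, 120, 240 degrees) share the spike layout and the
#' plant-level `true_count`. One randomly chosen reference view shows every
#' spike; in each other view a spike is visible with probability
#' `visible_probability`. The maximum per-view visible count therefore
#' always equals the plant total, mirroring how a plant's full spike count
#' is only guaranteed to be recoverable from the best of its three views.
#'
#' @inheritParams generate_scene
#' @return A list of three `scene_sample`s keyed by angle.
#' @export
generate_plant_views <- function(config, seed = config$seed,
                                 plant_id = "plant_1") {
  stopifnot(inherits(config, "scene_config"))
  if (config$n_spikes < 1L) abort("`n_spikes` must be >= 1 for plant views.")
  angles <- c(0L, 120L, 240L)
  withr::with_seed(as.integer(seed), {
    layout <- sample_spike_layout(config)
    n <- length(layout)
    full_view <- sample(3L, 1L)
    vis <- matrix(runif(3L * n) < config$visible_probability, nrow = 3L)
    vis[full_view, ] <- TRUE
    # a lone spike is unoccluded from every angle
    if (n == 1L) vis[] <- TRUE
    views <- lapply(1:3, function(v) {
      render_scene(config, layout, vis[v, ], plant_id, angles[v])
    })
  })
  names(views) <- paste0("view_", angles)
  views
}

#' Gamma-correct an image
#'
#' Non-linear luminance remapping `out = 255 * (in / 255)^(1 / gamma)`,
#' rounded and clipped to 0--255, applied per channel. `gamma < 1` darkens
#' and `gamma > 1` brightens, so sweeping gamma from 0.1 to 2.5 runs from
#' strongly under- to strongly over-illuminated variants of a scene.
#'
#' @param image Numeric matrix or array on the 0--255 scale.
#' @param gamma Positive gamma level.
#' @return Raster of the same shape, integer-valued on 0--255.
#' @export
#' @examples
#' apply_gamma(matrix(128, 2, 2), gamma = 0.5) # all 64
apply_gamma <- function(image, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    abort("`gamma` must be a single positive number.")
  }
  out <- round(255 * (pmin(pmax(image, 0), 255) / 255)^(1 / gamma))
  out <- pmin(pmax(out, 0), 255)
  dim(out) <- dim(image)
  out
}

#' Standard illumination sweep levels
#'
#' The gamma levels used by the illumination-robustness protocol, ordered
#' from darkest to brightest (1 itself being the unmodified image).
#'
#' @return Numeric vector of gamma values.
#' @export
default_gamma_levels <- function() c(0.1, 0.3, 0.5, 1.5, 2.0, 2.5)
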