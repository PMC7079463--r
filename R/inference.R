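# End-to-end segmentation of a full plant image: overlapping tiles through
# the patch network, merged, resized, refined globally, thresholded.

#' Threshold a probability map into a binary mask
#'
#' @param map Numeric raster with values in `[0, 1]`.
#' @param threshold Probability cut in `[0, 1]`; pixels with value `>=`
#'   threshold become 1.
#' @return Integer raster of 0/1 with the same shape.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must lie in [0, 1].")
  out <- (map >= threshold) + 0L
  dim(out) <- dim(map)
  out
}

resize_weights <- function(n_in, n_out, mode) {
  # Map output pixel centers to input pixel-center coordinates.
  src <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
  Wm <- matrix(0, n_out, n_in)
  if (mode == "nearest") {
    idx <- pmin(pmax(round(src), 1L), n_in)
    Wm[cbind(seq_len(n_out), idx)] <- 1
  } else {
    s <- pmin(pmax(src, 1), n_in)
    i0 <- pmin(floor(s), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1L, n_out)
    w1 <- s - i0
    i1 <- pmin(i0 + 1L, n_in)
    Wm[cbind(seq_len(n_out), i0)] <- Wm[cbind(seq_len(n_out), i0)] + (1 - w1)
    Wm[cbind(seq_len(n_out), i1)] <- Wm[cbind(seq_len(n_out), i1)] + w1
  }
  Wm
}

#' Resize a raster
#'
#' Separable resize with an anisotropic scale (aspect ratio is not
#' preserved, as in the full-image 1656 x 1356 to 256 x 256 reduction).
#' Use `"bilinear"` for probability maps and images and `"nearest"` for
#' binary masks (which must stay binary).
#'
#' @param map Matrix `[H, W]` or array `[H, W, C]`.
#' @param out_height,out_width Target size in pixels.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return Resized raster of the requested size.
#' @export
resize_map <- function(map, out_height, out_width,
                       mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  out_height <- as.integer(out_height); out_width <- as.integer(out_width)
  if (out_height < 1L || out_width < 1L) {
    abort("target dimensions must be positive.")
  }
  d <- dim(map)
  Wr <- resize_weights(d[1], out_height, mode)
  Wc <- resize_weights(d[2], out_width, mode)
  if (length(d) == 2L) {
    out <- Wr %*% map %*% t(Wc)
    if (mode == "nearest" && is.integer(map)) storage.mode(out) <- "integer"
    return(out)
  }
  out <- array(0, c(out_height, out_width, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% map[, , ch] %*% t(Wc)
  out
}

#' Segment a full plant image into a refined spike mask
#'
#' Pipeline: plan the overlapping tile grid, run every tile through the
#' patch network (LPNet), merge the per-tile probability maps into a
#' full-size map, resize it (bilinear) to the refinement network's input
#' size, refine with GMRNet, and threshold. Deterministic for fixed weights
#' and input.
#'
#' @param image RGB array `[H, W, 3]` on 0--255.
#' @param lpnet,gmrnet Built `spike_network` models; the tile size is taken
#'   from the LPNet spec and the refined-mask size from the GMRNet spec.
#' @param step Tile step in pixels (default 100).
#' @param threshold Probability cut applied to the refined map.
#' @param batch_size Tiles per forward batch.
#' @return A `segmentation_result`: `merged_map` (full-size probabilities),
#'   `refined_map`, `refined_mask` (both at the GMRNet input size), `grid`.
#' @export
segment_image <- function(image, lpnet, gmrnet, step = 100L, threshold = 0.5,
                          batch_size = 32L) {
  stopifnot(inherits(lpnet, "spike_network"), inherits(gmrnet, "spike_network"))
  d <- dim(image)
  grid <- plan_grid(d[1], d[2], lpnet$spec$patch_size, step)
  maps <- predict_patch_maps(lpnet, image, grid, batch_size)
  merged <- merge_patches(maps, grid)
  g <- gmrnet$spec$patch_size
  refined_in <- resize_map(merged, g, g, mode = "bilinear")
  refined <- predict_network(gmrnet, array(refined_in, c(g, g, 1, 1)))[, , 1, 1]
  structure(
    list(
      merged_map = merged,
      refined_map = refined,
      refined_mask = binarize(refined, threshold),
      grid = grid
    ),
    class = "segmentation_result"
  )
}

# LPNet over all tiles of one image, batched; returns per-tile probability
# matrices in grid order. Image is taken on 0--255 and scaled to [0, 1].
predict_patch_maps <- function(lpnet, image, grid, batch_size = 32L) {
  patches <- extract_patches(image / 255, grid)
  p <- grid$patch_size
  n <- length(patches)
  maps <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- array(0, c(p, p, dim(image)[3], length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- patches[[idx[j]]]
    out <- predict_network(lpnet, x)
    for (j in seq_along(idx)) maps[[idx[j]]] <- out[, , 1, j]
  }
  maps
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> merged %dx%d, refined %dx%d, foreground %.1f%%\n",
    nrow(x$merged_map), ncol(x$merged_map),
    nrow(x$refined_mask), ncol(x$refined_mask),
    100 * mean(x$refined_mask)
  ))
  invisible(x)
}

#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(
    merged_height = nrow(x$merged_map),
    merged_width = ncol(x$merged_map),
    refined_size = nrow(x$refined_mask),
    foreground_fraction = mean(x$refined_mask)
  )
}
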