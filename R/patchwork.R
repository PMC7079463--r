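# Overlapping-tile planning, extraction and merging. Full-size images are
# segmented tile by tile (default 256x256 tiles every 100 px) and the
# per-tile probability maps are reassembled into a full-size map.

offsets_1d <- function(dim, patch_size, step, what) {
  if (dim < patch_size) {
    abort(sprintf("image %s (%d) is smaller than `patch_size` (%d).",
                  what, dim, patch_size))
  }
  off <- seq.int(0L, dim - patch_size, by = step)
  if (off[length(off)] != dim - patch_size) {
    off <- c(off, dim - patch_size) # clamped final tile flush with the border
  }
  as.integer(off)
}

#' Plan an overlapping patch grid
#'
#' Computes the 0-based top-left offsets of `patch_size`-square tiles placed
#' every `step` pixels; when the image size minus the patch size is not a
#' multiple of the step, a final clamped offset flush with the image border
#' is appended so every pixel is covered. The canonical full-plant setting
#' (1656 x 1356 image, 256 px patches, 100 px step) yields 15 x 12 = 180
#' tiles.
#'
#' @param height,width Image dimensions in pixels.
#' @param patch_size Tile side length in pixels (default 256).
#' @param step Offset between consecutive tiles in pixels (default 100, i.e.
#'   an overlap of `patch_size - step`).
#' @return A `patch_grid` object with fields `image_height`, `image_width`,
#'   `patch_size`, `step`, `row_offsets`, `col_offsets`, `n_tiles`.
#' @export
#' @examples
#' g <- plan_grid(1656, 1356, 256, 100)
#' g$n_tiles # 180
plan_grid <- function(height, width, patch_size = 256L, step = 100L) {
  height <- as.integer(height); width <- as.integer(width)
  patch_size <- as.integer(patch_size); step <- as.integer(step)
  if (step < 1L) abort("`step` must be >= 1.")
  ro <- offsets_1d(height, patch_size, step, "height")
  co <- offsets_1d(width, patch_size, step, "width")
  structure(
    list(
      image_height = height, image_width = width,
      patch_size = patch_size, step = step,
      row_offsets = ro, col_offsets = co,
      n_tiles = length(ro) * length(co)
    ),
    class = "patch_grid"
  )
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %dx%d image, %d px tiles every %d px: %d x %d = %d tiles\n",
              x$image_height, x$image_width, x$patch_size, x$step,
              length(x$row_offsets), length(x$col_offsets), x$n_tiles))
  invisible(x)
}

#' @export
tidy.patch_grid <- function(x, ...) {
  tibble::tibble(
    tile = seq_len(x$n_tiles),
    row_offset = rep(x$row_offsets, each = length(x$col_offsets)),
    col_offset = rep(x$col_offsets, times = length(x$row_offsets))
  )
}

grid_check_image <- function(image, grid) {
  d <- dim(image)
  if (d[1] != grid$image_height || d[2] != grid$image_width) {
    abort(sprintf("image is %dx%d but the grid was planned for %dx%d.",
                  d[1], d[2], grid$image_height, grid$image_width))
  }
}

#' Extract the tiles of a planned grid
#'
#' @param image A matrix `[H, W]` or array `[H, W, C]` matching the grid.
#' @param grid A `patch_grid` from [plan_grid()].
#' @return A list of `grid$n_tiles` patches in row-major tile order
#'   (row offset varying slowest), each `patch_size` square with the same
#'   number of channels as the input.
#' @export
extract_patches <- function(image, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  grid_check_image(image, grid)
  p <- grid$patch_size
  three_d <- length(dim(image)) == 3L
  out <- vector("list", grid$n_tiles)
  k <- 1L
  for (r in grid$row_offsets) {
    for (cc in grid$col_offsets) {
      out[[k]] <- if (three_d) {
        image[r + seq_len(p), cc + seq_len(p), , drop = FALSE]
      } else {
        image[r + seq_len(p), cc + seq_len(p), drop = FALSE]
      }
      k <- k + 1L
    }
  }
  out
}

#' Merge per-tile probability maps back into a full-size map
#'
#' Where tiles overlap, the per-pixel values are combined by the arithmetic
#' mean (default) or by the maximum. With the mean rule, merging the tiles
#' extracted from a map reproduces that map exactly, since equal overlapping
#' values average to themselves.
#'
#' @param patch_maps List of `patch_size`-square matrices with values in
#'   `[0, 1]`, in the row-major tile order of [extract_patches()].
#' @param grid The `patch_grid` the maps were produced on.
#' @param method Overlap resolution rule, `"mean"` or `"max"`.
#' @return A `[image_height, image_width]` matrix with values in `[0, 1]`.
#' @export
merge_patches <- function(patch_maps, grid, method = c("mean", "max")) {
  stopifnot(inherits(grid, "patch_grid"))
  method <- match.arg(method)
  if (length(patch_maps) != grid$n_tiles) {
    abort(sprintf("expected %d patch maps for this grid, got %d.",
                  grid$n_tiles, length(patch_maps)))
  }
  p <- grid$patch_size
  acc <- matrix(if (method == "mean") 0 else -Inf,
                grid$image_height, grid$image_width)
  cnt <- matrix(0L, grid$image_height, grid$image_width)
  k <- 1L
  for (r in grid$row_offsets) {
    for (cc in grid$col_offsets) {
      m <- patch_maps[[k]]
      if (!all(dim(m)[1:2] == c(p, p))) {
        abort(sprintf("patch map %d is not %dx%d.", k, p, p))
      }
      ri <- r + seq_len(p); ci <- cc + seq_len(p)
      if (method == "mean") {
        acc[ri, ci] <- acc[ri, ci] + m
      } else {
        acc[ri, ci] <- pmax(acc[ri, ci], m)
      }
      cnt[ri, ci] <- cnt[ri, ci] + 1L
      k <- k + 1L
    }
  }
  if (any(cnt == 0L)) abort("grid does not cover the image.") # unreachable by construction
  if (method == "mean") acc / cnt else acc
}
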