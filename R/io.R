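# PNG image/mask handling with the on-disk mask polarity convention:
# black (0) = spike, white (255) = background. In memory masks are always
# 1 = spike, 0 = background.

#' Read a binary spike mask from a PNG file
#'
#' Accepts 8-bit greyscale or RGB files; RGB is collapsed to luminance
#' first. Pixels darker than 128 map to spike (1), the rest to background
#' (0), so hand-made nearly-binary masks are read tolerantly; `strict = TRUE`
#' refuses files with intermediate grey levels.
#'
#' @param path PNG file path.
#' @param strict Require strictly binary pixel values.
#' @return Binary matrix, 1 = spike.
#' @export
read_mask <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  lev <- round(img * 255)
  if (strict && !all(lev %in% c(0, 255))) {
    abort(sprintf("mask %s is not strictly binary.", path))
  }
  (lev < 128) + 0L
}

#' Write a binary spike mask to a PNG file
#'
#' Spike pixels are written black (0) and background white (255), the
#' inverse of the in-memory coding, so [read_mask()] round-trips exactly.
#'
#' @param mask Binary matrix, 1 = spike.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) abort("`mask` must be binary.")
  png::writePNG(1 - mask, path)
  invisible(path)
}

#' Read an RGB image as a 0--255 array
#'
#' @param path PNG file path.
#' @return Array `[H, W, 3]` on the 0--255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write an RGB image from a 0--255 array
#'
#' @param image Array `[H, W, 3]` on 0--255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Write a scene sample (image, mask, manifest line) to a directory
#'
#' Produces `<plant>_<angle>.png`, `<plant>_<angle>_mask.png` (disk
#' polarity: 0 = spike) and appends a line to `manifest.tsv` with the plant
#' id, view angle, true count and seed.
#'
#' @param sample A `scene_sample`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Tibble with the written file paths, invisibly.
#' @export
write_scene <- function(sample, dir, seed = NA_integer_) {
  stopifnot(inherits(sample, "scene_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%d", sample$plant_id, sample$view_angle)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_mask.png"))
  write_image(sample$image, img_path)
  write_mask(sample$mask, mask_path)
  manifest <- file.path(dir, "manifest.tsv")
  line <- sprintf("%s\t%d\t%d\t%s", sample$plant_id, sample$view_angle,
                  sample$true_count, as.character(seed))
  if (!file.exists(manifest)) {
    writeLines(c("plant_id\tangle\ttrue_count\tseed", line), manifest)
  } else {
    cat(line, "\n", sep = "", file = manifest, append = TRUE)
  }
  invisible(tibble::tibble(image = img_path, mask = mask_path))
}
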