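# "Analyse particles"-style connected-component counting on binary masks.
#
# Objects are maximal connected foreground regions under 4- or 8-
# connectivity, found by flood filling the pixel adjacency graph: the
# vectorised edge list between neighbouring foreground pixels is decomposed
# into connected components. Touching objects necessarily merge into one
# region, which is the known undercount failure mode when spikes overlap.

#' Label and measure connected foreground objects in a binary mask
#'
#' @param mask Binary matrix (values 0/1 or logical), 1 = foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @param min_area Minimum object area in pixels; smaller regions are erased
#'   from the label map and excluded from the count (default 0, no filter).
#' @return A `particle_report`: `n_objects`, integer `label_map` (0 =
#'   background, labels 1..n in scan order of each object's first pixel),
#'   `areas` (pixels per object), `connectivity`, `min_area`.
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L; m[6:7, 6:7] <- 1L
#' analyse_particles(m)$n_objects # 2
analyse_particles <- function(mask, connectivity = 8L, min_area = 0L) {
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a binary matrix with values in {0, 1}.")
  }
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask == 1) # column-major linear indices
  label_map <- matrix(0L, H, W)
  if (length(fg) == 0L) {
    return(new_particle_report(0L, label_map, integer(), connectivity, min_area))
  }
  # Map linear index -> vertex id in the foreground graph.
  vid <- integer(H * W)
  vid[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  # Half the neighbourhood suffices for an undirected graph.
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- mask[nb] == 1
    if (any(hit)) {
      edges <- c(edges, rbind(vid[fg[ok][hit]], vid[nb[hit]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # Relabel so object 1 is the first reached in column-major scan order.
  first <- tapply(seq_along(fg), memb, min)
  ord <- rank(first)
  lab <- as.integer(ord[memb])
  areas <- tabulate(lab)
  if (min_area > 0L) {
    keep <- which(areas >= min_area)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    lab <- remap[lab]
    areas <- areas[keep]
  }
  label_map[fg] <- lab
  new_particle_report(length(areas), label_map, as.integer(areas),
                      connectivity, as.integer(min_area))
}

new_particle_report <- function(n, label_map, areas, connectivity, min_area) {
  structure(
    list(n_objects = n, label_map = label_map, areas = areas,
         connectivity = connectivity, min_area = min_area),
    class = "particle_report"
  )
}

#' @export
print.particle_report <- function(x, ...) {
  cat(sprintf("<particle_report> %d object(s), connectivity %d, min_area %d\n",
              x$n_objects, x$connectivity, x$min_area))
  invisible(x)
}

#' @export
tidy.particle_report <- function(x, ...) {
  tibble::tibble(object = seq_len(x$n_objects), area = x$areas)
}

#' Count spikes of one plant from its three side-view masks
#'
#' Counts objects per view with [analyse_particles()] and takes the maximum
#' over the three views as the plant's spike count, since no single view is
#' guaranteed to show every spike.
#'
#' @param view_masks List of exactly three binary masks, ordered (or named)
#'   by the view angles 0, 120, 240.
#' @inheritParams analyse_particles
#' @return A `plant_count` with `per_view` (tibble of angle and count) and
#'   `final_count = max(per-view counts)`.
#' @export
count_spikes_plant <- function(view_masks, connectivity = 8L, min_area = 0L) {
  if (!is.list(view_masks) || length(view_masks) != 3L) {
    abort("`view_masks` must be a list of exactly three masks.")
  }
  counts <- vapply(view_masks, function(m) {
    analyse_particles(m, connectivity, min_area)$n_objects
  }, integer(1))
  structure(
    list(
      per_view = tibble::tibble(angle = c(0L, 120L, 240L), count = counts),
      final_count = max(counts)
    ),
    class = "plant_count"
  )
}

#' @export
print.plant_count <- function(x, ...) {
  cat(sprintf("<plant_count> views %s -> final %d\n",
              paste(x$per_view$count, collapse = "/"), x$final_count))
  invisible(x)
}

#' @export
tidy.plant_count <- function(x, ...) x$per_view

#' @export
glance.plant_count <- function(x, ...) {
  tibble::tibble(final_count = x$final_count)
}
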