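# Independent oracles used across the suite.

# Queue-based flood fill over linear indices; the reference for
# analyse_particles(). Scan order is column-major, so labels are comparable
# directly as well as up to relabeling.
flood_fill_oracle <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  dr <- c(1L, -1L, 0L, 0L)
  dc <- c(0L, 0L, 1L, -1L)
  if (connectivity == 8L) {
    dr <- c(dr, 1L, 1L, -1L, -1L)
    dc <- c(dc, 1L, -1L, 1L, -1L)
  }
  cur <- 0L
  stack <- integer(H * W)
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (mask[i, j] == 1 && lab[i, j] == 0L) {
        cur <- cur + 1L
        top <- 1L
        stack[1L] <- (j - 1L) * H + i
        lab[i, j] <- cur
        while (top > 0L) {
          p <- stack[top]; top <- top - 1L
          pr <- ((p - 1L) %% H) + 1L
          pc <- ((p - 1L) %/% H) + 1L
          for (k in seq_along(dr)) {
            r <- pr + dr[k]; cc <- pc + dc[k]
            if (r >= 1L && r <= H && cc >= 1L && cc <= W &&
                mask[r, cc] == 1 && lab[r, cc] == 0L) {
              lab[r, cc] <- cur
              top <- top + 1L
              stack[top] <- (cc - 1L) * H + r
            }
          }
        }
      }
    }
  }
  list(n = cur, labels = lab)
}

# Partition equality of two label maps (up to renaming of labels).
same_partition <- function(a, b) {
  fg_a <- a > 0
  fg_b <- b > 0
  if (!identical(fg_a, fg_b)) return(FALSE)
  pairs <- unique(cbind(a[fg_a], b[fg_b]))
  nrow(pairs) == length(unique(a[fg_a])) &&
    nrow(pairs) == length(unique(b[fg_b]))
}

random_mask <- function(H, W, density, seed) {
  withr::with_seed(seed, matrix(rbinom(H * W, 1, density), H, W))
}

# Per-pixel loop confusion counter, the reference for pixel_confusion().
confusion_loop_oracle <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

tiny_gmr_net <- function(seed = 1L, patch = 16L) {
  build_network(gmrnet_spec(c(2L, 3L, 4L), patch_size = patch), seed = seed)
}

tiny_lp_net <- function(seed = 1L) {
  build_network(lpnet_spec(c(2L, 3L, 4L), patch_size = 64L), seed = seed)
}
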