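cpu_cfg <- scene_config_cpu()

test_that("scene generation is deterministic and honours the empty case", {
  s1 <- generate_scene(cpu_cfg, seed = 11)
  s2 <- generate_scene(cpu_cfg, seed = 11)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_false(identical(s1$image, generate_scene(cpu_cfg, seed = 12)$image))

  empty <- generate_scene(scene_config_cpu(n_spikes = 0), seed = 1)
  expect_equal(sum(empty$mask), 0)
  expect_equal(empty$true_count, 0)
})

test_that("generated scenes have valid geometry and value ranges", {
  s <- generate_scene(cpu_cfg, seed = 3)
  expect_equal(dim(s$image), c(96L, 96L, 3L))
  expect_equal(dim(s$mask), c(96L, 96L))
  expect_true(all(s$image >= 0 & s$image <= 255))
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_equal(nrow(s$spike_centroids), s$true_count)
})

test_that("non-overlapping spikes produce exactly true_count components", {
  # brute-force labeling oracle on one derived example
  s <- generate_scene(scene_config_cpu(n_spikes = 5), seed = 42)
  expect_equal(flood_fill_oracle(s$mask, 8L)$n, 5)
  # property over many seeds
  for (seed in 1:100) {
    cfg <- scene_config_cpu(n_spikes = 1 + seed %% 6)
    s <- generate_scene(cfg, seed = seed)
    expect_equal(analyse_particles(s$mask, 8L)$n_objects, cfg$n_spikes)
  }
})

test_that("spike and foliage pixels are chromatically separated", {
  s <- generate_scene(cpu_cfg, seed = 9)
  rgbmat <- apply(s$image, 3, function(ch) ch[s$mask == 1])
  spike_hue <- mean(grDevices::rgb2hsv(t(rgbmat), maxColorValue = 255)[1, ])
  foliage <- s$mask == 0 &
    (abs(s$image[, , 2] - 140) < 60) & (s$image[, , 2] > s$image[, , 3] + 30)
  fol <- apply(s$image, 3, function(ch) ch[foliage])
  foliage_hue <- mean(grDevices::rgb2hsv(t(fol), maxColorValue = 255)[1, ])
  expect_gt(abs(spike_hue - foliage_hue), 0.05)
})

test_that("three views share layout, and the best view shows the full count", {
  views <- generate_plant_views(cpu_cfg, seed = 21, plant_id = "p1")
  expect_length(views, 3)
  expect_equal(vapply(views, function(v) v$view_angle, integer(1),
                      USE.NAMES = FALSE), c(0L, 120L, 240L))
  expect_true(all(vapply(views, function(v) v$plant_id, character(1)) == "p1"))
  totals <- unname(vapply(views, function(v) v$true_count, integer(1)))
  expect_true(all(totals == totals[1]))
  visible <- vapply(views, function(v) v$n_visible, integer(1))
  expect_equal(max(visible), totals[1])
  expect_true(all(visible <= totals[1]))
  # per-view mask component count equals the view's visible count
  for (v in views) {
    expect_equal(analyse_particles(v$mask)$n_objects, v$n_visible)
  }
  # determinism
  again <- generate_plant_views(cpu_cfg, seed = 21, plant_id = "p1")
  expect_identical(views$view_0$image, again$view_0$image)

  one <- generate_plant_views(scene_config_cpu(n_spikes = 1), seed = 4)
  expect_true(all(vapply(one, function(v) v$n_visible, integer(1)) == 1L))
})

test_that("configuration errors are refused", {
  expect_error(scene_config_cpu(overlap_probability = 1.4), "overlap_probability")
  expect_error(scene_config_cpu(image_height = 20, image_width = 20), "too small")
  expect_error(scene_config(image_height = 64, image_width = 64,
                            spike_axis_range = c(40, 80)), "too small")
  expect_error(generate_plant_views(scene_config_cpu(n_spikes = 0), seed = 1),
               "n_spikes")
})

test_that("gamma correction follows the closed form and its symmetries", {
  expect_equal(apply_gamma(matrix(128, 2, 2), 0.5), matrix(64, 2, 2))
  ramp <- matrix(0:255, nrow = 1)
  expect_equal(apply_gamma(ramp, 1), ramp) # identity at gamma 1
  for (g in c(0.1, 0.3, 2.5)) {
    out <- apply_gamma(ramp, g)
    expect_equal(out[1], 0) # endpoints fixed
    expect_equal(out[256], 255)
    expect_true(all(diff(as.vector(out)) >= 0)) # monotone
  }
  # darker-to-brighter ordering
  expect_lt(mean(apply_gamma(ramp, 0.1)), mean(ramp))
  expect_gt(mean(apply_gamma(ramp, 2.5)), mean(ramp))
  expect_error(apply_gamma(ramp, 0), "positive")
  expect_error(apply_gamma(ramp, -1), "positive")
})

test_that("gamma then inverse gamma returns within quantisation error", {
  # Rounding to integer levels makes the darkening direction lossy (many
  # dark levels collapse before the inverse can restore them), so the
  # quantisation-only +/-2 bound applies to the expanding application first.
  # At gamma 0.1 the inverse map has slope 10 near the bright end and even
  # that ordering cannot stay within +/-2.
  ramp <- matrix(0:255, nrow = 1)
  for (g in c(0.3, 0.5, 1.5, 2.0, 2.5)) {
    gb <- max(g, 1 / g)
    back <- apply_gamma(apply_gamma(ramp, gb), 1 / gb)
    expect_true(all(abs(back - ramp) <= 2))
  }
})
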