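trace_shape <- function(tr, stage_, layer_) {
  row <- dplyr::filter(tr, .data$stage == stage_, .data$layer == layer_)
  unname(unlist(row[1, c("height", "width", "channels")]))
}

test_that("default LPNet trace reproduces the encoder table cell by cell", {
  tr <- shape_trace(lpnet_spec())
  # block: input / output / pooled output
  expected <- list(
    list(1, c(256, 256, 3), c(256, 256, 16), c(128, 128, 16)),
    list(2, c(128, 128, 16), c(128, 128, 64), c(64, 64, 64)),
    list(3, c(64, 64, 64), c(64, 64, 128), c(32, 32, 128))
  )
  for (e in expected) {
    st <- sprintf("encoder_block_%d", e[[1]])
    expect_equal(trace_shape(tr, st, "input"), e[[2]])
    expect_equal(trace_shape(tr, st, "output"), e[[3]])
    expect_equal(trace_shape(tr, st, "pool_input"), e[[3]])
    expect_equal(trace_shape(tr, st, "pool_output"), e[[4]])
  }
})

test_that("default LPNet trace reproduces the hourglass table", {
  tr <- shape_trace(lpnet_spec())
  expect_equal(trace_shape(tr, "hourglass_1", "input"), c(32, 32, 128))
  expect_equal(trace_shape(tr, "hourglass_1", "output"), c(32, 32, 128))
  expect_equal(trace_shape(tr, "hourglass_1", "after_scale_up"), c(64, 64, 128))
  expect_equal(trace_shape(tr, "hourglass_2", "input"), c(64, 64, 128))
  expect_equal(trace_shape(tr, "hourglass_2", "output"), c(64, 64, 128))
  expect_equal(trace_shape(tr, "hourglass_2", "after_scale_down"), c(32, 32, 128))
  expect_equal(trace_shape(tr, "hourglass_3", "input"), c(32, 32, 128))
  expect_equal(trace_shape(tr, "hourglass_3", "output"), c(32, 32, 128))
})

test_that("default trace reproduces the decoder table and head", {
  tr <- shape_trace(lpnet_spec())
  expected <- list(
    list(1, c(32, 32, 128), c(64, 64, 128), c(64, 64, 256), c(64, 64, 128)),
    list(2, c(64, 64, 128), c(128, 128, 64), c(128, 128, 128), c(128, 128, 64)),
    list(3, c(128, 128, 64), c(256, 256, 64), c(256, 256, 80), c(256, 256, 16))
  )
  for (e in expected) {
    st <- sprintf("decoder_block_%d", e[[1]])
    expect_equal(trace_shape(tr, st, "tconv_input"), e[[2]])
    expect_equal(trace_shape(tr, st, "tconv_output"), e[[3]])
    expect_equal(trace_shape(tr, st, "input"), e[[3]])
    expect_equal(trace_shape(tr, st, "after_concat"), e[[4]])
    expect_equal(trace_shape(tr, st, "output"), e[[5]])
  }
  expect_equal(trace_shape(tr, "head", "output"), c(256, 256, 1))
})

test_that("GMRNet spec mirrors LPNet without the bottleneck", {
  gs <- gmrnet_spec()
  expect_equal(gs$input_shape, c(256L, 256L, 1L))
  expect_equal(gs$n_hourglass, 0L)
  tr <- shape_trace(gs)
  expect_false(any(grepl("hourglass", tr$stage)))
  expect_equal(trace_shape(tr, "head", "output"), c(256, 256, 1))
  # encoder/decoder tables identical to LPNet's (bar the raw input channels)
  lt <- shape_trace(lpnet_spec())
  keep <- function(x) {
    x <- x[grepl("encoder|decoder", x$stage), ]
    x[!(x$stage == "encoder_block_1" & x$layer == "input"), ]
  }
  expect_equal(keep(tr), keep(lt))
})

test_that("traces scale down coherently and errors name the failing layer", {
  tr <- shape_trace(lpnet_spec(c(4, 8, 16), patch_size = 64))
  expect_equal(trace_shape(tr, "encoder_block_3", "pool_output"), c(8, 8, 16))
  expect_equal(trace_shape(tr, "hourglass_2", "input"), c(16, 16, 16))
  expect_equal(trace_shape(tr, "head", "output"), c(64, 64, 1))
  expect_equal(trace_shape(tr, "encoder_block_1", "input"), c(64, 64, 3))
  expect_error(lpnet_spec(patch_size = 100), "divisible by 8")
  expect_error(shape_trace(lpnet_spec(), input_shape = c(256, 256, 4)), "enc1/conv1")
})

test_that("parameter count matches the closed form and the built model", {
  # single 3x3 conv, 3 -> 16, with bias: 3*3*3*16 + 16 = 448
  l <- spikeseg:::new_conv(3L, 16L, 3L)
  expect_equal(length(l$W$value) + length(l$b$value), 448)

  for (spec in list(gmrnet_spec(c(2, 3, 4), 16), lpnet_spec(c(4, 8, 16), 64))) {
    model <- build_network(spec, seed = 1)
    expect_equal(spikeseg:::n_model_parameters(model), count_parameters(spec))
  }
  # hourglasses add parameters
  expect_lt(count_parameters(gmrnet_spec()), count_parameters(lpnet_spec()))
  # conv parameters scale roughly quadratically with width
  p1 <- count_parameters(lpnet_spec(c(8, 16, 32), 64))
  p2 <- count_parameters(lpnet_spec(c(16, 32, 64), 64))
  expect_gt(p2 / p1, 3.4)
  expect_lt(p2 / p1, 4.1)
})

test_that("built models realise the traced shapes with outputs in [0, 1]", {
  lp <- tiny_lp_net(seed = 2)
  x <- array(0, c(64, 64, 3, 2))
  out <- predict_network(lp, x)
  expect_equal(dim(out), c(64L, 64L, 1L, 2L))
  expect_true(all(out >= 0 & out <= 1))
  # arbitrary real inputs stay in [0, 1]
  withr::with_seed(1, xr <- array(rnorm(64 * 64 * 3, sd = 40), c(64, 64, 3, 1)))
  pr <- predict_network(lp, xr)
  expect_true(all(pr >= 0 & pr <= 1))

  gm <- tiny_gmr_net(seed = 2, patch = 16)
  og <- predict_network(gm, array(0.5, c(16, 16, 1, 3)))
  expect_equal(dim(og), c(16L, 16L, 1L, 3L))
})

test_that("weight initialisation is reproducible from the seed", {
  spec <- gmrnet_spec(c(2, 3, 4), 16)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  a <- predict_network(build_network(spec, seed = 7), x)
  b <- predict_network(build_network(spec, seed = 7), x)
  c <- predict_network(build_network(spec, seed = 8), x)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("hourglass forward preserves spatial dims and channels", {
  hg <- withr::with_seed(3, spikeseg:::build_hourglass(4L))
  for (s in c(8L, 16L, 32L)) {
    x <- spikeseg:::new_tensor(array(rnorm(4 * s * s * 2), c(4, s, s, 2)))
    out <- spikeseg:::hg_forward(NULL, x, hg)
    expect_equal(dim(out$value), c(4L, s, s, 2L))
  }
})

test_that("model state save/restore reproduces predictions exactly", {
  net <- tiny_gmr_net(seed = 4, patch = 16)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  p1 <- predict_network(net, x)
  net2 <- restore_network(network_state(net))
  expect_identical(predict_network(net2, x), p1)
})
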