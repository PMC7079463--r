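test_that("the plant split follows the floor rule, by plant", {
  s <- split_dataset(paste0("p", 1:200), seed = 1)
  expect_length(s$train, 170)
  expect_length(s$validation, 30)

  s10 <- split_dataset(paste0("p", 1:10), seed = 3)
  expect_length(s10$train, 8) # floor(8.5)
  expect_length(s10$validation, 2)

  expect_identical(split_dataset(letters[1:10], seed = 5),
                   split_dataset(letters[1:10], seed = 5))
  expect_error(split_dataset("p1"), "at least 2")
})

test_that("splits are disjoint and exhaustive for all sizes and seeds", {
  for (seed in 1:20) {
    n <- 2 + seed
    ids <- paste0("plant", seq_len(n))
    s <- split_dataset(ids, seed = seed)
    expect_length(intersect(s$train, s$validation), 0)
    expect_setequal(c(s$train, s$validation), ids)
    expect_length(s$train, floor(0.85 * n))
  }
})

test_that("binary cross-entropy matches its closed forms", {
  t <- array(c(0, 1, 0, 1), c(2, 2))
  expect_equal(bce_loss(array(0.5, c(2, 2)), t), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(array(0.25, c(1, 1)), array(1, c(1, 1))), -log(0.25),
               tolerance = 1e-12)
  expect_lt(bce_loss(t, t), 1e-5) # perfect prediction, up to clipping
  # non-negative on random inputs
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- array(runif(16), c(4, 4))
      tt <- array(rbinom(16, 1, 0.5), c(4, 4))
    })
    expect_gte(bce_loss(p, tt), 0)
  }
  expect_error(bce_loss(array(0.5, c(2, 2)), array(1, c(3, 3))), "shapes")
})

test_that("zero-epoch training leaves the model untouched", {
  net <- tiny_gmr_net(seed = 1, patch = 16)
  before <- lapply(net$params, function(p) p$value)
  x <- array(runif(16 * 16 * 4), c(16, 16, 1, 4))
  y <- array(rbinom(16 * 16 * 4, 1, 0.4), c(16, 16, 1, 4))
  tr <- train_network(net, x, y, train_config(1e-3, epochs = 0, batch_size = 2))
  expect_equal(nrow(tr$history), 0)
  expect_identical(lapply(net$params, function(p) p$value), before)
})

test_that("training is reproducible and reduces the loss substantially", {
  # small learnable task: recover a blob mask from its noisy soft rendering
  make_pair <- function(seed) {
    withr::with_seed(seed, {
      m <- matrix(0L, 16, 16)
      r <- sample(3:12, 1); c <- sample(3:12, 1)
      m[r + (-2:2), c + (-2:2)] <- 1L
      x <- pmin(pmax(m * 0.8 + 0.1 + matrix(rnorm(256, 0, 0.05), 16, 16), 0), 1)
    })
    list(x = array(x, c(16, 16, 1)), y = m)
  }
  pairs <- lapply(1:20, make_pair)
  xs <- lapply(pairs, `[[`, "x")
  ys <- lapply(pairs, `[[`, "y")
  cfg <- train_config(3e-3, epochs = 30, batch_size = 8, seed = 11)

  net <- tiny_gmr_net(seed = 2, patch = 16)
  tr <- train_network(net, xs, ys, cfg)
  expect_equal(nrow(tr$history), 30)
  expect_lt(tr$history$loss[30], 0.5 * tr$history$loss[1])

  net2 <- tiny_gmr_net(seed = 2, patch = 16)
  tr2 <- train_network(net2, xs, ys, cfg)
  expect_identical(tr$history$loss, tr2$history$loss)
})

test_that("two-stage training wires stage-1 outputs into stage 2", {
  scenes <- lapply(1:2, function(i) {
    generate_scene(scene_config_cpu(n_spikes = 3), seed = 30 + i)
  })
  lp <- tiny_lp_net(seed = 1)
  gm <- build_network(gmrnet_spec(c(2, 3, 4), 64), seed = 2)
  fit <- multistage_train(
    scenes, lp, gm,
    lp_config = train_config(1e-3, epochs = 1, batch_size = 8, seed = 1),
    gmr_config = train_config(1e-3, epochs = 1, batch_size = 2, seed = 2),
    step = 32L
  )
  # 96x96 scenes with 64-px tiles every 32 px: 2x2 tiles per scene
  expect_equal(fit$n_patches, 8)
  expect_equal(fit$n_merged, 2)
  expect_equal(nrow(fit$lp_history), 1)
  expect_equal(nrow(fit$gmr_history), 1)
  expect_error(multistage_train(list(), lp, gm,
                                train_config(), train_config()), "non-empty")
})
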