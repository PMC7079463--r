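test_that("pixel confusion matches a per-pixel loop oracle", {
  expect_error(pixel_confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "identical")
  p0 <- matrix(1L, 4, 4)
  t0 <- matrix(0L, 4, 4)
  cf <- pixel_confusion(p0, t0)
  expect_equal(cf$fp, 16)
  expect_equal(cf$tp + cf$tn + cf$fn, 0)

  same <- random_mask(8, 8, 0.4, 1)
  cf2 <- pixel_confusion(same, same)
  expect_equal(cf2$fp + cf2$fn, 0)

  for (seed in 1:10) {
    pr <- random_mask(16, 16, 0.4, seed)
    tr <- random_mask(16, 16, 0.4, seed + 100)
    expect_equal(unclass(pixel_confusion(pr, tr))[c("tp", "tn", "fp", "fn")],
                 confusion_loop_oracle(pr, tr)[c("tp", "tn", "fp", "fn")])
  }
})

test_that("segmentation metrics satisfy their identities on random confusions", {
  for (seed in 1:25) {
    cf <- withr::with_seed(seed, list(
      tp = sample(0:200, 1), tn = sample(0:200, 1),
      fp = sample(0:50, 1), fn = sample(0:50, 1)
    ))
    if (sum(unlist(cf)) == 0) next
    m <- segmentation_metrics(cf)
    expect_lte(m$ji, m$precision + 1e-12)
    expect_lte(m$ji, m$recall + 1e-12)
    expect_equal(m$f1, 2 * m$ji / (1 + m$ji), tolerance = 1e-12)
    expect_equal(m$e1 * sum(unlist(cf)), cf$fp + cf$fn, tolerance = 1e-9)
  }
  perf <- segmentation_metrics(list(tp = 40, tn = 60, fp = 0, fn = 0))
  expect_equal(unlist(perf[c("precision", "recall", "accuracy", "f1", "ji")]),
               c(precision = 1, recall = 1, accuracy = 1, f1 = 1, ji = 1))
  expect_equal(perf$e1 + perf$e2, 0)
  expect_error(segmentation_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("reported precision/recall operating point implies F1 and JI", {
  expect_equal(round(f_measure(0.9993, 0.9989), 4), 0.9991)
  expect_equal(round(jaccard_from_pr(0.9993, 0.9989), 4), 0.9982)
})

test_that("implied misclassified-pixel counts match the worked examples", {
  expect_equal(implied_error_pixels(0.0016, 65536), 105)
  expect_equal(implied_error_pixels(0.005349223, 65536), 351)
  expect_equal(implied_error_pixels(0, 1e6), 0)
  expect_error(implied_error_pixels(1.2, 100), "\\[0, 1\\]")
})

test_that("counting metrics reproduce the validation-table worked rows", {
  r15 <- counting_metrics(list(tp = 13, fp = 2, fn = 1))
  expect_equal(round(r15$precision, 2), 0.87)
  expect_equal(round(r15$accuracy, 2), 0.81)
  expect_equal(round(r15$f1, 2), 0.90)

  r4 <- counting_metrics(list(tp = 10, fp = 0, fn = 1))
  expect_equal(round(r4$precision, 2), 1.00)
  expect_equal(round(r4$accuracy, 2), 0.91)
  expect_equal(round(r4$f1, 2), 0.95)

  all1 <- counting_metrics(list(tp = 7, fp = 0, fn = 0))
  expect_true(all(unlist(all1) == 1))
  expect_error(counting_metrics(list(tp = 1, fp = 0, fn = 0, tn = 3)), "TN")
  # with tn = 0, accuracy coincides with the Jaccard index
  for (seed in 1:10) {
    cf <- withr::with_seed(seed, list(tp = sample(1:20, 1),
                                      fp = sample(0:5, 1),
                                      fn = sample(0:5, 1)))
    cm <- counting_metrics(cf)
    sm <- segmentation_metrics(c(cf, list(tn = 0)))
    expect_equal(cm$accuracy, sm$ji)
  }
})

test_that("the 30-plant validation table is reproduced row by row", {
  tab <- spike_count_validation()
  expect_equal(nrow(tab), 30)
  rec <- purrr::pmap_dfr(tab[, c("tp", "fp", "fn")], function(tp, fp, fn) {
    counting_metrics(list(tp = tp, fp = fp, fn = fn))
  })
  expect_equal(round(rec$precision, 2), tab$precision)
  expect_equal(round(rec$accuracy, 2), tab$accuracy)
  expect_equal(round(rec$f1, 2), tab$f1)
  # tabulated averages at two decimals: 0.99 / 0.95 / 0.97
  expect_equal(round(mean(rec$precision), 2), 0.99)
  expect_equal(round(mean(rec$accuracy), 2), 0.95)
  expect_equal(round(mean(rec$f1), 2), 0.97)
})

test_that("error overlays paint exactly the disagreeing pixels", {
  tr <- matrix(0L, 6, 6); tr[2:3, 2:3] <- 1L
  pr <- tr
  ov <- error_overlay(pr, tr)
  pink <- ov[, , 1] == 255 & ov[, , 2] == 105
  green <- ov[, , 1] == 0 & ov[, , 2] == 200
  expect_equal(sum(pink) + sum(green), 0)

  pr2 <- tr; pr2[2, 2] <- 0L            # one miss
  pr2[5, 5] <- 1L                        # one spurious
  ov2 <- error_overlay(pr2, tr)
  pink2 <- ov2[, , 1] == 255 & ov2[, , 2] == 105
  green2 <- ov2[, , 1] == 0 & ov2[, , 2] == 200
  cf <- pixel_confusion(pr2, tr)
  expect_equal(sum(pink2), cf$fn)
  expect_equal(sum(green2), cf$fp)
  expect_equal(sum(pink2) + sum(green2), cf$fp + cf$fn)
})

test_that("dataset evaluation averages per-image metrics", {
  a <- random_mask(12, 12, 0.3, 1)
  b <- random_mask(12, 12, 0.3, 2)
  one <- evaluate_dataset(list(list(predicted = a, truth = b)))
  expect_equal(nrow(one$per_image), 1)
  expect_equal(unlist(one$average),
               unlist(one$per_image[, -1]))
  two <- evaluate_dataset(list(list(predicted = a, truth = b),
                               list(predicted = a, truth = b)))
  expect_equal(unlist(two$average), unlist(one$average))
  # tibble input with list-columns works the same
  tb <- tibble::tibble(predicted = list(a, a), truth = list(b, b))
  expect_equal(evaluate_dataset(tb)$average, two$average)
  expect_error(evaluate_dataset(list()), "at least one")
})
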