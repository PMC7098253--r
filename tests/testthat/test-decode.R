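# Bin labeling, SVM decoder bundles and classification metrics.

test_that("label_bins marks 25 bins per 2.5 s cue and shifts with lag", {
  s <- make_cue_schedule("Task1", 0, seed = 1)
  nb <- floor(s$block_duration / 0.1)
  l <- label_bins(s, nb)
  expect_equal(sum(l != "rest"), 10 * 25)
  for (i in seq_len(nrow(s$events))) {
    k0 <- round(s$events$onset_s[i] / 0.1) + 1
    expect_true(all(l[k0:(k0 + 24)] == s$events$movement[i]))
  }
  expect_true(all(label_bins(rest_schedule(10), 100) == "rest"))
  l5 <- label_bins(s, nb, lag = 0.5)
  expect_equal(which(l5 != "rest"), which(l != "rest") + 5)
  expect_error(label_bins(s, nb, lag = -1), "non-negative")
})

test_that("separable features train to perfect accuracy, deterministically", {
  s <- make_cue_schedule("Task2", 0, seed = 2)
  nb <- floor(s$block_duration / 0.1)
  l <- label_bins(s, nb)
  # one indicator feature per movement, well separated
  x <- matrix(0, nb, 4)
  for (j in 1:4) x[l == levels(l)[j], j] <- 5
  x <- x + matrix(rnorm(nb * 4, sd = 0.05), nb, 4)
  b1 <- train_decoders(x, l)
  b2 <- train_decoders(x, l)
  expect_equal(b1$models$wrist_flexion$scale, b2$models$wrist_flexion$scale)
  res <- predict(b1, x)
  expect_true(all(res$scores >= -1 & res$scores <= 1))
  m <- compute_metrics(res, l)
  expect_equal(m$overall_accuracy, 100)
  expect_true(all(m$per_movement$sensitivity == 100))
  expect_true(all(m$per_movement$specificity == 100))
})

test_that("the argmax-above-zero rule falls back to rest", {
  s <- make_cue_schedule("Task1", 0, seed = 3)
  nb <- floor(s$block_duration / 0.1)
  l <- label_bins(s, nb)
  x <- matrix(0, nb, 2)
  x[l == "hand_open", 1] <- 4
  x[l == "hand_close", 2] <- 4
  x <- x + matrix(rnorm(nb * 2, sd = 0.05), nb, 2)
  b <- train_decoders(x, l)
  # a point deep in the rest cluster scores negative everywhere -> rest
  far <- matrix(0, 3, 2)
  res <- predict(b, far)
  expect_true(all(res$predicted == "rest"))
  expect_true(all(res$scores <= 0))
  # a clear movement-1 point wins
  res2 <- predict(b, matrix(c(4, 0), 1, 2))
  expect_equal(as.character(res2$predicted), "hand_open")
  expect_error(predict(b, matrix(0, 2, 5)), "dimensionality")
  expect_error(train_decoders(x, factor(rep("rest", nb),
                                        levels = c("hand_open", "rest"))),
               "hand_open")
})

test_that("metrics match definitional arithmetic and counting oracles", {
  # constructed confusion: TP = 40, FN = 10, TN = 90, FP = 10
  truth <- factor(c(rep("m", 50), rep("rest", 100)), levels = c("m", "rest"))
  pred <- factor(c(rep("m", 40), rep("rest", 10),
                   rep("m", 10), rep("rest", 90)), levels = c("m", "rest"))
  m <- compute_metrics(pred, truth)
  expect_equal(m$per_movement$sensitivity, 80)
  expect_equal(m$per_movement$specificity, 90)
  expect_equal(m$overall_accuracy, 100 * 130 / 150)
  expect_equal(compute_metrics(pred, truth,
                               per_movement = "precision")$per_movement$accuracy,
               100 * 40 / 50)

  # always-rest predictor on a Task1 block
  s <- make_cue_schedule("Task1", 0, seed = 4)
  nb <- floor(s$block_duration / 0.1) # 965 bins
  l <- label_bins(s, nb)
  rest_only <- factor(rep("rest", nb), levels = levels(l))
  mr <- compute_metrics(rest_only, l)
  expect_equal(mr$overall_accuracy, 100 * mean(l == "rest"))
  expect_equal(mr$overall_accuracy, 100 * (965 - 250) / 965)
  expect_true(all(mr$per_movement$sensitivity == 0))
  expect_true(all(mr$per_movement$specificity == 100))

  # label renaming leaves metrics unchanged
  ren <- function(f) factor(sub("hand_open", "A", sub("hand_close", "B", f)),
                            levels = c("A", "B", "rest"))
  m1 <- compute_metrics(rest_only, l)
  m2 <- compute_metrics(ren(rest_only), ren(l))
  expect_equal(m2$overall_accuracy, m1$overall_accuracy)
  expect_equal(m2$per_movement[-1], m1$per_movement[-1])
})

test_that("overall accuracy obeys the brute-force misdetected-rest bound", {
  set.seed(31)
  for (i in 1:20) {
    n <- 200
    labs <- factor(sample(c("a", "b", "rest"), n, replace = TRUE),
                   levels = c("a", "b", "rest"))
    preds <- factor(sample(c("a", "b", "rest"), n, replace = TRUE),
                    levels = c("a", "b", "rest"))
    m <- compute_metrics(preds, labs)
    # brute-force count of rest bins predicted as movement
    miss_rest <- sum(labs == "rest" & preds != "rest") / n
    expect_lte(m$overall_accuracy / 100, 1 - miss_rest + 1e-12)
    # and the direct count oracle
    expect_equal(m$overall_accuracy,
                 100 * sum(as.character(preds) == as.character(labs)) / n)
  }
})
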