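# scalar-loop reference implementations, independent of the vectorised code
bce_loop <- function(y, p, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
  }
  -s / length(y)
}

dice_loop <- function(y, p, smooth = 1) {
  num <- 0; dy <- 0; dp <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] * p[i]
    dy <- dy + y[i]
    dp <- dp + p[i]
  }
  1 - (2 * num + smooth) / (dy + dp + smooth)
}

test_that("losses match scalar-loop oracles on random short vectors", {
  set.seed(31)
  for (rep in 1:120) {
    n <- sample(1:16, 1)
    y <- rbinom(n, 1, 0.4)
    p <- runif(n)
    sm <- runif(1, 0.1, 2)
    expect_equal(bce_loss(y, p), bce_loop(y, p), tolerance = 1e-10)
    expect_equal(dice_loss(y, p, smooth = sm), dice_loop(y, p, smooth = sm),
                 tolerance = 1e-10)
  }
})

test_that("hand-computed loss cases evaluate exactly", {
  expect_equal(bce_loss(1, 0.5), -log(0.5), tolerance = 1e-6)  # 0.693147
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.2)), -log(0.8), tolerance = 1e-6) # 0.223144
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), smooth = 1e-12),
               1 / 3, tolerance = 1e-6)
  # perfect prediction at the clamp bound
  expect_equal(bce_loss(c(1, 0), c(1, 0)), -log(1 - 1e-7), tolerance = 1e-12)
  # perfect binary overlap and the empty/empty convention
  expect_equal(dice_loss(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-12)
  expect_equal(dice_loss(rep(0, 5), rep(0, 5)), 0, tolerance = 1e-12)
})

test_that("the hybrid loss decomposes into its weighted terms", {
  set.seed(32)
  y <- rbinom(12, 1, 0.5)
  p <- runif(12)
  expect_equal(total_loss(y, p, loss_config(alpha = 0, beta = 1)),
               dice_loss(y, p), tolerance = 1e-12)
  expect_equal(total_loss(y, p, loss_config(alpha = 1, beta = 0)),
               bce_loss(y, p), tolerance = 1e-12)
  got <- total_loss(1, 0.5, loss_config(alpha = 1, beta = 1, smooth = 1e-12))
  expect_equal(got, 0.693147 + (1 - 1 / 1.5), tolerance = 1e-5) # 1.026480
})

test_that("loss and pixel-vector validation reject malformed inputs", {
  expect_error(bce_loss(c(1, 0), 0.5), class = "hemoseg_value_error")
  expect_error(dice_loss(c(1, 2), c(0.5, 0.5)), class = "hemoseg_value_error")
  expect_error(bce_loss(1, 1.5), class = "hemoseg_value_error")
  expect_error(loss_config(alpha = -1), class = "hemoseg_value_error")
  expect_error(loss_config(alpha = 0, beta = 0), class = "hemoseg_value_error")
  expect_error(loss_config(clamp_eps = 0.7), class = "hemoseg_value_error")
})

test_that("confusion counts enumerate pixels exactly", {
  pred <- matrix(c(1, 1, 0, 0), 2, 2)
  truth <- matrix(c(1, 0, 1, 0), 2, 2)
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")], list(TP = 1, FP = 1, FN = 1, TN = 1))
  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0)
  allfp <- confusion(matrix(1, 3, 4), matrix(0, 3, 4))
  expect_equal(allfp$FP, 12)
  expect_equal(allfp$TP + allfp$TN + allfp$FN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 2, 3)), class = "hemoseg_dim_error")
})

test_that("metrics from the 2x2 enumerated case are exact", {
  m <- metrics_from_counts(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(m$dice, 0.5)
  expect_equal(m$jaccard, 1 / 3, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.5)
})

test_that("metric identities hold over random confusion counts", {
  set.seed(33)
  for (rep in 1:1000) {
    cnt <- as.list(setNames(rpois(4, lambda = sample(c(2, 50, 2000), 1)),
                            c("TP", "FP", "TN", "FN")))
    m <- metrics_from_counts(cnt)
    vals <- unlist(m[hemoseg:::metric_names])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(m$jaccard, m$dice / (2 - m$dice), tolerance = 1e-12)
    expect_lte(m$jaccard, m$dice)
  }
  perfect <- metrics_from_counts(list(TP = 7, FP = 0, TN = 93, FN = 0))
  expect_true(all(unlist(perfect[hemoseg:::metric_names]) == 1))
})

test_that("degenerate confusion counts follow the stated conventions", {
  # empty truth, empty prediction: all metrics perfect
  e <- metrics_from_counts(list(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_equal(e$dice, 1)
  expect_equal(e$sensitivity, 1)
  # empty truth but false positives: sensitivity 0
  f <- metrics_from_counts(list(TP = 0, FP = 3, TN = 7, FN = 0))
  expect_equal(f$sensitivity, 0)
  expect_equal(f$dice, 0)
  # all-lesion truth, all-lesion prediction: specificity 1 by convention
  g <- metrics_from_counts(list(TP = 10, FP = 0, TN = 0, FN = 0))
  expect_equal(g$specificity, 1)
})

test_that("binary predictions tie the Dice loss to the Dice coefficient", {
  set.seed(34)
  for (rep in 1:25) {
    y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    p <- matrix(rbinom(64, 1, 0.3), 8, 8)
    d_loss <- dice_loss(as.numeric(y), as.numeric(p), smooth = 1e-12)
    d_coef <- metrics_from_counts(confusion(p, y))$dice
    if (sum(y) + sum(p) > 0) expect_equal(1 - d_loss, d_coef, tolerance = 1e-9)
  }
})

test_that("better overlap never raises the hybrid loss", {
  # move probability mass from a background pixel to a lesion pixel,
  # keeping sum(p) fixed: the loss must not increase
  set.seed(35)
  y <- c(1, 1, 0, 0, 0, 0)
  p <- c(0.3, 0.4, 0.5, 0.2, 0.1, 0.3)
  cfg <- loss_config()
  l0 <- total_loss(y, p, cfg)
  p2 <- p + c(0.2, 0, -0.2, 0, 0, 0)
  expect_lte(total_loss(y, p2, cfg), l0)
})

test_that("aggregation reports means and population standard deviations", {
  one <- metrics_from_counts(list(TP = 3, FP = 1, TN = 90, FN = 2), slice_id = "a")
  agg1 <- aggregate_metrics(one)
  expect_equal(agg1$summary$mean[agg1$summary$metric == "dice"], one$dice)
  expect_true(all(agg1$summary$sd == 0))

  two <- dplyr::bind_rows(
    metrics_from_counts(list(TP = 1, FP = 2, TN = 90, FN = 1), slice_id = "a"), # dice 0.4
    metrics_from_counts(list(TP = 2, FP = 1, TN = 90, FN = 0), slice_id = "b")  # dice 0.8
  )
  agg2 <- aggregate_metrics(two)
  expect_equal(agg2$summary$mean[agg2$summary$metric == "dice"], 0.6, tolerance = 1e-12)
  expect_equal(agg2$summary$sd[agg2$summary$metric == "dice"], 0.2, tolerance = 1e-12)
  # permutation invariance
  agg2r <- aggregate_metrics(two[2:1, ])
  expect_equal(agg2$summary, agg2r$summary)
  expect_error(aggregate_metrics(two[0, ]), class = "hemoseg_value_error")
})

test_that("metrics CSV round-trips rows plus mean/sd footer", {
  per <- dplyr::bind_rows(
    metrics_from_counts(list(TP = 1, FP = 2, TN = 90, FN = 1), slice_id = "a"),
    metrics_from_counts(list(TP = 2, FP = 1, TN = 90, FN = 0), slice_id = "b")
  )
  rep <- aggregate_metrics(per)
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(rep, f)
  got <- read.csv(f)
  expect_equal(nrow(got), 4L)
  expect_equal(got$slice_id, c("a", "b", "mean", "sd"))
  expect_equal(got$dice[3], 0.6, tolerance = 1e-12)
})
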