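test_that("a minimal config applies the documented defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("data_dir: /tmp/data", "output_dir: /tmp/out"), f)
  cfg <- load_config(f)
  expect_equal(cfg$train$learning_rate, 1e-4)
  expect_equal(cfg$train$batch_size, 4L)
  expect_equal(cfg$train$max_epochs, 150L)
  expect_equal(cfg$loss$alpha, 1)
  expect_equal(cfg$loss$beta, 1)
  expect_equal(cfg$model$encoder_depth, 34L)
  expect_equal(cfg$model$output_threshold, 0.5)
})

test_that("configs reject unknown keys and invalid values by name", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("data_dir: x", "frobnicate: 1"), f)
  expect_error(load_config(f), regexp = "frobnicate", class = "hemoseg_value_error")
  writeLines(c("loss:", "  alpha: -1"), f)
  expect_error(load_config(f), regexp = "alpha", class = "hemoseg_value_error")
  writeLines(c("model:", "  warp_factor: 2"), f)
  expect_error(load_config(f), regexp = "warp_factor", class = "hemoseg_value_error")
  expect_error(load_config(tempfile()), class = "hemoseg_value_error")
})

test_that("configuration round-trips through YAML unchanged", {
  cfg <- run_config(data_dir = "d", output_dir = "o",
                    train = list(max_epochs = 7L, seed = 3L),
                    loss = list(alpha = 0.4, beta = 0.6),
                    phantom = list(size = 96L))
  f <- tempfile(fileext = ".yaml")
  save_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$train$max_epochs, 7L)
  expect_equal(cfg2$loss$alpha, 0.4)
  expect_equal(cfg2$phantom$size, 96L)
  f2 <- tempfile(fileext = ".yaml")
  save_config(cfg2, f2)
  expect_equal(load_config(f2), cfg2)
})

test_that("slice pairs survive the PNG round trip", {
  p <- generate_slice(phantom_config(seed = 61L))
  dir <- tempfile("pngs")
  write_slice_pair(p, dir)
  q <- read_slice_pair(file.path(dir, paste0(p$slice_id, ".png")),
                       file.path(dir, paste0(p$slice_id, "_mask.png")),
                       slice_id = p$slice_id)
  expect_identical(q$mask, p$mask) # masks are bit-exact through 0/255 PNG
  expect_lt(max(abs(q$image - p$image)), 1 / 255) # 8-bit quantisation only
  # a second round trip is lossless: quantisation happened once
  dir2 <- tempfile("pngs2")
  write_slice_pair(q, dir2)
  q2 <- read_slice_pair(file.path(dir2, paste0(p$slice_id, ".png")),
                        file.path(dir2, paste0(p$slice_id, "_mask.png")))
  expect_lt(max(abs(q2$image - q$image)), 1e-6)
  expect_identical(q2$mask, q$mask)
})

test_that("mask binarisation uses the >127 rule", {
  f_img <- tempfile(fileext = ".png")
  f_msk <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f_img)
  png::writePNG(matrix(c(127, 128, 0, 255) / 255, 2, 2)[rep(1:2, 2), rep(1:2, 2)], f_msk)
  pair <- read_slice_pair(f_img, f_msk)
  m <- matrix(c(127, 128, 0, 255), 2, 2)[rep(1:2, 2), rep(1:2, 2)]
  expect_identical(pair$mask, matrix(as.integer(m > 127), 4, 4))
})

test_that("mismatched or non-grayscale inputs are rejected with named errors", {
  f_img <- tempfile(fileext = ".png")
  f_msk <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f_img)
  png::writePNG(matrix(0, 6, 6), f_msk)
  expect_error(read_slice_pair(f_img, f_msk), class = "hemoseg_dim_error")
  rgb <- array(runif(48), c(4, 4, 3))
  f_rgb <- tempfile(fileext = ".png")
  png::writePNG(rgb, f_rgb)
  expect_error(read_slice_pair(f_rgb, f_img), regexp = "grayscale",
               class = "hemoseg_value_error")
  expect_error(read_slice_pair(tempfile(fileext = ".png"), f_msk),
               class = "hemoseg_value_error")
})

test_that("NIfTI slices are accepted with min-max scaling", {
  skip_if_not_installed("RNifti")
  f_img <- tempfile(fileext = ".nii.gz")
  f_msk <- tempfile(fileext = ".png")
  v <- matrix(seq(-100, 155, length.out = 64), 8, 8)
  RNifti::writeNifti(RNifti::asNifti(v), f_img)
  png::writePNG(matrix(rep(c(0, 1), each = 32), 8, 8), f_msk)
  pair <- read_slice_pair(f_img, f_msk)
  expect_equal(range(pair$image), c(0, 1))
  expect_equal(dim(pair$image), c(8L, 8L))
})

test_that("NIfTI export round-trips a slice pair", {
  skip_if_not_installed("RNifti")
  p <- generate_slice(phantom_config(seed = 65L))
  prefix <- file.path(tempfile("nii"), "slice")
  files <- write_slice_nifti(p, prefix)
  q <- read_slice_pair(files[["image"]], files[["mask"]], slice_id = p$slice_id)
  expect_identical(q$mask, p$mask)
  # reading applies min-max intensity scaling to NIfTI voxels
  rng <- range(p$image)
  expect_lt(max(abs(q$image - (p$image - rng[1]) / diff(rng))), 1e-6)
})

test_that("datasets round-trip with their manifest", {
  pairs <- generate_dataset(phantom_config(seed = 62L), 3)
  dir <- tempfile("ds")
  manifest <- write_dataset(pairs, dir)
  expect_equal(manifest$lesion_area_px, vapply(pairs, function(p) sum(p$mask), 0))
  back <- read_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) expect_identical(back[[i]]$mask, pairs[[i]]$mask)
})

test_that("predictions write a re-thresholdable probability map and mask", {
  set.seed(63)
  prob <- matrix(runif(64 * 64), 64, 64)
  prefix <- file.path(tempfile("pred"), "slice")
  files <- write_prediction(prob, prefix, threshold = 0.5)
  expect_true(all(file.exists(files)))
  mask_back <- png::readPNG(files[["mask"]])
  expect_identical(matrix(as.integer(mask_back > 0.5), 64, 64),
                   unname(binarize(prob, 0.5)))
  if (requireNamespace("tiff", quietly = TRUE) && grepl("tif$", files[["prob"]])) {
    prob_back <- tiff::readTIFF(files[["prob"]])
    expect_lt(max(abs(prob_back - prob)), 1 / 65535 + 1e-9) # 16-bit precision
  }
})

test_that("the CLI runs generate/split/summarize end-to-end and propagates contracts", {
  dir <- tempfile("cliwork")
  dir.create(dir)
  cfgf <- file.path(dir, "cfg.yaml")
  save_config(run_config(
    data_dir = file.path(dir, "data"), output_dir = file.path(dir, "out"),
    model = list(stage_channels = c(8L, 8L, 16L, 32L, 64L),
                 decoder_channels = c(32L, 16L, 16L, 8L, 8L),
                 channel_reduction = 4L),
    phantom = list(size = 32L)
  ), cfgf)

  expect_equal(cli(c("generate", "--config", cfgf, "--n", "6", "--seed", "7")), 0L)
  expect_true(file.exists(file.path(dir, "data", "manifest.csv")))
  dir.create(file.path(dir, "out"), showWarnings = FALSE)
  expect_equal(cli(c("split", "--config", cfgf, "--seed", "7",
                     "--out", file.path(dir, "out", "folds.json"))), 0L)
  expect_true(file.exists(file.path(dir, "out", "folds.json")))
  expect_output(code <- cli(c("summarize", "--config", cfgf)), "total")
  expect_equal(code, 0L)
  # training two epochs on the tiny phantom set completes
  expect_equal(cli(c("train", "--config", cfgf, "--epochs", "2", "--seed", "7")), 0L)
  expect_true(file.exists(file.path(dir, "out", "train_log.csv")))
  ckpt <- file.path(dir, "out", "best_checkpoint.rds")
  expect_true(file.exists(ckpt))
  # prediction on a non-multiple-of-32 image fails with the divisibility rule
  bad <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 50, 50), bad)
  expect_equal(cli(c("predict", "--image", bad, "--checkpoint", ckpt,
                     "--out", file.path(dir, "out", "p"))), 1L)
  good <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 32, 32), good)
  expect_equal(cli(c("predict", "--image", good, "--checkpoint", ckpt,
                     "--out", file.path(dir, "out", "p"))), 0L)
  # unknown commands and malformed flags exit 2
  expect_equal(suppressMessages(cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli(c("generate", "--n"))), 2L)
})

test_that("tidy, glance and autoplot cover the result types", {
  pairs <- generate_dataset(phantom_config(size = 32L, seed = 64L), 4)
  res <- train_fold(pairs[1:2], pairs[3:4],
                    model_cfg = slim_model_config(),
                    train_cfg = train_config(max_epochs = 2L, batch_size = 2L, seed = 8L))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$epochs, 2L)
  expect_equal(g$parameters, count_parameters(res$model))
  rep <- evaluate(res$model, pairs[3:4])
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_slices, 2L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_slice_pair(pairs[[1]]), "ggplot")
})
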