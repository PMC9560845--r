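# Padding, loss, the training loop, evaluation pipeline and checkpoints.

test_that("padding reaches the next multiple of 32 and inverts exactly", {
  x <- matrix(runif(584 * 565), 584, 565)      # retina-image size
  p <- pad_to_stride(x)
  expect_identical(dim(p$image), c(608L, 576L))
  expect_identical(crop_to_original(p$image, p$crop), x)
  # already divisible: unchanged
  y <- array(runif(64 * 96 * 3), c(64, 96, 3))
  q <- pad_to_stride(y)
  expect_identical(q$image, y)
  # random image round trip at another stride
  z <- matrix(runif(41 * 53), 41, 53)
  r <- pad_to_stride(z, stride = 16)
  expect_identical(dim(r$image), c(48L, 64L))
  expect_identical(crop_to_original(r$image, r$crop), z)
})

test_that("logit-space BCE equals probability-space BCE", {
  set.seed(4)
  z <- rnorm(500, sd = 3)
  y <- rbinom(500, 1, 0.4)
  p <- 1 / (1 + exp(-z))
  expect_equal(bce_with_logits(z, y),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-6)
})

test_that("training presets follow the per-dataset protocol", {
  expect_identical(train_presets("drive")[c("batch_size", "epochs")],
                   list(batch_size = 4L, epochs = 300L))
  expect_identical(train_presets("frsa")[c("batch_size", "epochs")],
                   list(batch_size = 4L, epochs = 150L))
  expect_identical(train_presets("polyp")[c("batch_size", "epochs")],
                   list(batch_size = 8L, epochs = 150L))
  expect_equal(train_config()$learning_rate, 1e-4)
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("a short run reduces the loss and is seed-reproducible", {
  ds <- tiny_blobs(8, seed = 301)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4L, epochs = 4L,
                      seed = 21)
  f1 <- train(tiny_model(seed = 21, size = c(64, 64)), ds, NULL, cfg)
  expect_lt(tail(f1$log$loss, 1), f1$log$loss[1])
  f2 <- train(tiny_model(seed = 21, size = c(64, 64)), ds, NULL, cfg)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(nn_parameters(f1$model), nn_parameters(f2$model))
  expect_identical(attr(f1$log, "config_hash"), attr(f2$log, "config_hash"))
})

test_that("checkpoints embed the config and reload to identical predictions", {
  ds <- tiny_blobs(4, seed = 55)
  fit <- train(tiny_model(seed = 3, size = c(64, 64)), ds, ds[1:2],
               train_config(learning_rate = 1e-3, batch_size = 2L,
                            epochs = 2L, seed = 3))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  expect_identical(back$config$width_mult, 0.25)
  x <- ds[[3]]$image
  expect_identical(predict(back, x), predict(fit$model, x))
  expect_true(all(c("epoch", "loss", "val_dice", "seconds") %in%
                    names(fit$log)))
  expect_true(all(is.finite(fit$log$loss)))
})

test_that("the evaluation pipeline matches direct per-image computation", {
  m <- tiny_model(seed = 17, size = c(64, 64))
  # non-divisible images exercise the pad -> predict -> crop path
  set.seed(8)
  recs <- lapply(1:2, function(i) {
    mask <- matrix(0L, 50, 70)
    mask[10:30, 20:45] <- 1L
    structure(list(image = array(runif(50 * 70 * 3), c(50, 70, 3)),
                   mask = mask, seed = i, spec = NULL),
              class = "sample_record")
  })
  ev <- evaluate(m, recs, threshold = 0.5)
  # oracle: run the same model manually per image
  want <- lapply(recs, function(r) {
    p <- pad_to_stride(r$image)
    prob <- crop_to_original(predict(m, p$image)[, , 1, 1], p$crop)
    suppressWarnings(metric_report(prob, r$mask))
  })
  for (i in 1:2)
    expect_equal(as.numeric(ev$per_image[i, -1]),
                 as.numeric(unlist(want[[i]])), tolerance = 1e-12)
  # macro aggregate is the unweighted mean of per-image metrics
  expect_equal(unlist(ev$aggregate),
               colMeans(ev$per_image[, -1]), tolerance = 1e-12)
  # micro aggregate equals metrics of the pooled counts
  evm <- evaluate(m, recs, threshold = 0.5, average = "micro")
  probs <- lapply(recs, function(r) {
    p <- pad_to_stride(r$image)
    crop_to_original(predict(m, p$image)[, , 1, 1], p$crop)
  })
  cc <- confusion_counts(unlist(lapply(probs, function(p) p > 0.5)),
                         unlist(lapply(recs, function(r) r$mask)))
  expect_equal(evm$aggregate$dc, suppressWarnings(dice(cc)),
               tolerance = 1e-12)
})

test_that("padding is neutral for an already-divisible image", {
  m <- tiny_model(seed = 23, size = c(64, 64))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- pad_to_stride(img)
  direct <- predict(m, img)
  padded <- crop_to_original(predict(m, p$image), p$crop)
  expect_identical(direct, padded)
})

test_that("predict_mask writes consistent probability and mask files", {
  m <- tiny_model(seed = 29, size = c(64, 64))
  img <- array(runif(50 * 70 * 3), c(50, 70, 3))
  prefix <- tempfile()
  out <- predict_mask(m, img, prefix, threshold = 0.5)
  expect_true(file.exists(out$prob_path))
  expect_true(file.exists(out$mask_path))
  mask <- png::readPNG(out$mask_path)
  expect_identical(dim(mask), c(50L, 70L))        # crop-back contract
  expect_true(all(mask %in% c(0, 1)))             # {0, 255} on disk
  prob <- tiff::readTIFF(out$prob_path)
  expect_identical(dim(prob), c(50L, 70L))
  # re-thresholding the written probability map reproduces the mask
  expect_identical(unname(prob > 0.5), unname(mask == 1))
})

test_that("an empty training set is rejected", {
  expect_error(train(tiny_model(), list(), NULL, train_config()), "empty")
})

test_that("sample pairing by file name reports missing partners", {
  d <- tempfile(); dir.create(file.path(d, "images"), recursive = TRUE)
  dir.create(file.path(d, "masks"))
  r <- generate_sample(synthetic_spec(c(64, 64), "polyp"), 5)
  png::writePNG(r$image, file.path(d, "images", "a.png"))
  png::writePNG(r$image, file.path(d, "images", "b.png"))
  png::writePNG(r$mask + 0, file.path(d, "masks", "a.png"))
  expect_error(dataset_from_dirs(file.path(d, "images"),
                                 file.path(d, "masks")),
               "has 0 mask partners")
  png::writePNG(r$mask + 0, file.path(d, "masks", "b.png"))
  recs <- dataset_from_dirs(file.path(d, "images"), file.path(d, "masks"))
  expect_length(recs, 2)
  expect_identical(recs[[1]]$mask, r$mask)
})

test_that("dataset splits cover all records with the requested fractions", {
  recs <- as.list(1:10)
  sp <- split_dataset(recs, c(train = 0.8, val = 0.1, test = 0.1), seed = 2)
  expect_identical(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(sp), 1:10)
  expect_error(split_dataset(recs, c(train = 0.5, val = 0.1)), "sum to 1")
})
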