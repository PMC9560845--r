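# Encoder: seeded determinism, the stride/width shape contract of the five
# taps, batch independence, and the analytic parameter budget.

test_that("same seed gives bitwise-identical encoders, different seeds differ", {
  e1 <- build_encoder(seed = 7, width_mult = 0.25)
  e2 <- build_encoder(seed = 7, width_mult = 0.25)
  e3 <- build_encoder(seed = 8, width_mult = 0.25)
  expect_identical(nn_parameters(e1), nn_parameters(e2))
  expect_false(identical(nn_parameters(e1), nn_parameters(e3)))
})

test_that("encoder parameter count equals the layer-by-layer formula", {
  expect_identical(count_parameters(build_encoder(seed = 1)),
                   resnet34_expected_params(64))
  # the standard backbone is ~21.3 M
  expect_equal(resnet34_expected_params(64) / 1e6, 21.3, tolerance = 0.01)
  expect_identical(count_parameters(build_encoder(seed = 1,
                                                  width_mult = 0.25)),
                   resnet34_expected_params(16))
})

test_that("tap shapes follow the closed-form stride arithmetic", {
  enc <- build_encoder(seed = 3, width_mult = 0.25)
  w <- 16L
  for (size in list(c(32L, 32L), c(64L, 96L), c(160L, 64L),
                    c(352L, 352L))) {
    pyr <- encode(enc, array(runif(prod(size) * 3), c(size, 3L)))
    widths <- c(w, w, 2L * w, 4L * w, 8L * w)
    strides <- c(2L, 4L, 8L, 16L, 32L)
    for (i in seq_along(pyr)) {
      d <- dim(pyr[[i]]$data)
      expect_identical(d[1:2], size %/% strides[i])
      expect_identical(d[3], widths[i])
      expect_identical(pyr[[i]]$stride, strides[i])
    }
  }
})

test_that("full-width taps carry the declared 64/64/128/256/512 channels", {
  enc <- build_encoder(seed = 3)
  pyr <- encode(enc, array(0.5, c(64, 64, 3)))
  expect_identical(vapply(pyr, function(f) dim(f$data)[3], 0L),
                   c(tap_s2 = 64L, tap_s4 = 64L, tap_s8 = 128L,
                     tap_s16 = 256L, bottleneck = 512L))
  expect_identical(dim(pyr$bottleneck$data)[1:2], c(2L, 2L))
  # minimal divisible input collapses to a 1x1x512 bottleneck
  tiny <- encode(enc, array(0.5, c(32, 32, 3)))
  expect_identical(dim(tiny$bottleneck$data), c(1L, 1L, 512L, 1L))
})

test_that("encoding a batch equals encoding each image separately", {
  enc <- build_encoder(seed = 11, width_mult = 0.25)
  set.seed(2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  both <- encode(enc, x)
  one <- encode(enc, x[, , , 1, drop = FALSE])
  two <- encode(enc, x[, , , 2, drop = FALSE])
  for (nm in names(both)) {
    expect_equal(both[[nm]]$data[, , , 1, drop = FALSE], one[[nm]]$data,
                 tolerance = 1e-5)
    expect_equal(both[[nm]]$data[, , , 2, drop = FALSE], two[[nm]]$data,
                 tolerance = 1e-5)
  }
})

test_that("repeated evaluation-mode encodes are identical", {
  enc <- build_encoder(seed = 11, width_mult = 0.25)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(encode(enc, x)$bottleneck$data,
                   encode(enc, x)$bottleneck$data)
})

test_that("non-divisible input sizes are rejected with padding advice", {
  enc <- build_encoder(seed = 1, width_mult = 0.25)
  expect_error(encode(enc, array(0, c(50, 64, 3))), "pad_to_stride")
  expect_error(encode(enc, array(0, c(64, 65, 3))), "divisible by 32")
})

test_that("pretrained weights require an explicit checkpoint source", {
  expect_error(build_encoder(pretrained = TRUE, seed = 1),
               "no weight source|checkpoint")
})

test_that("encoder weights round-trip through the checkpoint format", {
  enc <- build_encoder(seed = 77, width_mult = 0.25)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(enc, path)
  back <- build_encoder(pretrained = TRUE, seed = 1, width_mult = 0.25,
                        weights = path)
  expect_identical(nn_parameters(back), nn_parameters(enc))
  # an encoder-only checkpoint is not a loadable full model
  expect_error(load_checkpoint(path), "build_encoder")
})
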