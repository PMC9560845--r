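# Decoder stages and full-model assembly: stage wiring, ablation switches,
# output contracts, determinism and gradient flow.

test_that("stage config enforces the summation channel match", {
  expect_error(decoder_stage_config(64, 32, out_channels = 16,
                                    use_sum = TRUE),
               "out_channels.*skip_channels")
  expect_silent(decoder_stage_config(64, 32, out_channels = 16,
                                     use_sum = FALSE))
})

test_that("an inconsistent stage chain is rejected naming the stage", {
  stages <- lapply(1:4, function(i)
    decoder_stage_config(c(128, 64, 32, 16)[i], c(64, 32, 16, 16)[i]))
  stages[[2]]$in_channels <- 99L
  expect_error(model_config(width_mult = 0.25, input_size = c(32, 32),
                            stages = stages),
               "stage 2 is inconsistent")
})

test_that("a decoder stage halves channels and doubles resolution", {
  set.seed(1)
  st <- mhanet:::nn_mha_stage(decoder_stage_config(32, 16))
  deep <- array(rnorm(4 * 4 * 32 * 2), c(4, 4, 32, 2))
  skip <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  out <- st$forward(deep, skip)
  expect_identical(dim(out), c(8L, 8L, 16L, 2L))
  expect_identical(st$last_shapes$upsampled, c(8L, 8L, 32L, 2L))
  expect_identical(st$last_shapes$concat, c(8L, 8L, 48L, 2L))
})

test_that("summation with an all-zero skip equals the sum-free stage", {
  set.seed(2)
  st <- mhanet:::nn_mha_stage(decoder_stage_config(16, 8, se_reduction = 2))
  deep <- array(rnorm(4 * 4 * 16), c(4, 4, 16, 1))
  zskip <- array(0, c(8, 8, 8, 1))
  with_sum <- st$forward(deep, zskip)
  st$cfg$use_sum <- FALSE
  without_sum <- st$forward(deep, zskip)
  expect_identical(with_sum, without_sum)
})

test_that("the ablation triples order the parameter counts", {
  counts <- vapply(c("baseline", "psa", "se", "full"), function(v)
    count_parameters(assemble_mhanet(ablation_config(v))), 0)
  expect_lt(counts["baseline"], counts["psa"])
  expect_lt(counts["baseline"], counts["se"])
  expect_lt(counts["psa"], counts["full"])
  expect_lt(counts["se"], counts["full"])
})

test_that("model output is a (H, W, 1, N) probability map in (0, 1)", {
  m <- tiny_model(seed = 5)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p <- predict(m, x)
  expect_identical(dim(p), c(32L, 32L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))
  z <- predict(m, x, type = "logits")
  expect_equal(p, 1 / (1 + exp(-z)), tolerance = 1e-12)
})

test_that("evaluation-mode forward passes are identical", {
  m <- tiny_model(seed = 6)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("one config runs at several divisible resolutions", {
  m <- tiny_model(seed = 8, size = c(64, 64))
  for (s in c(32L, 96L)) {
    p <- predict(m, array(0.5, c(s, s, 3)))
    expect_identical(dim(p), c(s, s, 1L, 1L))
  }
  expect_error(predict(m, array(0.5, c(33, 32, 3))), "pad_to_stride")
})

test_that("the shape trace at reduced scale follows the stride arithmetic", {
  m <- tiny_model(seed = 9, size = c(96, 96))
  tr <- trace_shapes(m)
  expect_identical(tr$bottleneck, c(3L, 3L, 128L, 1L))
  expect_identical(tr$stage1_upsampled, c(6L, 6L, 128L, 1L))
  expect_identical(tr$stage1_concat, c(6L, 6L, 192L, 1L))
  expect_identical(tr$stage1_out, c(6L, 6L, 64L, 1L))
  expect_identical(tr$stage2_concat, c(12L, 12L, 96L, 1L))
  expect_identical(tr$prehead, c(96L, 96L, 8L, 1L))
  expect_identical(tr$output, c(96L, 96L, 1L, 1L))
})

test_that("one optimization step leaves no dead parameter group", {
  m <- tiny_model(seed = 5)
  nn_set_training(m, TRUE)
  set.seed(31)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  z <- m$forward_logits(x)
  m$backward(mhanet:::bce_grad(z, y))
  g <- nn_gradients(m)
  dead <- names(g)[vapply(g, function(a) is.null(a) || all(a == 0), TRUE)]
  expect_identical(dead, character(0))
})

test_that("assembly is reproducible from the config seed", {
  m1 <- tiny_model(seed = 13)
  m2 <- tiny_model(seed = 13)
  expect_identical(nn_parameters(m1), nn_parameters(m2))
})
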