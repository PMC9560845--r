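# The compiled convolution kernels and every layer's backward pass are
# checked against independent oracles: a direct nested-loop convolution and
# central finite differences.

test_that("conv2d forward matches the direct-convolution oracle", {
  set.seed(1)
  cases <- list(c(k = 3, s = 1, p = 1, g = 1), c(k = 3, s = 2, p = 1, g = 1),
                c(k = 5, s = 1, p = 2, g = 2), c(k = 1, s = 2, p = 0, g = 1),
                c(k = 7, s = 2, p = 3, g = 1), c(k = 9, s = 1, p = 4, g = 4))
  for (cs in cases) {
    cin <- 4L; cout <- 8L; H <- 9L; W <- 8L; N <- 2L
    x <- array(rnorm(H * W * cin * N), c(H, W, cin, N))
    layer <- mhanet:::nn_conv2d(cin, cout, cs[["k"]],
                                stride = cs[["s"]], pad = cs[["p"]],
                                groups = cs[["g"]], bias = TRUE)
    got <- layer$forward(x)
    want <- naive_conv(x, layer$params$W, layer$params$b,
                       cs[["s"]], cs[["p"]], cs[["g"]])
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste("conv", paste(cs, collapse = "/")))
  }
})

test_that("transposed convolution doubles the spatial size exactly", {
  ct <- mhanet:::nn_conv_transpose2d(2, 3, k = 4, stride = 2, pad = 1)
  x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  expect_identical(dim(ct$forward(x)), c(10L, 12L, 3L, 2L))
})

test_that("every layer's backward pass matches finite differences", {
  layers <- list(
    conv = list(mhanet:::nn_conv2d(3, 4, 3, stride = 2, pad = 1),
                c(7, 8, 3, 2)),
    gconv = list(mhanet:::nn_conv2d(4, 4, 3, pad = 1, groups = 2),
                 c(6, 6, 4, 2)),
    convT = list(mhanet:::nn_conv_transpose2d(3, 5, 4, 2, 1), c(5, 6, 3, 2)),
    bn = list(mhanet:::nn_batchnorm2d(3), c(5, 5, 3, 2)),
    se = list(mhanet:::nn_se_block(8, 4), c(5, 5, 8, 2)),
    pool = list(mhanet:::nn_maxpool2d(3, 2, 1), c(7, 7, 2, 2)),
    resblock = list(mhanet:::nn_basic_block(4, 8, 2), c(8, 8, 4, 2)))
  set.seed(42)
  for (nm in names(layers)) {
    layer <- layers[[nm]][[1]]
    xdim <- layers[[nm]][[2]]
    nn_set_training(layer, TRUE)
    x <- array(rnorm(prod(xdim)), xdim)
    out <- layer$forward(x)
    R <- array(rnorm(length(out)), dim(out))     # random projection loss
    layer$forward(x)
    dx <- layer$backward(R)
    f <- function(xx) sum(layer$forward(xx) * R)
    idx <- sample(length(x), 12)
    expect_equal(as.vector(dx)[idx], fd_grad(f, x, idx), tolerance = 1e-5,
                 label = paste(nm, "input gradient"))
    ps <- nn_parameters(layer)
    gs <- nn_gradients(layer)
    for (pn in names(ps)) {
      i <- sample(length(ps[[pn]]), 1)
      fp <- function(v) {
        q <- ps; q[[pn]][i] <- v
        nn_set_parameters(layer, q)
        sum(layer$forward(x) * R)
      }
      num <- (fp(ps[[pn]][i] + 1e-5) - fp(ps[[pn]][i] - 1e-5)) / 2e-5
      nn_set_parameters(layer, ps)
      expect_equal(gs[[pn]][i], num, tolerance = 1e-4,
                   label = paste(nm, pn, "parameter gradient"))
    }
  }
})

test_that("batchnorm evaluation mode uses frozen statistics", {
  bn <- mhanet:::nn_batchnorm2d(2)
  x <- array(rnorm(4 * 4 * 2 * 3, mean = 5, sd = 2), c(4, 4, 2, 3))
  nn_set_training(bn, TRUE)
  y_train <- bn$forward(x)
  # training mode standardizes per channel
  expect_equal(mean(y_train[, , 1, ]), 0, tolerance = 1e-10)
  expect_equal(mean(y_train[, , 1, ]^2), 1, tolerance = 1e-4)
  nn_set_training(bn, FALSE)
  y1 <- bn$forward(x)
  y2 <- bn$forward(x)
  expect_identical(y1, y2)  # no state drift in evaluation mode
})
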