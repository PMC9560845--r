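# ResNet-34 feature encoder with five skip taps for the decoder.
#
# Stage layout: 7x7/stride-2 stem conv + BN + ReLU, 3x3/stride-2 max pool,
# then residual stages of [3, 4, 6, 3] basic blocks at widths 64/128/256/512
# (scaled by `width_mult`).  Skip taps: stem output (stride 2), stage-1
# output (stride 4), stage-2 (stride 8), stage-3 (stride 16) and the stage-4
# bottleneck (stride 32).  The stem tap is taken after the stem conv but
# before max pooling so that the stride-2 tap keeps half resolution.

# residual basic block: two 3x3 convs + BN, identity (or 1x1 projection) add
nn_basic_block <- function(in_ch, out_ch, stride = 1L) {
  self <- new_module("nn_basic_block")
  self$children$conv1 <- nn_conv2d(in_ch, out_ch, 3L, stride = stride,
                                   pad = 1L, bias = FALSE)
  self$children$bn1 <- nn_batchnorm2d(out_ch)
  self$children$conv2 <- nn_conv2d(out_ch, out_ch, 3L, pad = 1L, bias = FALSE)
  self$children$bn2 <- nn_batchnorm2d(out_ch)
  self$proj <- (stride != 1L || in_ch != out_ch)
  if (self$proj) {
    self$children$down_conv <- nn_conv2d(in_ch, out_ch, 1L, stride = stride,
                                         pad = 0L, bias = FALSE)
    self$children$down_bn <- nn_batchnorm2d(out_ch)
  }
  self$forward <- function(x) {
    ch <- self$children
    y <- ch$bn1$forward(ch$conv1$forward(x))
    m1 <- y > 0
    y <- ch$bn2$forward(ch$conv2$forward(y * m1))
    id <- if (self$proj) ch$down_bn$forward(ch$down_conv$forward(x)) else x
    out <- y + id
    m2 <- out > 0
    if (self$training) { self$m1 <- m1; self$m2 <- m2 }
    out * m2
  }
  self$backward <- function(dy) {
    ch <- self$children
    dy <- dy * self$m2
    dmain <- ch$conv1$backward(ch$bn1$backward(
      ch$conv2$backward(ch$bn2$backward(dy)) * self$m1))
    did <- if (self$proj) {
      ch$down_conv$backward(ch$down_bn$backward(dy))
    } else dy
    dmain + did
  }
  self
}

res_stage <- function(n_blocks, in_ch, out_ch, stride) {
  blocks <- list(nn_basic_block(in_ch, out_ch, stride))
  for (i in seq_len(n_blocks - 1L)) blocks <- c(blocks, list(
    nn_basic_block(out_ch, out_ch, 1L)))
  names(blocks) <- paste0("block", seq_len(n_blocks))
  do.call(nn_sequential, blocks)
}

#' Build the ResNet-34 feature encoder
#'
#' Constructs the five-tap convolutional encoder. All weights come from a
#' seeded He-normal initialisation, so two builds with the same seed are
#' bitwise identical. ImageNet-pretrained weights are supported only through
#' an explicit checkpoint file; none are bundled.
#'
#' @param pretrained logical; if `TRUE`, `weights` must point to an encoder
#'   checkpoint saved with [save_checkpoint()]. No weight file is downloaded.
#' @param seed integer seed for weight initialisation.
#' @param width_mult positive multiplier on all channel widths (1 gives the
#'   standard 64/64/128/256/512 taps; 0.25 the reduced desk-scale model).
#' @param weights optional path to a checkpoint holding encoder parameters.
#' @return an `nn_module` of class `resnet_encoder`
#' @examples
#' enc <- build_encoder(seed = 7, width_mult = 0.25)
#' count_parameters(enc)
#' @export
build_encoder <- function(pretrained = FALSE, seed = 1L, width_mult = 1,
                          weights = NULL) {
  w <- as.integer(round(64 * width_mult))
  if (w < 4L || w %% 4L != 0L)
    stop("width_mult must give a base width that is a positive multiple of 4")
  set.seed(seed)
  self <- new_module("resnet_encoder")
  self$widths <- c(w, w, 2L * w, 4L * w, 8L * w)
  self$strides <- c(2L, 4L, 8L, 16L, 32L)
  self$children$conv1 <- nn_conv2d(3L, w, 7L, stride = 2L, pad = 3L,
                                   bias = FALSE)
  self$children$bn1 <- nn_batchnorm2d(w)
  self$children$pool <- nn_maxpool2d(3L, 2L, 1L)
  self$children$layer1 <- res_stage(3L, w, w, 1L)
  self$children$layer2 <- res_stage(4L, w, 2L * w, 2L)
  self$children$layer3 <- res_stage(6L, 2L * w, 4L * w, 2L)
  self$children$layer4 <- res_stage(3L, 4L * w, 8L * w, 2L)

  # returns the raw list of tap arrays (t2, t4, t8, t16, t32)
  self$forward_taps <- function(x) {
    ch <- self$children
    s <- ch$bn1$forward(ch$conv1$forward(x))
    ms <- s > 0
    if (self$training) self$ms <- ms
    t2 <- s * ms
    t4 <- ch$layer1$forward(ch$pool$forward(t2))
    t8 <- ch$layer2$forward(t4)
    t16 <- ch$layer3$forward(t8)
    t32 <- ch$layer4$forward(t16)
    list(t2 = t2, t4 = t4, t8 = t8, t16 = t16, t32 = t32)
  }
  self$forward <- function(x) self$forward_taps(x)$t32

  # dtaps: list with gradients for any subset of t2/t4/t8/t16/t32
  self$backward_taps <- function(dtaps) {
    ch <- self$children
    zero <- function(g) if (is.null(g)) 0 else g
    d16 <- ch$layer4$backward(dtaps$t32) + zero(dtaps$t16)
    d8 <- ch$layer3$backward(d16) + zero(dtaps$t8)
    d4 <- ch$layer2$backward(d8) + zero(dtaps$t4)
    d2 <- ch$pool$backward(ch$layer1$backward(d4))
    if (!is.null(dtaps$t2)) d2 <- d2 + dtaps$t2
    ch$conv1$backward(ch$bn1$backward(d2 * self$ms))
  }

  if (pretrained) {
    if (is.null(weights))
      stop("pretrained = TRUE but no weight source is available: no ",
           "ImageNet-pretrained ResNet-34 checkpoint is bundled with this ",
           "package; pass `weights = <path to an encoder checkpoint>` or ",
           "use pretrained = FALSE for seeded random initialisation",
           call. = FALSE)
    ck <- readRDS(weights)
    nn_set_parameters(self, ck$params)
    nn_set_buffers(self, ck$buffers)
  }
  nn_set_training(self, FALSE)
  self
}

#' Encode an image batch into the five-tap feature pyramid
#'
#' @param encoder an encoder from [build_encoder()]
#' @param images numeric array `(H, W, 3)` or `(H, W, 3, N)` with H and W
#'   divisible by 32
#' @return an `encoder_pyramid`: list of five feature maps (`tap_s2`,
#'   `tap_s4`, `tap_s8`, `tap_s16`, `bottleneck`), each a list with `data`
#'   (the `(H, W, C, N)` array), `stride` and `channels`
#' @examples
#' enc <- build_encoder(seed = 1, width_mult = 0.25)
#' pyr <- encode(enc, array(0.5, c(64, 64, 3)))
#' dim(pyr$bottleneck$data)
#' @export
encode <- function(encoder, images) {
  x <- as_batch(images, channels = 3L)
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input size ", d[1], "x", d[2], " is not divisible by 32; ",
         "use pad_to_stride() first", call. = FALSE)
  taps <- encoder$forward_taps(x)
  fm <- function(a, stride) {
    structure(list(data = a, stride = stride, channels = dim(a)[3]),
              class = "feature_map")
  }
  structure(list(tap_s2 = fm(taps$t2, 2L), tap_s4 = fm(taps$t4, 4L),
                 tap_s8 = fm(taps$t8, 8L), tap_s16 = fm(taps$t16, 16L),
                 bottleneck = fm(taps$t32, 32L)),
            class = "encoder_pyramid")
}

#' @export
print.encoder_pyramid <- function(x, ...) {
  cat("<encoder_pyramid>\n")
  for (nm in names(x)) {
    d <- dim(x[[nm]]$data)
    cat(sprintf("  %-10s stride %2d: %dx%dx%d (batch %d)\n", nm,
                x[[nm]]$stride, d[1], d[2], d[3], d[4]))
  }
  invisible(x)
}

# coerce (H,W,C) / (H,W,C,N) to a 4-D batch, checking the channel count
as_batch <- function(x, channels = NULL) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L, 4L)))
    stop("expected an array of 2-4 dimensions")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (!is.null(channels) && dim(x)[3] != channels)
    stop("expected ", channels, " channels, got ", dim(x)[3])
  x
}
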