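# Multibranch hybrid attention (MHA) decoder and full-network assembly.
#
# One decoder stage: transposed-conv upsample (x2, channel preserving),
# concatenation with the matching encoder skip tap, two 3x3 conv+BN+ReLU
# (first fusing the concatenation back to the incoming width, second
# projecting to the skip width), squeeze-excitation channel attention, and
# an elementwise summation with the skip tap.  The SE and summation branches
# are the ablation switches.  A final skip-free x2 transposed-conv stage
# brings the stride-2 features to full resolution before the two-conv
# segmentation head.

#' Configuration of one MHA decoder stage
#'
#' @param in_channels channels of the incoming (deep) feature map
#' @param skip_channels channels of the encoder skip tap at twice the
#'   spatial size
#' @param out_channels stage output channels; must equal `skip_channels`
#'   when `use_sum` is `TRUE` (the summation needs matching widths)
#' @param mid_channels width of the first 3x3 convolution's output; defaults
#'   to `in_channels`
#' @param use_se include squeeze-excitation channel attention
#' @param use_sum include the additive skip branch
#' @param upsample_kernel transposed-convolution kernel (stride 2); the
#'   default 4 with padding 1 doubles the spatial size exactly
#' @param se_reduction SE bottleneck reduction ratio
#' @return a `decoder_stage_config` list
#' @export
decoder_stage_config <- function(in_channels, skip_channels,
                                 out_channels = skip_channels,
                                 mid_channels = in_channels,
                                 use_se = TRUE, use_sum = TRUE,
                                 upsample_kernel = 4L, se_reduction = 16L) {
  cfg <- list(in_channels = as.integer(in_channels),
              skip_channels = as.integer(skip_channels),
              out_channels = as.integer(out_channels),
              mid_channels = as.integer(mid_channels),
              use_se = isTRUE(use_se), use_sum = isTRUE(use_sum),
              upsample_kernel = as.integer(upsample_kernel),
              se_reduction = as.integer(se_reduction))
  if (cfg$use_sum && cfg$out_channels != cfg$skip_channels)
    stop("use_sum = TRUE requires out_channels (", cfg$out_channels,
         ") to equal skip_channels (", cfg$skip_channels, ")", call. = FALSE)
  if (cfg$upsample_kernel %% 2L != 0L)
    stop("upsample_kernel must be even for exact x2 upsampling")
  structure(cfg, class = "decoder_stage_config")
}

# center-crop a (H,W,C,N) array to (th, tw); returns list(x, oh, ow, H, W)
crop_center <- function(a, th, tw) {
  d <- dim(a)
  if (d[1] - th > 2L || d[2] - tw > 2L)
    stop("cannot reconcile feature sizes ", d[1], "x", d[2], " and ",
         th, "x", tw, " by cropping at most 1 pixel per edge")
  oh <- (d[1] - th) %/% 2L; ow <- (d[2] - tw) %/% 2L
  x <- if (oh > 0L || ow > 0L)
    a[(oh + 1L):(oh + th), (ow + 1L):(ow + tw), , , drop = FALSE] else a
  list(x = x, oh = oh, ow = ow, H = d[1], W = d[2])
}

uncrop <- function(dx, cr, C, N) {
  if (cr$oh == 0L && cr$ow == 0L) return(dx)
  out <- array(0, c(cr$H, cr$W, C, N))
  d <- dim(dx)
  out[(cr$oh + 1L):(cr$oh + d[1]), (cr$ow + 1L):(cr$ow + d[2]), , ] <- dx
  out
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

nn_mha_stage <- function(scfg) {
  stopifnot(inherits(scfg, "decoder_stage_config"))
  self <- new_module("nn_mha_stage")
  self$cfg <- scfg
  k <- scfg$upsample_kernel
  self$children$up <- nn_conv_transpose2d(scfg$in_channels, scfg$in_channels,
                                          k = k, stride = 2L,
                                          pad = (k - 2L) %/% 2L, bias = FALSE)
  self$children$up_bn <- nn_batchnorm2d(scfg$in_channels)
  self$children$conv1 <- nn_conv2d(scfg$in_channels + scfg$skip_channels,
                                   scfg$mid_channels, 3L, pad = 1L,
                                   bias = FALSE)
  self$children$bn1 <- nn_batchnorm2d(scfg$mid_channels)
  self$children$conv2 <- nn_conv2d(scfg$mid_channels, scfg$out_channels, 3L,
                                   pad = 1L, bias = FALSE)
  self$children$bn2 <- nn_batchnorm2d(scfg$out_channels)
  if (scfg$use_se)
    self$children$se <- nn_se_block(scfg$out_channels, scfg$se_reduction)

  self$forward <- function(deep, skip) {
    ch <- self$children; cfg <- self$cfg
    dd <- dim4(deep); ds <- dim4(skip)
    if (ds[3] != cfg$skip_channels)
      stop("skip tap has ", ds[3], " channels; stage expects ",
           cfg$skip_channels)
    u <- ch$up_bn$forward(ch$up$forward(deep))
    mu <- u > 0
    u <- u * mu
    th <- min(dim(u)[1], ds[1]); tw <- min(dim(u)[2], ds[2])
    cru <- crop_center(u, th, tw)
    crs <- crop_center(skip, th, tw)
    xcat <- cat_channels(cru$x, crs$x)
    y <- ch$bn1$forward(ch$conv1$forward(xcat))
    m1 <- y > 0
    y <- ch$bn2$forward(ch$conv2$forward(y * m1))
    m2 <- y > 0
    y <- y * m2
    if (cfg$use_se) y <- ch$se$forward(y)
    if (cfg$use_sum) y <- y + crs$x
    self$last_shapes <- list(upsampled = dim(u), concat = dim(xcat),
                             out = dim(y))
    if (self$training) {
      self$mu <- mu; self$m1 <- m1; self$m2 <- m2
      self$cru <- cru[c("oh", "ow", "H", "W")]
      self$crs <- crs[c("oh", "ow", "H", "W")]
      self$du_dim <- dim(u); self$skip_dim <- ds
    }
    y
  }

  # returns list(deep = d deep, skip = d skip)
  self$backward <- function(dy) {
    ch <- self$children; cfg <- self$cfg
    dskip_c <- 0
    if (cfg$use_sum) dskip_c <- dy
    if (cfg$use_se) dy <- ch$se$backward(dy)
    dy <- dy * self$m2
    dy <- ch$conv2$backward(ch$bn2$backward(dy))
    dy <- dy * self$m1
    dcat <- ch$conv1$backward(ch$bn1$backward(dy))
    cu <- cfg$in_channels; cs <- cfg$skip_channels
    dcr <- dim(dcat)
    du <- dcat[, , seq_len(cu), , drop = FALSE]
    dskip_c <- dskip_c + dcat[, , cu + seq_len(cs), , drop = FALSE]
    dskip <- uncrop(dskip_c, self$crs, cs, dcr[4])
    du <- uncrop(du, self$cru, cu, dcr[4])
    du <- du * self$mu
    ddeep <- ch$up$backward(ch$up_bn$backward(du))
    list(deep = ddeep, skip = dskip)
  }
  self
}

# final skip-free upsampling + two-conv segmentation head
nn_mha_head <- function(in_ch, head_ch, upsample_kernel = 4L) {
  self <- new_module("nn_mha_head")
  k <- upsample_kernel
  self$children$up <- nn_conv_transpose2d(in_ch, head_ch, k = k, stride = 2L,
                                          pad = (k - 2L) %/% 2L, bias = FALSE)
  self$children$up_bn <- nn_batchnorm2d(head_ch)
  self$children$conv1 <- nn_conv2d(head_ch, head_ch, 3L, pad = 1L,
                                   bias = FALSE)
  self$children$bn1 <- nn_batchnorm2d(head_ch)
  self$children$conv2 <- nn_conv2d(head_ch, 1L, 3L, pad = 1L, bias = TRUE)
  self$forward <- function(x) {
    ch <- self$children
    u <- ch$up_bn$forward(ch$up$forward(x))
    mu <- u > 0
    self$prehead_dim <- dim(u)
    y <- ch$bn1$forward(ch$conv1$forward(u * mu))
    m1 <- y > 0
    if (self$training) { self$mu <- mu; self$m1 <- m1 }
    ch$conv2$forward(y * m1)
  }
  self$backward <- function(dy) {
    ch <- self$children
    dy <- ch$conv2$backward(dy) * self$m1
    du <- ch$conv1$backward(ch$bn1$backward(dy)) * self$mu
    ch$up$backward(ch$up_bn$backward(du))
  }
  self
}

#' Full-network configuration
#'
#' Describes the complete segmentation network: encoder widths, the PSA
#' bridge, the four decoder stages and the segmentation head, plus the three
#' ablation switches. The four ablation rows of the component study are the
#' triples (use_psa, use_se, use_sum) = (F,F,F) baseline, (T,F,F), (F,T,F)
#' and (T,T,T) full model.
#'
#' @param input_size length-2 integer `(H, W)`, both divisible by 32; only
#'   used for documentation/trace defaults — the assembled network is fully
#'   convolutional and runs on any divisible size
#' @param width_mult channel-width multiplier (1 = full model, 0.25 =
#'   quarter-width desk-scale model)
#' @param use_psa include the pyramid split attention bridge
#' @param use_se include channel attention inside the decoder stages
#' @param use_sum include the additive skip branch inside the decoder stages
#' @param head_channels width of the full-resolution pre-head feature map
#'   (default `32 * width_mult`)
#' @param upsample_kernel transposed-convolution kernel for all upsampling
#' @param se_reduction SE reduction ratio used in decoder stages
#' @param psa a [psa_config()]; defaults to four groups over the bottleneck
#' @param stages optional list of 4 [decoder_stage_config()]s overriding the
#'   default chain
#' @param seed integer; the single seed behind all weight initialisation
#' @return a `mhanet_config`
#' @examples
#' cfg <- model_config(width_mult = 0.25, input_size = c(96, 96))
#' cfg$stages[[1]]$in_channels
#' @export
model_config <- function(input_size = c(800L, 800L), width_mult = 1,
                         use_psa = TRUE, use_se = TRUE, use_sum = TRUE,
                         head_channels = NULL, upsample_kernel = 4L,
                         se_reduction = 16L, psa = NULL, stages = NULL,
                         seed = 1L) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 32L != 0L))
    stop("input_size must be two integers divisible by 32")
  w <- as.integer(round(64 * width_mult))
  if (w < 4L || w %% 4L != 0L)
    stop("width_mult must give a base width that is a positive multiple of 4")
  if (is.null(head_channels)) head_channels <- max(4L, w %/% 2L)
  if (is.null(psa))
    psa <- psa_config(group_channels = (8L * w) %/% 4L,
                      se_reduction = max(1L, min(se_reduction,
                                                 (8L * w) %/% 16L)))
  if (is.null(stages)) {
    widths <- c(8L * w, 4L * w, 2L * w, w, w)  # deep widths + final out
    skips <- c(4L * w, 2L * w, w, w)
    stages <- lapply(1:4, function(i)
      decoder_stage_config(in_channels = widths[i], skip_channels = skips[i],
                           use_se = use_se, use_sum = use_sum,
                           upsample_kernel = upsample_kernel,
                           se_reduction = max(1L, min(se_reduction,
                                                      skips[i] %/% 4L))))
  }
  cfg <- structure(list(input_size = input_size, width_mult = width_mult,
                        base_width = w, use_psa = isTRUE(use_psa),
                        use_se = isTRUE(use_se), use_sum = isTRUE(use_sum),
                        head_channels = as.integer(head_channels),
                        upsample_kernel = as.integer(upsample_kernel),
                        se_reduction = as.integer(se_reduction),
                        psa = psa, stages = stages, seed = as.integer(seed)),
                   class = "mhanet_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  w <- cfg$base_width
  if (length(cfg$stages) != 4L)
    stop("a model needs exactly 4 decoder stages, got ", length(cfg$stages))
  expect_in <- 8L * w
  skips <- c(4L * w, 2L * w, w, w)
  for (i in 1:4) {
    s <- cfg$stages[[i]]
    if (s$in_channels != expect_in)
      stop("decoder stage ", i, " is inconsistent: in_channels = ",
           s$in_channels, " but the incoming feature map has ", expect_in,
           " channels", call. = FALSE)
    if (s$skip_channels != skips[i])
      stop("decoder stage ", i, " is inconsistent: skip_channels = ",
           s$skip_channels, " but the encoder tap has ", skips[i],
           " channels", call. = FALSE)
    expect_in <- s$out_channels
  }
  if (cfg$use_psa &&
      cfg$psa$n_groups * cfg$psa$group_channels != 8L * w)
    stop("PSA config covers ", cfg$psa$n_groups * cfg$psa$group_channels,
         " channels but the bottleneck has ", 8L * w, call. = FALSE)
  invisible(cfg)
}

#' Ablation-study configurations
#'
#' @param variant one of `"baseline"` (no PSA, no SE, no summation),
#'   `"psa"`, `"se"`, `"full"`
#' @param ... passed to [model_config()]
#' @return a `mhanet_config`
#' @export
ablation_config <- function(variant = c("baseline", "psa", "se", "full"),
                            ...) {
  variant <- match.arg(variant)
  flags <- switch(variant,
                  baseline = c(FALSE, FALSE, FALSE),
                  psa = c(TRUE, FALSE, FALSE),
                  se = c(FALSE, TRUE, FALSE),
                  full = c(TRUE, TRUE, TRUE))
  model_config(use_psa = flags[1], use_se = flags[2], use_sum = flags[3], ...)
}

#' Assemble the full segmentation network
#'
#' Encoder, optional PSA bridge, four MHA decoder stages wired to the
#' stride-16/8/4/2 taps, and the full-resolution segmentation head. All
#' weights are drawn from the single seed in the config.
#'
#' @param cfg a [model_config()]
#' @return an `nn_module` of class `mhanet_model`; query size with
#'   [count_parameters()], run it with [predict()][predict.mhanet_model]
#' @examples
#' model <- assemble_mhanet(model_config(width_mult = 0.25,
#'                                       input_size = c(64, 64)))
#' p <- predict(model, array(runif(64 * 64 * 3), c(64, 64, 3)))
#' dim(p)
#' @export
assemble_mhanet <- function(cfg) {
  stopifnot(inherits(cfg, "mhanet_config"))
  validate_model_config(cfg)
  self <- new_module(c("mhanet_model"))
  class(self) <- c("mhanet_model", "nn_module")
  self$config <- cfg
  self$children$encoder <- build_encoder(pretrained = FALSE, seed = cfg$seed,
                                         width_mult = cfg$width_mult)
  if (cfg$use_psa) self$children$psa <- nn_psa(cfg$psa)
  for (i in 1:4)
    self$children[[paste0("stage", i)]] <- nn_mha_stage(cfg$stages[[i]])
  self$children$head <- nn_mha_head(cfg$stages[[4]]$out_channels,
                                    cfg$head_channels, cfg$upsample_kernel)
  nn_set_training(self, FALSE)

  self$forward_logits <- function(x) {
    x <- as_batch(x, channels = 3L)
    d <- dim(x)
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
      stop("input size ", d[1], "x", d[2], " is not divisible by 32; ",
           "use pad_to_stride() first", call. = FALSE)
    ch <- self$children
    taps <- ch$encoder$forward_taps(x)
    b <- taps$t32
    trace <- list(input = dim(x), bottleneck = dim(b))
    if (!is.null(ch$psa)) {
      b <- ch$psa$forward(b)
      trace$psa_out <- dim(b)
    }
    skips <- list(taps$t16, taps$t8, taps$t4, taps$t2)
    for (i in 1:4) {
      st <- ch[[paste0("stage", i)]]
      b <- st$forward(b, skips[[i]])
      trace[[paste0("stage", i, "_upsampled")]] <- st$last_shapes$upsampled
      trace[[paste0("stage", i, "_concat")]] <- st$last_shapes$concat
      trace[[paste0("stage", i, "_out")]] <- st$last_shapes$out
    }
    logits <- ch$head$forward(b)
    trace$prehead <- ch$head$prehead_dim
    trace$output <- dim(logits)
    self$last_trace <- trace
    logits
  }

  self$backward <- function(dlogits) {
    ch <- self$children
    dy <- ch$head$backward(dlogits)
    dtaps <- list()
    keys <- c("t16", "t8", "t4", "t2")
    for (i in 4:1) {
      g <- ch[[paste0("stage", i)]]$backward(dy)
      dtaps[[keys[i]]] <- g$skip
      dy <- g$deep
    }
    if (!is.null(ch$psa)) dy <- ch$psa$backward(dy)
    dtaps$t32 <- dy
    ch$encoder$backward_taps(dtaps)
  }
  self
}

#' Run the network on an image batch
#'
#' @param object a model from [assemble_mhanet()]
#' @param images `(H, W, 3)` or `(H, W, 3, N)` array in `[0, 1]`, H and W
#'   divisible by 32
#' @param type `"prob"` for sigmoid probabilities in (0, 1), `"logits"` for
#'   the raw head output
#' @param ... unused
#' @return `(H, W, 1, N)` array
#' @export
predict.mhanet_model <- function(object, images, type = c("prob", "logits"),
                                 ...) {
  type <- match.arg(type)
  z <- object$forward_logits(images)
  if (type == "logits") z else 1 / (1 + exp(-z))
}

#' @export
print.mhanet_model <- function(x, ...) {
  cfg <- x$config
  cat("<mhanet_model> width_mult=", cfg$width_mult,
      " psa=", cfg$use_psa, " se=", cfg$use_se, " sum=", cfg$use_sum, "\n",
      "  trainable parameters: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Record the feature-map sizes of a forward pass
#'
#' Runs one evaluation-mode forward pass on a zero image of the given size
#' and returns every intermediate shape: bottleneck, PSA output, per-stage
#' upsampled/concatenated/output maps, the full-resolution pre-head feature
#' map, and the output.
#'
#' @param model a `mhanet_model`
#' @param size `(H, W)`, divisible by 32; defaults to the config input size
#' @return named list of integer shape vectors `(H, W, C, N)`
#' @examples
#' m <- assemble_mhanet(model_config(width_mult = 0.25,
#'                                   input_size = c(64, 64)))
#' trace_shapes(m)$bottleneck
#' @export
trace_shapes <- function(model, size = model$config$input_size) {
  stopifnot(inherits(model, "mhanet_model"))
  was <- model$training
  nn_set_training(model, FALSE)
  on.exit(nn_set_training(model, was))
  x <- array(0, c(size[1], size[2], 3L, 1L))
  model$forward_logits(x)
  model$last_trace
}
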