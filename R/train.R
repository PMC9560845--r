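# Training protocol: binary cross-entropy on logits, Adam, fixed learning
# rate, best-validation-Dice checkpoint selection, fully seeded.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4 and
#' binary cross-entropy. [train_presets()] gives the per-dataset batch-size
#' and epoch presets (retina 4/300, X-ray 4/150, polyp 8/150).
#'
#' @param learning_rate Adam learning rate (> 0)
#' @param batch_size images per optimization step (>= 1)
#' @param epochs training epochs (>= 1)
#' @param seed integer seed for shuffling and any other randomness
#' @param threshold binarization threshold for validation Dice
#' @param checkpoint_dir optional directory to write the best checkpoint to
#' @param average aggregation mode for validation metrics
#' @return a `train_config`
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         epochs = 150L, seed = 1L, threshold = 0.5,
                         checkpoint_dir = NULL,
                         average = c("macro", "micro")) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 threshold = threshold, checkpoint_dir = checkpoint_dir,
                 average = match.arg(average)),
            class = "train_config")
}

#' @rdname train_config
#' @param dataset `"drive"`, `"frsa"` or `"polyp"`
#' @param ... overrides passed on to [train_config()]
#' @export
train_presets <- function(dataset = c("drive", "frsa", "polyp"), ...) {
  dataset <- match.arg(dataset)
  preset <- switch(dataset,
                   drive = list(batch_size = 4L, epochs = 300L),
                   frsa = list(batch_size = 4L, epochs = 150L),
                   polyp = list(batch_size = 8L, epochs = 150L))
  do.call(train_config, utils::modifyList(preset, list(...)))
}

#' Binary cross-entropy computed on logits
#'
#' Numerically stable form `max(z,0) - z*y + log(1 + exp(-|z|))`, averaged
#' over all pixels; identical to probability-space BCE up to floating-point
#' error.
#'
#' @param logits numeric array of raw network outputs
#' @param target binary array of the same shape
#' @return scalar loss
#' @export
bce_with_logits <- function(logits, target) {
  z <- as.vector(logits); y <- as.vector(target)
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

bce_grad <- function(logits, target) {
  g <- (1 / (1 + exp(-logits)) - target) / length(logits)
  dim(g) <- dim(logits)
  g
}

# --- Adam ------------------------------------------------------------------

adam_init <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(st, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- if (is.null(st$m[[nm]])) g * (1 - beta1)
         else beta1 * st$m[[nm]] + (1 - beta1) * g
    v <- if (is.null(st$v[[nm]])) g^2 * (1 - beta2)
         else beta2 * st$v[[nm]] + (1 - beta2) * g^2
    st$m[[nm]] <- m; st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  params
}

# --- training loop ---------------------------------------------------------

pad_record <- function(r, stride = 32L) {
  p <- pad_to_stride(r$image, stride)
  m <- pad_to_stride(array(r$mask, c(dim(r$mask), 1L)), stride)
  list(image = p$image, mask = m$image, crop = p$crop, orig = r)
}

#' Train a segmentation network
#'
#' Runs per-epoch optimization of binary cross-entropy (computed on logits)
#' with Adam at a constant learning rate. When a validation set is given,
#' the parameters with the best validation Dice are restored into the model
#' at the end and stored in the returned checkpoint. Fully deterministic
#' for a fixed config seed.
#'
#' @param model a `mhanet_model` from [assemble_mhanet()]
#' @param train_set,val_set lists of `sample_record`s (all images the same
#'   size after stride padding); `val_set` may be `NULL`
#' @param cfg a [train_config()]
#' @return list with `model`, `checkpoint` (see [save_checkpoint()]) and
#'   `log` — a data frame with one row per epoch (`epoch`, `loss`,
#'   `val_dice`, `seconds`) carrying the config hash and seed as attributes
#' @export
train <- function(model, train_set, val_set = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "mhanet_model"), inherits(cfg, "train_config"))
  if (length(train_set) == 0L) stop("train_set is empty", call. = FALSE)
  tr <- lapply(train_set, pad_record)
  sizes <- vapply(tr, function(r) dim(r$image)[1:2], integer(2))
  if (any(sizes != sizes[, 1]))
    stop("all training images must share one size after padding",
         call. = FALSE)
  H <- sizes[1, 1]; W <- sizes[2, 1]
  n <- length(tr)
  opt <- adam_init()
  set.seed(cfg$seed)
  best_dice <- -Inf
  best <- NULL
  log_rows <- vector("list", cfg$epochs)
  t0 <- Sys.time()
  for (epoch in seq_len(cfg$epochs)) {
    nn_set_training(model, TRUE)
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      ids <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      B <- length(ids)
      x <- array(0, c(H, W, 3L, B)); y <- array(0, c(H, W, 1L, B))
      for (j in seq_len(B)) {
        x[, , , j] <- tr[[ids[j]]]$image
        y[, , , j] <- tr[[ids[j]]]$mask
      }
      z <- model$forward_logits(x)
      loss <- bce_with_logits(z, y)
      if (!is.finite(loss))
        stop("training aborted: loss became non-finite at epoch ", epoch,
             ". Check that images lie in [0, 1] and consider a smaller ",
             "learning rate (current ", cfg$learning_rate, ")",
             call. = FALSE)
      losses <- c(losses, loss)
      model$backward(bce_grad(z, y))
      nn_set_parameters(model, adam_step(opt, nn_parameters(model),
                                         nn_gradients(model),
                                         cfg$learning_rate))
    }
    val_dice <- NA_real_
    if (!is.null(val_set) && length(val_set) > 0L) {
      val_dice <- mean_dice(model, val_set, cfg$threshold)
      if (val_dice > best_dice) {
        best_dice <- val_dice
        best <- list(params = nn_parameters(model),
                     buffers = nn_buffers(model))
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(losses), val_dice = val_dice,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  if (!is.null(best)) {
    nn_set_parameters(model, best$params)
    nn_set_buffers(model, best$buffers)
  }
  nn_set_training(model, FALSE)
  log <- do.call(rbind, log_rows)
  attr(log, "seed") <- cfg$seed
  attr(log, "config_hash") <- config_hash(cfg)
  ck <- checkpoint_object(model)
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(ck, file.path(cfg$checkpoint_dir, "checkpoint.rds"))
  }
  list(model = model, checkpoint = ck, log = log)
}

mean_dice <- function(model, records, threshold) {
  nn_set_training(model, FALSE)
  mean(vapply(records, function(r) {
    p <- pad_record(r)
    prob <- predict(model, p$image)
    prob <- crop_to_original(prob[, , 1L, 1L], p$crop)
    dice(confusion_counts(prob > threshold, r$mask))
  }, 0))
}

# --- checkpoints -----------------------------------------------------------

checkpoint_object <- function(model) {
  list(format = "mhanet_checkpoint", version = 1L,
       config = model$config,
       params = nn_parameters(model),
       buffers = nn_buffers(model))
}

#' Save / load a model checkpoint
#'
#' The single checkpoint format embeds the full model configuration, so a
#' checkpoint reloads without any sidecar config file. Bare modules (e.g. an
#' encoder from [build_encoder()]) can be saved too; their weights reload
#' through `build_encoder(pretrained = TRUE, weights = path)` rather than
#' [load_checkpoint()].
#'
#' @param model a `mhanet_model`, or any bare `nn_module`
#' @param path file to write (RDS)
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `mhanet_model` in evaluation mode
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(checkpoint_object(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param x a path to a saved checkpoint, a checkpoint list, or a
#'   `mhanet_model` (returned unchanged)
#' @export
load_checkpoint <- function(x) {
  if (inherits(x, "mhanet_model")) return(x)
  if (is.character(x)) x <- readRDS(x)
  if (!identical(x$format, "mhanet_checkpoint"))
    stop("not a recognised checkpoint object", call. = FALSE)
  if (is.null(x$config))
    stop("checkpoint holds bare module weights without a model config; ",
         "encoder weights load via build_encoder(pretrained = TRUE, ",
         "weights = <path>)", call. = FALSE)
  model <- assemble_mhanet(x$config)
  nn_set_parameters(model, x$params)
  nn_set_buffers(model, x$buffers)
  nn_set_training(model, FALSE)
  model
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# --- evaluation ------------------------------------------------------------

#' Evaluate a model or checkpoint on a test set
#'
#' Each image is reflection-padded to stride 32, predicted, cropped back,
#' and scored with [metric_report()] against its original-size mask.
#'
#' @param x a `mhanet_model`, checkpoint list or checkpoint path
#' @param test_set list of `sample_record`s
#' @param threshold binarization threshold
#' @param average `"macro"` (mean of per-image metrics) or `"micro"`
#'   (metrics of the pooled pixel counts)
#' @return list with `per_image` (data frame) and `aggregate`
#'   (`metric_report`)
#' @export
evaluate <- function(x, test_set, threshold = 0.5,
                     average = c("macro", "micro")) {
  average <- match.arg(average)
  model <- load_checkpoint(x)
  nn_set_training(model, FALSE)
  if (length(test_set) == 0L) stop("test_set is empty", call. = FALSE)
  probs <- vector("list", length(test_set))
  reports <- vector("list", length(test_set))
  for (i in seq_along(test_set)) {
    r <- test_set[[i]]
    p <- pad_record(r)
    prob <- crop_to_original(predict(model, p$image)[, , 1L, 1L], p$crop)
    probs[[i]] <- prob
    reports[[i]] <- suppressWarnings(metric_report(prob, r$mask, threshold))
  }
  per_image <- do.call(rbind, lapply(seq_along(reports), function(i)
    data.frame(image = test_set[[i]]$name %||% sprintf("sample_%03d", i),
               as.data.frame(unclass(reports[[i]])))))
  aggregate <- if (average == "macro") {
    vals <- colMeans(per_image[, -1, drop = FALSE], na.rm = TRUE)
    structure(as.list(vals), class = "metric_report")
  } else {
    pooled_pred <- unlist(lapply(probs, function(p) p > threshold))
    pooled_truth <- unlist(lapply(test_set, function(r) r$mask))
    cc <- confusion_counts(pooled_pred, pooled_truth)
    suppressWarnings(report_from_counts(cc, prob = unlist(probs),
                                        truth = pooled_truth))
  }
  list(per_image = per_image, aggregate = aggregate, average = average)
}

# --- single-image prediction -----------------------------------------------

#' Predict a segmentation mask for one image and write it to disk
#'
#' Writes the probability map as 16-bit TIFF and the thresholded mask as
#' 8-bit {0, 255} PNG, both cropped back to the input size. The mask is
#' derived from the 16-bit-quantized probabilities, so re-thresholding the
#' written probability map reproduces the written mask exactly.
#'
#' @param x model, checkpoint or checkpoint path
#' @param image image file path or `(H, W, 3)` array
#' @param out_prefix output prefix; files are `<prefix>_prob.tiff` and
#'   `<prefix>_mask.png`
#' @param threshold binarization threshold
#' @return invisible list with the two output paths and the probability
#'   matrix
#' @export
predict_mask <- function(x, image, out_prefix, threshold = 0.5) {
  model <- load_checkpoint(x)
  nn_set_training(model, FALSE)
  if (is.character(image)) image <- read_image(image)
  p <- pad_to_stride(image)
  prob <- crop_to_original(predict(model, p$image)[, , 1L, 1L], p$crop)
  q <- round(prob * 65535) / 65535
  prob_path <- paste0(out_prefix, "_prob.tiff")
  mask_path <- paste0(out_prefix, "_mask.png")
  tiff::writeTIFF(q, prob_path, bits.per.sample = 16L)
  png::writePNG((q > threshold) + 0, mask_path)
  invisible(list(prob_path = prob_path, mask_path = mask_path, prob = q))
}
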