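# Pixel-overlap evaluation metrics for binary segmentation.
#
# Everything reduces to the four confusion counts TP/FP/TN/FN between a
# predicted and a true mask:
#   DC   = 2 TP / (2 TP + FP + FN)        Dice coefficient
#   IR   = TP / (TP + FP + FN)            intersection ratio (= IoU_poly)
#   Rec  = TP / (TP + FN)   (= Se)        Spec = TN / (TN + FP)
#   Prec = TP / (TP + FP)                 IoU_bg = TN / (TN + FP + FN)
#   mIoU = (IoU_poly + IoU_bg) / 2        Ac = (TP + TN) / total
# AUC is computed from the un-thresholded probabilities via the rank
# (Mann-Whitney) formulation, which equals the trapezoidal area under the
# ROC curve over all distinct thresholds, ties handled by averaging.

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth arrays of identical shape, strictly binary (0/1 or
#'   logical)
#' @return a `confusion_counts` list with fields `tp`, `fp`, `fn`, `tn`
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical shapes", call. = FALSE)
  check_binary(pred, "pred"); check_binary(truth, "truth")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(p) - tp - fp - fn),
            class = "confusion_counts")
}

check_binary <- function(x, name) {
  if (is.logical(x)) return(invisible())
  if (!all(x == 0 | x == 1))
    stop(name, " must be strictly binary (0/1); binarize probabilities ",
         "with a threshold first", call. = FALSE)
  invisible()
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: TP", x$tp, " FP", x$fp, " FN", x$fn, " TN", x$tn,
      "\n")
  invisible(x)
}

# degenerate-safe ratio: empty-vs-empty comparisons count as agreement
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("degenerate ", what, ": no pixels in either mask enter the ",
            "denominator; returning 1 (perfect-agreement convention)",
            call. = FALSE)
    return(1)
  }
  num / den
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`. For the degenerate empty-vs-empty comparison
#' (TP = FP = FN = 0) returns 1 with a warning.
#'
#' @param c a [confusion_counts()] object
#' @return number in `[0, 1]`
#' @export
dice <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "Dice")
}

#' Foreground intersection-over-union (Jaccard / intersection ratio)
#'
#' `TP / (TP + FP + FN)`; related to Dice by `DC = 2 IR / (1 + IR)`.
#' Degenerate empty-vs-empty comparisons return 1 with a warning.
#'
#' @inheritParams dice
#' @return number in `[0, 1]`
#' @export
iou_poly <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_ratio(c$tp, c$tp + c$fp + c$fn, "IoU")
}

#' Area under the ROC curve over pixel probabilities
#'
#' Rank-based (Mann-Whitney) formulation, identical to the trapezoidal area
#' under the ROC built from all distinct thresholds; ties in the
#' probabilities are handled by mid-rank averaging.
#'
#' @param prob numeric array of probabilities in `[0, 1]`
#' @param truth binary array of the same shape containing both classes
#' @return number in `[0, 1]`; 0.5 is chance level
#' @examples
#' auc_score(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(prob, truth) {
  if (length(prob) != length(truth))
    stop("prob and truth must have identical shapes", call. = FALSE)
  check_binary(truth, "truth")
  y <- as.logical(truth)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined: truth contains a single class", call. = FALSE)
  r <- rank(as.vector(prob), ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report for one probability map
#'
#' Binarizes `prob` at `threshold`, computes the confusion counts and fills
#' every overlap metric; AUC comes from the un-thresholded probabilities
#' (`NA` with a warning when the truth holds a single class). `se` is an
#' alias of `rec`, and `ir` is the same quantity as `ioup`.
#'
#' @param prob numeric array with values in `[0, 1]`
#' @param truth binary array of the same shape
#' @param threshold binarization threshold (default 0.5)
#' @return a `metric_report` list with fields `dc`, `ir`, `rec`, `spec`,
#'   `prec`, `ioup`, `ioub`, `miou`, `ac`, `se`, `auc`
#' @examples
#' set.seed(1)
#' truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
#' prob <- pmin(pmax(truth + rnorm(64, 0, 0.3), 0), 1)
#' unlist(metric_report(prob, truth))
#' @export
metric_report <- function(prob, truth, threshold = 0.5) {
  if (!identical(dim(prob), dim(truth)) || length(prob) != length(truth))
    stop("prob and truth must have identical shapes", call. = FALSE)
  if (any(prob < 0 | prob > 1))
    stop("prob values must lie in [0, 1]", call. = FALSE)
  pred <- prob > threshold
  cc <- confusion_counts(pred, truth)
  report_from_counts(cc, prob = prob, truth = truth)
}

# the report body, reused by micro-averaging; AUC optional
report_from_counts <- function(cc, prob = NULL, truth = NULL) {
  auc <- NA_real_
  if (!is.null(prob)) {
    y <- as.logical(truth)
    if (sum(y) == 0 || sum(!y) == 0) {
      warning("AUC undefined for a single-class truth mask; reporting NA",
              call. = FALSE)
    } else {
      auc <- auc_score(prob, truth)
    }
  }
  ioup <- safe_ratio(cc$tp, cc$tp + cc$fp + cc$fn, "IoU")
  ioub <- safe_ratio(cc$tn, cc$tn + cc$fp + cc$fn, "background IoU")
  rec <- safe_ratio(cc$tp, cc$tp + cc$fn, "recall")
  structure(list(
    dc = safe_ratio(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn, "Dice"),
    ir = ioup,
    rec = rec,
    spec = safe_ratio(cc$tn, cc$tn + cc$fp, "specificity"),
    prec = safe_ratio(cc$tp, cc$tp + cc$fp, "precision"),
    ioup = ioup,
    ioub = ioub,
    miou = (ioup + ioub) / 2,
    ac = (cc$tp + cc$tn) / (cc$tp + cc$fp + cc$fn + cc$tn),
    se = rec,
    auc = auc), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.4f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' Write per-image and aggregate metrics to CSV and JSON
#'
#' @param per_image data frame of per-image metric rows
#' @param aggregate a `metric_report`
#' @param path_prefix output files are `<path_prefix>.csv` (per-image rows
#'   plus an `aggregate` row) and `<path_prefix>.json`
#' @return invisible character vector of the two paths
#' @export
write_metric_report <- function(per_image, aggregate, path_prefix) {
  agg <- as.data.frame(unclass(aggregate))
  agg$image <- "aggregate"
  per <- per_image
  out <- rbind(per[, c("image", names(unclass(aggregate)))],
               agg[, c("image", names(unclass(aggregate)))])
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  utils::write.csv(out, csv, row.names = FALSE)
  jsonlite::write_json(list(per_image = per_image,
                            aggregate = unclass(aggregate)),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = json))
}
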