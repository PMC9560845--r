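# Image/mask readers, stride padding, dataset layout and splits.

#' Read a raster image as an `(H, W, 3)` array in `[0, 1]`
#'
#' PNG and TIFF are read natively; JPEG is read through EBImage when that
#' package is installed. Grayscale images are replicated to 3 channels and
#' an alpha channel is dropped.
#'
#' @param path image file
#' @return numeric `(H, W, 3)` array
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the EBImage package")
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop("unsupported image format: .", ext)),
    error = function(e) stop("cannot read image ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 2L) img <- array(img, c(d, 1L))
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a binary mask from a single-channel image file
#'
#' Pixel values above 127/255 are foreground (the on-disk convention is
#' {0, 255} 8-bit PNG).
#'
#' @param path mask file
#' @return `H x W` 0/1 integer matrix
#' @export
read_mask <- function(path) {
  m <- read_image(path)[, , 1L]
  matrix(as.integer(m > 127 / 255), nrow(m), ncol(m))
}

#' Pad an image to the next multiple of a stride
#'
#' Pads the bottom and right edges by reflection (edge pixel not repeated)
#' so that both spatial sizes become divisible by `stride`. The returned
#' crop record inverts the padding exactly via [crop_to_original()].
#'
#' @param image `(H, W)`, `(H, W, C)` or `(H, W, C, N)` array
#' @param stride integer >= 1
#' @return list with `image` (padded array) and `crop` (`list(H, W)`)
#' @examples
#' p <- pad_to_stride(matrix(runif(584 * 565), 584, 565))
#' dim(p$image)  # 608 x 576
#' @export
pad_to_stride <- function(image, stride = 32L) {
  stopifnot(stride >= 1L)
  d <- dim(image) %||% stop("image must be an array")
  H <- d[1]; W <- d[2]
  ph <- (stride - H %% stride) %% stride
  pw <- (stride - W %% stride) %% stride
  if (ph >= H || pw >= W)
    stop("image ", H, "x", W, " is too small to reflection-pad to stride ",
         stride, call. = FALSE)
  if (ph > 0L || pw > 0L) {
    ih <- c(seq_len(H), H - seq_len(ph))
    iw <- c(seq_len(W), W - seq_len(pw))
    image <- if (length(d) == 2L) image[ih, iw]
    else if (length(d) == 3L) image[ih, iw, , drop = FALSE]
    else image[ih, iw, , , drop = FALSE]
  }
  list(image = image, crop = list(H = H, W = W))
}

#' Invert [pad_to_stride()] on a prediction
#'
#' @param x array whose first two dims cover the padded size
#' @param crop the `crop` record from [pad_to_stride()]
#' @return the array cut back to the original `H x W`
#' @export
crop_to_original <- function(x, crop) {
  d <- dim(x)
  if (length(d) == 2L) x[seq_len(crop$H), seq_len(crop$W)]
  else if (length(d) == 3L) x[seq_len(crop$H), seq_len(crop$W), , drop = FALSE]
  else x[seq_len(crop$H), seq_len(crop$W), , , drop = FALSE]
}

#' Build a dataset from paired image and mask directories
#'
#' Files are paired by base name (extension stripped); every image must have
#' exactly one mask partner.
#'
#' @param image_dir,mask_dir directories of raster images / binary masks
#' @return list of `sample_record`s (with `seed = NA`)
#' @export
dataset_from_dirs <- function(image_dir, mask_dir) {
  imgs <- sort(list.files(image_dir, "\\.(png|tif|tiff|jpg|jpeg)$",
                          ignore.case = TRUE))
  if (length(imgs) == 0L) stop("no images found under ", image_dir)
  masks <- list.files(mask_dir, "\\.(png|tif|tiff)$", ignore.case = TRUE)
  mbase <- tools::file_path_sans_ext(masks)
  lapply(imgs, function(f) {
    b <- tools::file_path_sans_ext(f)
    hit <- which(mbase == b | mbase == paste0(b, "_mask"))
    if (length(hit) != 1L)
      stop("image ", f, " has ", length(hit), " mask partners in ",
           mask_dir, " (expected exactly 1)", call. = FALSE)
    structure(list(image = read_image(file.path(image_dir, f)),
                   mask = read_mask(file.path(mask_dir, masks[hit])),
                   seed = NA_integer_, spec = NULL,
                   name = b),
              class = "sample_record")
  })
}

#' Split a record list into train/validation/test subsets
#'
#' @param records list of `sample_record`s
#' @param fractions named numeric vector summing to 1
#' @param seed integer seed for the shuffle
#' @return named list of record lists
#' @export
split_dataset <- function(records,
                          fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  n <- length(records)
  idx <- with_seed(seed, sample.int(n))
  sizes <- floor(fractions * n)
  while (sum(sizes) < n) sizes[which.max(fractions * n - sizes)] <-
      sizes[which.max(fractions * n - sizes)] + 1L
  out <- list()
  at <- 0L
  for (nm in names(fractions)) {
    out[[nm]] <- records[idx[seq_len(sizes[[nm]]) + at]]
    at <- at + sizes[[nm]]
  }
  out
}
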