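# Deterministic synthetic image/mask generator.
#
# Three styles emulate the modalities the network targets at desk scale:
#   vessel - dark random-walk curvilinear trees on a bright textured fundus
#   stent  - thin bright wobbly wire lattices on a dark radiograph texture
#   polyp  - one to three deformed bright ellipses with soft boundaries
# Every sample is fully determined by (spec, seed).  A dataset derives
# per-sample seeds from one global seed with a counter scheme, so it is
# reproducible regardless of generation order.

#' Specification of a synthetic image/mask sample
#'
#' @param size `(H, W)`, both divisible by 32
#' @param style `"vessel"`, `"stent"` or `"polyp"`
#' @param foreground_fraction closed interval the realized mask foreground
#'   fraction must fall into
#' @param contrast foreground/background intensity separation in `(0, 1]`
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#' @param blur_sigma Gaussian blur applied to the clean image (0 = none)
#' @return a `synthetic_spec`
#' @examples
#' synthetic_spec(c(96, 96), "polyp")
#' @export
synthetic_spec <- function(size = c(96L, 96L),
                           style = c("vessel", "stent", "polyp"),
                           foreground_fraction = c(0.03, 0.15),
                           contrast = 0.7, noise_sd = 0.05,
                           blur_sigma = 0.5) {
  style <- match.arg(style)
  size <- as.integer(size)
  if (length(size) != 2L || any(size %% 32L != 0L) || any(size < 32L))
    stop("size must be two integers divisible by 32")
  ff <- as.numeric(foreground_fraction)
  if (length(ff) != 2L || ff[1] > ff[2] || ff[1] < 0 || ff[2] > 1)
    stop("foreground_fraction must be a nonempty interval inside [0, 1]")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  if (noise_sd < 0 || blur_sigma < 0)
    stop("noise_sd and blur_sigma must be >= 0")
  structure(list(size = size, style = style, foreground_fraction = ff,
                 contrast = contrast, noise_sd = noise_sd,
                 blur_sigma = blur_sigma),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# separable Gaussian blur via banded row/column smoothing matrices
gaussian_blur_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smooth_mat <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    w <- stats::dnorm(-r:r, sd = sigma)
    B <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1L & j <= n
      B[cbind(i[ok], j[ok])] <- w[d + r + 1]
    }
    B / rowSums(B)
  }
  smooth_mat(nrow(m)) %*% m %*% t(smooth_mat(ncol(m)))
}

smooth_noise <- function(H, W, sigma = 6) {
  z <- gaussian_blur_2d(matrix(runif(H * W), H, W), sigma)
  rng <- range(z)
  if (diff(rng) < 1e-12) return(matrix(0.5, H, W))
  (z - rng[1]) / diff(rng)
}

# stamp a set of (row, col) points with a small plus/disc footprint
stamp_points <- function(mask, pts, radius = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  off <- expand.grid(dh = -radius:radius, dw = -radius:radius)
  off <- off[off$dh^2 + off$dw^2 <= radius^2 + 0.5, ]
  for (i in seq_len(nrow(off))) {
    h <- pts[, 1] + off$dh[i]
    w <- pts[, 2] + off$dw[i]
    ok <- h >= 1L & h <= H & w >= 1L & w <= W
    mask[cbind(h[ok], w[ok])] <- TRUE
  }
  mask
}

# one smooth random-walk curve across the image
random_curve_points <- function(H, W) {
  n <- round(1.5 * max(H, W))
  theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(n, 0, 0.18))
  h <- runif(1, 1, H) + cumsum(sin(theta))
  w <- runif(1, 1, W) + cumsum(cos(theta))
  cbind(round(h), round(w))
}

draw_vessel_mask <- function(H, W, lo, hi) {
  for (attempt in 1:25) {
    mask <- matrix(FALSE, H, W)
    for (i in 1:200) {
      mask <- stamp_points(mask, random_curve_points(H, W),
                           radius = sample(1:2, 1, prob = c(0.7, 0.3)))
      f <- mean(mask)
      if (f >= lo) break
    }
    f <- mean(mask)
    if (f >= lo && f <= hi) return(mask)
  }
  NULL
}

draw_stent_mask <- function(H, W, lo, hi) {
  diag_len <- sqrt(H^2 + W^2)
  spacing <- diag_len * 4 / (0.5 * (lo + hi) * min(H, W))  # initial guess
  for (attempt in 1:25) {
    mask <- matrix(FALSE, H, W)
    base <- runif(1, 0, pi)
    for (fam in 1:2) {
      ang <- base + (fam - 1) * (pi / 2 + runif(1, -0.2, 0.2))
      u <- c(sin(ang), cos(ang)); v <- c(-u[2], u[1])
      amp <- runif(1, 1, 4); lam <- runif(1, 20, 60); ph <- runif(1, 0, 2 * pi)
      tt <- seq(-diag_len / 2, diag_len / 2, by = 0.5)
      for (o in seq(-diag_len / 2, diag_len / 2, by = spacing)) {
        wob <- o + amp * sin(2 * pi * tt / lam + ph + o)
        h <- round(H / 2 + tt * u[1] + wob * v[1])
        w <- round(W / 2 + tt * u[2] + wob * v[2])
        mask <- stamp_points(mask, cbind(h, w), radius = 1L)
      }
    }
    f <- mean(mask)
    if (f >= lo && f <= hi) return(mask)
    spacing <- spacing * if (f < lo) 0.7 else 1.4
  }
  NULL
}

draw_polyp_mask <- function(H, W, lo, hi) {
  target <- runif(1, lo + 0.2 * (hi - lo), hi - 0.2 * (hi - lo))
  scale <- 1
  rows <- matrix(rep(seq_len(H), W), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  for (attempt in 1:25) {
    mask <- matrix(FALSE, H, W)
    nb <- sample(1:3, 1)
    for (b in seq_len(nb)) {
      r0 <- scale * sqrt(target / nb * H * W / pi)
      cy <- runif(1, 0.25 * H, 0.75 * H)
      cx <- runif(1, 0.25 * W, 0.75 * W)
      stretch <- runif(1, 0.7, 1.4)
      a_k <- runif(3, 0, 0.45) / (2:4)
      p_k <- runif(3, 0, 2 * pi)
      dy <- (rows - cy) * stretch
      dx <- (cols - cx) / stretch
      rr <- sqrt(dy^2 + dx^2)
      phi <- atan2(dy, dx)
      rb <- r0 * (1 + a_k[1] * cos(2 * phi + p_k[1]) +
                    a_k[2] * cos(3 * phi + p_k[2]) +
                    a_k[3] * cos(4 * phi + p_k[3]))
      mask <- mask | (rr <= rb)
    }
    f <- mean(mask)
    if (f >= lo && f <= hi) return(mask)
    scale <- scale * sqrt(max(0.25, min(4, (target / max(f, 1e-6))))) ^ 0.5
  }
  NULL
}

#' Generate one synthetic image/mask sample
#'
#' The sample is a pure function of `(spec, seed)`: two calls with the same
#' arguments return bitwise-identical records.
#'
#' @param spec a [synthetic_spec()]
#' @param seed integer seed for this sample
#' @return a `sample_record`: list with `image` (`(H, W, 3)` array in
#'   `[0, 1]`), `mask` (`H x W` 0/1 integer matrix), `seed` and `spec`
#' @examples
#' rec <- generate_sample(synthetic_spec(c(64, 64), "polyp"), seed = 3)
#' mean(rec$mask)
#' @export
generate_sample <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  lo <- spec$foreground_fraction[1]; hi <- spec$foreground_fraction[2]
  with_seed(seed, {
    mask <- switch(spec$style,
                   vessel = draw_vessel_mask(H, W, lo, hi),
                   stent = draw_stent_mask(H, W, lo, hi),
                   polyp = draw_polyp_mask(H, W, lo, hi))
    if (is.null(mask))
      stop("could not reach a foreground fraction inside [", lo, ", ", hi,
           "] for style '", spec$style, "' after bounded retries",
           call. = FALSE)
    base <- switch(spec$style,
                   vessel = 0.55 + 0.25 * smooth_noise(H, W),
                   stent = 0.15 + 0.25 * smooth_noise(H, W),
                   polyp = 0.20 + 0.25 * smooth_noise(H, W))
    sgn <- if (spec$style == "vessel") -1 else 1
    clean <- pmin(pmax(base + sgn * spec$contrast * 0.8 * mask, 0), 1)
    clean <- gaussian_blur_2d(clean, spec$blur_sigma)
    tint <- switch(spec$style,
                   vessel = c(1.00, 0.85, 0.70),
                   stent = c(0.95, 1.00, 0.95),
                   polyp = c(1.00, 0.80, 0.75))
    img <- array(0, c(H, W, 3L))
    for (c in 1:3)
      img[, , c] <- pmin(pmax(clean * tint[c] +
                                matrix(rnorm(H * W, 0, spec$noise_sd), H, W),
                              0), 1)
    structure(list(image = img, mask = matrix(as.integer(mask), H, W),
                   seed = as.integer(seed), spec = spec),
              class = "sample_record")
  })
}

# counter-based per-sample seeds below 2^31
sample_seed <- function(global_seed, index) {
  as.integer((as.double(global_seed) * 1000003 + index) %% 2147483629)
}

#' Generate a reproducible list of synthetic samples
#'
#' Per-sample seeds are derived from `seed` with a counter scheme
#' (`seed * 1000003 + i`, reduced below 2^31), so sample `i` is identical no
#' matter how many samples are requested.
#'
#' @param spec a [synthetic_spec()]
#' @param n number of samples
#' @param seed global integer seed
#' @return list of `sample_record`s
#' @export
generate_dataset <- function(spec, n, seed = 1L) {
  lapply(seq_len(n), function(i) generate_sample(spec, sample_seed(seed, i)))
}

#' Write samples to an image/mask directory with a manifest
#'
#' Images go to 8-bit 3-channel PNG, masks to 8-bit single-channel PNG with
#' values {0, 255}; `manifest.csv` lists the pairs together with each
#' sample's seed and generator settings, so [read_dataset()] reconstructs
#' the masks exactly.
#'
#' @param records list of `sample_record`s
#' @param dir output directory (created if missing)
#' @return the manifest data frame, invisibly; its path is in
#'   `attr(, "path")`
#' @export
write_dataset <- function(records, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create dataset directory ", dir, call. = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    ip <- sprintf("img_%04d.png", i)
    mp <- sprintf("mask_%04d.png", i)
    ok <- tryCatch({
      png::writePNG(r$image, file.path(dir, ip))
      png::writePNG(r$mask + 0, file.path(dir, mp))
      TRUE
    }, error = function(e)
      stop("failed writing sample ", i, " under ", dir, ": ",
           conditionMessage(e), call. = FALSE))
    data.frame(image_path = ip, mask_path = mp, seed = r$seed,
               style = r$spec$style, height = r$spec$size[1],
               width = r$spec$size[2],
               fg_lo = r$spec$foreground_fraction[1],
               fg_hi = r$spec$foreground_fraction[2],
               contrast = r$spec$contrast, noise_sd = r$spec$noise_sd,
               blur_sigma = r$spec$blur_sigma)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  attr(manifest, "path") <- path
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()] (or any directory
#' with a compatible manifest)
#'
#' @param dir dataset directory containing `manifest.csv`
#' @return list of `sample_record`s (spec fields restored from the manifest)
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path))
    stop("no manifest.csv under ", dir, call. = FALSE)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- read_image(file.path(dir, m$image_path))
    mask <- read_mask(file.path(dir, m$mask_path))
    spec <- synthetic_spec(c(m$height, m$width), m$style,
                           c(m$fg_lo, m$fg_hi), m$contrast, m$noise_sd,
                           m$blur_sigma)
    structure(list(image = img, mask = mask, seed = m$seed, spec = spec),
              class = "sample_record")
  })
}
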