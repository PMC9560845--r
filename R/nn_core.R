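#' @useDynLib mhanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Minimal CPU neural-network engine.
#
# Every layer/block is an environment of class "nn_module" with:
#   $params    named list of numeric arrays (trainable)
#   $grads     named list, filled by $backward
#   $buffers   named list (non-trainable state, e.g. batchnorm running stats)
#   $children  named list of sub-modules
#   $training  logical; controls caching for backprop and batchnorm semantics
#   $forward(x), $backward(dy)
#
# Tensors are plain R arrays with dim (H, W, C, N).  All convolution heavy
# lifting happens in the compiled im2col kernels (src/conv_ops.cpp).
# ---------------------------------------------------------------------------

new_module <- function(class) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$grads <- list()
  self$buffers <- list()
  self$children <- list()
  self$training <- TRUE
  class(self) <- c(class, "nn_module")
  self
}

#' @export
print.nn_module <- function(x, ...) {
  cat("<", class(x)[1], "> ", format(count_parameters(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# broadcast a per-channel vector (length C or C*N) over (H,W,C,N)
bc_ch <- function(v, HW) rep(v, each = HW)

# per-channel reductions over (H,W,N); x flattened array, returns length-C
ch_sum <- function(x, HW, C, N) {
  cs <- .colSums(matrix(x, HW, C * N), HW, C * N)
  if (N == 1L) cs else rowSums(matrix(cs, C, N))
}
# per-(channel, image) sums, returns C x N matrix
cn_sum <- function(x, HW, C, N) {
  matrix(.colSums(matrix(x, HW, C * N), HW, C * N), C, N)
}

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

#' Switch a module (recursively) between training and evaluation mode
#'
#' Training mode enables activation caching for backpropagation and makes
#' batch normalisation use batch statistics; evaluation mode uses the frozen
#' running statistics and is fully deterministic.
#'
#' @param mod an `nn_module`
#' @param on logical; `TRUE` for training mode
#' @return the module, invisibly
#' @export
nn_set_training <- function(mod, on) {
  mod$training <- isTRUE(on)
  for (ch in mod$children) nn_set_training(ch, on)
  invisible(mod)
}

#' Collect all trainable parameters of a module
#'
#' @param mod an `nn_module`
#' @param prefix internal; name prefix for recursion
#' @return named list of numeric arrays; names are dot-separated paths
#' @export
nn_parameters <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params))
    out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  for (cn in names(mod$children))
    out <- c(out, nn_parameters(mod$children[[cn]], paste0(prefix, cn, ".")))
  out
}

#' Collect gradients after a backward pass (same names as [nn_parameters()])
#' @inheritParams nn_parameters
#' @return named list of numeric arrays
#' @export
nn_gradients <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params))
    out[[paste0(prefix, nm)]] <- mod$grads[[nm]]
  for (cn in names(mod$children))
    out <- c(out, nn_gradients(mod$children[[cn]], paste0(prefix, cn, ".")))
  out
}

#' Write a flat named parameter list back into a module
#' @param mod an `nn_module`
#' @param values named list as returned by [nn_parameters()]
#' @export
nn_set_parameters <- function(mod, values, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, nm)
    if (!is.null(values[[key]])) {
      stopifnot(length(values[[key]]) == length(mod$params[[nm]]))
      dim(values[[key]]) <- dim(mod$params[[nm]])
      mod$params[[nm]] <- values[[key]]
    }
  }
  for (cn in names(mod$children))
    nn_set_parameters(mod$children[[cn]], values, paste0(prefix, cn, "."))
  invisible(mod)
}

nn_buffers <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$buffers))
    out[[paste0(prefix, nm)]] <- mod$buffers[[nm]]
  for (cn in names(mod$children))
    out <- c(out, nn_buffers(mod$children[[cn]], paste0(prefix, cn, ".")))
  out
}

nn_set_buffers <- function(mod, values, prefix = "") {
  for (nm in names(mod$buffers)) {
    key <- paste0(prefix, nm)
    if (!is.null(values[[key]])) mod$buffers[[nm]] <- values[[key]]
  }
  for (cn in names(mod$children))
    nn_set_buffers(mod$children[[cn]], values, paste0(prefix, cn, "."))
  invisible(mod)
}

#' Count trainable parameters
#' @param mod an `nn_module`
#' @return integer-valued double: total number of trainable scalars
#' @export
count_parameters <- function(mod) {
  sum(vapply(nn_parameters(mod), length, 0))
}

# --- convolution -----------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      groups = 1L, bias = TRUE) {
  stopifnot(in_ch %% groups == 0L, out_ch %% groups == 0L)
  self <- new_module("nn_conv2d")
  self$in_ch <- in_ch; self$out_ch <- out_ch; self$k <- k
  self$stride <- stride; self$pad <- pad; self$groups <- groups
  fan_in <- k * k * in_ch / groups
  self$params$W <- array(he_init(k * k * (in_ch / groups) * out_ch, fan_in),
                         dim = c(k, k, in_ch / groups, out_ch))
  if (bias) self$params$b <- numeric(out_ch)
  self$forward <- function(x) {
    d <- dim4(x)
    stopifnot(d[3] == self$in_ch)
    if (self$training) { self$x <- x }
    out <- cpp_conv_fwd(x, as.integer(d), self$params$W, self$k,
                        self$out_ch, self$stride, self$pad, self$groups)
    if (!is.null(self$params$b)) {
      do <- dim(out)
      out <- out + bc_ch(self$params$b, do[1] * do[2])
      dim(out) <- do
    }
    out
  }
  self$backward <- function(dy) {
    d <- dim4(self$x); dd <- dim4(dy)
    self$grads$W <- cpp_conv_bwd_weight(self$x, as.integer(d), dy,
                                        as.integer(dd), self$k,
                                        self$stride, self$pad, self$groups)
    if (!is.null(self$params$b))
      self$grads$b <- ch_sum(dy, dd[1] * dd[2], dd[3], dd[4])
    cpp_conv_bwd_input(dy, as.integer(dd), self$params$W, self$k,
                       self$in_ch, d[1], d[2], self$stride, self$pad,
                       self$groups)
  }
  self
}

# Transposed convolution; weight kept in "conv layout" (k, k, out_ch, in_ch)
# so forward = conv_bwd_input, backward-input = conv_fwd.
nn_conv_transpose2d <- function(in_ch, out_ch, k = 4L, stride = 2L,
                                pad = 1L, bias = TRUE) {
  self <- new_module("nn_conv_transpose2d")
  self$in_ch <- in_ch; self$out_ch <- out_ch; self$k <- k
  self$stride <- stride; self$pad <- pad
  self$params$W <- array(he_init(k * k * out_ch * in_ch, k * k * out_ch),
                         dim = c(k, k, out_ch, in_ch))
  if (bias) self$params$b <- numeric(out_ch)
  self$forward <- function(x) {
    d <- dim4(x)
    stopifnot(d[3] == self$in_ch)
    if (self$training) { self$x <- x }
    Ho <- (d[1] - 1L) * self$stride - 2L * self$pad + self$k
    Wo <- (d[2] - 1L) * self$stride - 2L * self$pad + self$k
    out <- cpp_conv_bwd_input(x, as.integer(d), self$params$W, self$k,
                              self$out_ch, Ho, Wo, self$stride, self$pad, 1L)
    if (!is.null(self$params$b)) {
      do <- dim(out)
      out <- out + bc_ch(self$params$b, do[1] * do[2])
      dim(out) <- do
    }
    out
  }
  self$backward <- function(dy) {
    d <- dim4(self$x); dd <- dim4(dy)
    # roles swap: the transposed conv's output plays the conv input
    self$grads$W <- cpp_conv_bwd_weight(dy, as.integer(dd), self$x,
                                        as.integer(d), self$k,
                                        self$stride, self$pad, 1L)
    if (!is.null(self$params$b))
      self$grads$b <- ch_sum(dy, dd[1] * dd[2], dd[3], dd[4])
    cpp_conv_fwd(dy, as.integer(dd), self$params$W, self$k, self$in_ch,
                 self$stride, self$pad, 1L)
  }
  self
}

# --- batch normalisation ---------------------------------------------------

nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  self <- new_module("nn_batchnorm2d")
  self$ch <- ch; self$eps <- eps; self$momentum <- momentum
  self$params$gamma <- rep(1, ch)
  self$params$beta <- rep(0, ch)
  self$buffers$running_mean <- rep(0, ch)
  self$buffers$running_var <- rep(1, ch)
  self$forward <- function(x) {
    d <- dim4(x)
    stopifnot(d[3] == self$ch)
    HW <- d[1] * d[2]; m <- HW * d[4]
    if (self$training) {
      mu <- ch_sum(x, HW, d[3], d[4]) / m
      xc <- x - bc_ch(mu, HW)
      v <- ch_sum(xc * xc, HW, d[3], d[4]) / m
      self$buffers$running_mean <-
        (1 - self$momentum) * self$buffers$running_mean + self$momentum * mu
      vu <- if (m > 1) v * m / (m - 1) else v
      self$buffers$running_var <-
        (1 - self$momentum) * self$buffers$running_var + self$momentum * vu
      invstd <- 1 / sqrt(v + self$eps)
      xhat <- xc * bc_ch(invstd, HW)
      self$xhat <- xhat; self$invstd <- invstd; self$m <- m; self$d <- d
    } else {
      invstd <- 1 / sqrt(self$buffers$running_var + self$eps)
      xhat <- (x - bc_ch(self$buffers$running_mean, HW)) * bc_ch(invstd, HW)
    }
    out <- xhat * bc_ch(self$params$gamma, HW) + bc_ch(self$params$beta, HW)
    dim(out) <- d
    out
  }
  self$backward <- function(dy) {
    d <- self$d; HW <- d[1] * d[2]; m <- self$m
    dgamma <- ch_sum(dy * self$xhat, HW, d[3], d[4])
    dbeta <- ch_sum(dy, HW, d[3], d[4])
    self$grads$gamma <- dgamma
    self$grads$beta <- dbeta
    dx <- (bc_ch(self$params$gamma * self$invstd / m, HW)) *
      (m * dy - bc_ch(dbeta, HW) - self$xhat * bc_ch(dgamma, HW))
    dim(dx) <- d
    dx
  }
  self
}

# --- activations & pooling -------------------------------------------------

nn_relu <- function() {
  self <- new_module("nn_relu")
  self$forward <- function(x) {
    out <- x * (x > 0)
    if (self$training) self$mask <- x > 0
    out
  }
  self$backward <- function(dy) dy * self$mask
  self
}

nn_sigmoid <- function() {
  self <- new_module("nn_sigmoid")
  self$forward <- function(x) {
    out <- 1 / (1 + exp(-x))
    if (self$training) self$out <- out
    out
  }
  self$backward <- function(dy) dy * self$out * (1 - self$out)
  self
}

nn_maxpool2d <- function(k = 3L, stride = 2L, pad = 1L) {
  self <- new_module("nn_maxpool2d")
  self$k <- k; self$stride <- stride; self$pad <- pad
  self$forward <- function(x) {
    d <- dim4(x)
    r <- cpp_maxpool_fwd(x, as.integer(d), self$k, self$stride, self$pad)
    if (self$training) { self$idx <- r$idx; self$xdim <- d }
    r$out
  }
  self$backward <- function(dy) {
    cpp_maxpool_bwd(dy, self$idx, prod(self$xdim), as.integer(self$xdim))
  }
  self
}

# --- linear (used inside squeeze-excitation) -------------------------------

nn_linear <- function(in_f, out_f) {
  self <- new_module("nn_linear")
  self$params$W <- matrix(he_init(out_f * in_f, in_f), out_f, in_f)
  self$params$b <- numeric(out_f)
  self$forward <- function(z) {          # z: in_f x batch
    if (self$training) self$z <- z
    self$params$W %*% z + self$params$b
  }
  self$backward <- function(dy) {
    self$grads$W <- dy %*% t(self$z)
    self$grads$b <- rowSums(dy)
    t(self$params$W) %*% dy
  }
  self
}

# --- squeeze-excitation channel attention ----------------------------------

# SEWeight: global average pool -> bottleneck MLP (reduction r) -> sigmoid.
# Returns the per-channel weight vector (ch x N) without applying it, so it
# serves both the plain SE block and the pyramid-split-attention softmax.
nn_se_weight <- function(ch, reduction = 16L) {
  hidden <- ch %/% reduction
  if (hidden < 1L)
    stop("SEWeight: ", ch, " channels with reduction ", reduction,
         " would produce zero hidden units", call. = FALSE)
  self <- new_module("nn_se_weight")
  self$ch <- ch
  self$children$fc1 <- nn_linear(ch, hidden)
  # small positive bias keeps the bottleneck units initially active for the
  # nonnegative pooled descriptors (guards against dead ReLUs at low width)
  self$children$fc1$params$b <- rep(0.1, hidden)
  self$children$fc2 <- nn_linear(hidden, ch)
  self$forward <- function(x) {
    d <- dim4(x); HW <- d[1] * d[2]
    z <- cn_sum(x, HW, d[3], d[4]) / HW            # ch x N descriptor
    self$last_pooled <- z
    h <- self$children$fc1$forward(z)
    s <- 1 / (1 + exp(-self$children$fc2$forward(h * (h > 0))))
    if (self$training) { self$s <- s; self$hmask <- h > 0; self$d <- d }
    s
  }
  # gradient wrt the input feature map given ds (ch x N)
  self$backward <- function(ds) {
    d <- self$d; HW <- d[1] * d[2]
    dlogit <- ds * self$s * (1 - self$s)
    dh <- self$children$fc2$backward(dlogit) * self$hmask
    dz <- self$children$fc1$backward(dh)
    dx <- array(bc_ch(as.vector(dz), HW) / HW, dim = d)
    dx
  }
  self
}

# SE block proper: compute the weight vector and rescale the input by it.
nn_se_block <- function(ch, reduction = 16L) {
  self <- new_module("nn_se_block")
  self$ch <- ch
  self$children$sw <- nn_se_weight(ch, reduction)
  self$forward <- function(x) {
    d <- dim4(x); HW <- d[1] * d[2]
    s <- self$children$sw$forward(x)
    self$last_weights <- s
    if (self$training) { self$x <- x; self$s <- s; self$d <- d }
    out <- x * bc_ch(as.vector(s), HW)
    dim(out) <- d
    out
  }
  self$backward <- function(dy) {
    d <- self$d; HW <- d[1] * d[2]
    dx <- dy * bc_ch(as.vector(self$s), HW)
    ds <- cn_sum(dy * self$x, HW, d[3], d[4])      # ch x N
    dx <- dx + self$children$sw$backward(ds)
    dim(dx) <- d
    dx
  }
  self
}

# --- sequential container --------------------------------------------------

nn_sequential <- function(...) {
  self <- new_module("nn_sequential")
  mods <- list(...)
  if (is.null(names(mods)) || any(names(mods) == ""))
    names(mods) <- paste0("m", seq_along(mods))
  self$children <- mods
  self$forward <- function(x) {
    for (ch in self$children) x <- ch$forward(x)
    x
  }
  self$backward <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$backward(dy)
    dy
  }
  self
}
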