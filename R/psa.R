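# Pyramid split attention (PSA) bridge between the encoder bottleneck and
# the decoder.  The bottleneck is channel-split into groups, each group is
# convolved at its own kernel scale (with its own group-convolution count),
# per-group SEWeight attention vectors are renormalised with a softmax
# across the group axis at every channel position, and the re-weighted
# groups are concatenated back.

#' Configuration for the pyramid split attention module
#'
#' Defaults follow the four-branch pyramid used on a 512-channel bottleneck:
#' 4 groups of 128 channels, kernel sizes 3/5/7/9, group-convolution counts
#' 1/4/8/16, squeeze-excitation reduction 16. Kernel sizes must be odd so
#' that same-padding is symmetric; the even kernel occasionally quoted for
#' the fourth branch is therefore not accepted as a default (see the methods
#' vignette) but any odd pyramid can be configured here.
#'
#' @param n_groups number of channel groups
#' @param group_channels channels per group; `n_groups * group_channels`
#'   must equal the channel count of the feature map the module is applied to
#' @param kernel_sizes odd convolution kernel size per group
#' @param conv_groups group-convolution count per group; each must divide
#'   `group_channels`
#' @param se_reduction reduction ratio of the SEWeight bottleneck MLP
#' @return a `psa_config` list
#' @examples
#' psa_config()                          # the 512-channel default
#' psa_config(group_channels = 32)      # quarter-width variant
#' @export
psa_config <- function(n_groups = 4L, group_channels = 128L,
                       kernel_sizes = c(3L, 5L, 7L, 9L),
                       conv_groups = c(1L, 4L, 8L, 16L),
                       se_reduction = 16L) {
  cfg <- list(n_groups = as.integer(n_groups),
              group_channels = as.integer(group_channels),
              kernel_sizes = as.integer(kernel_sizes),
              conv_groups = as.integer(conv_groups),
              se_reduction = as.integer(se_reduction))
  if (length(cfg$kernel_sizes) != cfg$n_groups ||
      length(cfg$conv_groups) != cfg$n_groups)
    stop("kernel_sizes and conv_groups must have one entry per group")
  if (any(cfg$kernel_sizes %% 2L == 0L))
    stop("every PSA kernel size must be odd for symmetric same-padding; ",
         "got ", paste(cfg$kernel_sizes, collapse = ", "))
  if (any(cfg$group_channels %% cfg$conv_groups != 0L))
    stop("every conv_groups value must divide group_channels (",
         cfg$group_channels, ")")
  if (cfg$group_channels %/% cfg$se_reduction < 1L)
    stop("group_channels < se_reduction: SEWeight would have no hidden units")
  structure(cfg, class = "psa_config")
}

# the trainable PSA module
nn_psa <- function(cfg) {
  stopifnot(inherits(cfg, "psa_config"))
  self <- new_module("nn_psa")
  self$cfg <- cfg
  gc <- cfg$group_channels
  for (g in seq_len(cfg$n_groups)) {
    k <- cfg$kernel_sizes[g]
    self$children[[paste0("conv", g)]] <-
      nn_conv2d(gc, gc, k, pad = (k - 1L) %/% 2L,
                groups = cfg$conv_groups[g], bias = FALSE)
    self$children[[paste0("se", g)]] <- nn_se_weight(gc, cfg$se_reduction)
  }
  self$forward <- function(x) {
    cfg <- self$cfg; gc <- cfg$group_channels; G <- cfg$n_groups
    d <- dim4(x)
    if (d[3] != G * gc)
      stop("PSA expects ", G * gc, " channels (", G, " groups x ", gc,
           "), got ", d[3], call. = FALSE)
    HW <- d[1] * d[2]
    ys <- vector("list", G)
    V <- array(0, c(gc, d[4], G))                 # pre-softmax SE weights
    for (g in seq_len(G)) {
      xg <- x[, , ((g - 1L) * gc + 1L):(g * gc), , drop = FALSE]
      ys[[g]] <- self$children[[paste0("conv", g)]]$forward(xg)
      V[, , g] <- self$children[[paste0("se", g)]]$forward(ys[[g]])
    }
    E <- exp(V - apply(V, c(1, 2), max)[rep(seq_len(gc * d[4]), G)])
    dim(E) <- dim(V)
    A <- E / as.vector(apply(E, c(1, 2), sum))    # softmax over group axis
    self$pre_softmax <- V
    self$post_softmax <- A
    out <- array(0, c(d[1], d[2], G * gc, d[4]))
    for (g in seq_len(G)) {
      og <- ys[[g]] * bc_ch(as.vector(A[, , g]), HW)
      out[, , ((g - 1L) * gc + 1L):(g * gc), ] <- og
    }
    if (self$training) { self$ys <- ys; self$A <- A; self$d <- d }
    out
  }
  self$backward <- function(dy) {
    cfg <- self$cfg; gc <- cfg$group_channels; G <- cfg$n_groups
    d <- self$d; HW <- d[1] * d[2]
    A <- self$A
    dA <- array(0, dim(A))
    dys <- vector("list", G)
    for (g in seq_len(G)) {
      dyg <- dy[, , ((g - 1L) * gc + 1L):(g * gc), , drop = FALSE]
      dys[[g]] <- dyg * bc_ch(as.vector(A[, , g]), HW)
      dA[, , g] <- cn_sum(dyg * self$ys[[g]], HW, gc, d[4])
    }
    # softmax backward per (channel, image): dV_g = A_g * (dA_g - sum A dA)
    S <- apply(dA * A, c(1, 2), sum)
    dV <- A * (dA - as.vector(S))
    dx <- array(0, d)
    for (g in seq_len(G)) {
      dyg <- dys[[g]] +
        self$children[[paste0("se", g)]]$backward(dV[, , g, drop = TRUE])
      dx[, , ((g - 1L) * gc + 1L):(g * gc), ] <-
        self$children[[paste0("conv", g)]]$backward(dyg)
    }
    dx
  }
  self
}

#' Build a standalone pyramid split attention module
#'
#' @param cfg a [psa_config()]
#' @param seed integer seed for weight initialisation
#' @return an `nn_module` of class `nn_psa`
#' @export
build_psa <- function(cfg = psa_config(), seed = 1L) {
  set.seed(seed)
  nn_set_training(nn_psa(cfg), FALSE)
}

#' Apply a pyramid split attention module to a feature map
#'
#' Output shape always equals input shape. The pre- and post-softmax group
#' attention weights of the call are retrievable with [psa_attention()].
#'
#' @param psa a module from [build_psa()] (or the `psa` child of an
#'   assembled network)
#' @param feature `(H, W, C, N)` array (or 3-D single image) with
#'   `C = n_groups * group_channels`
#' @return array of the same shape as `feature`
#' @export
psa_forward <- function(psa, feature) {
  stopifnot(inherits(psa, "nn_psa"))
  psa$forward(as_batch(feature))
}

#' Retrieve the group-attention weights of the most recent PSA forward pass
#'
#' @param psa an `nn_psa` module that has run at least one forward pass
#' @return list with `pre_softmax` and `post_softmax`, each a
#'   `(group_channels, batch, n_groups)` array; summing `post_softmax` over
#'   its third axis gives 1 at every position
#' @export
psa_attention <- function(psa) {
  stopifnot(inherits(psa, "nn_psa"))
  if (is.null(psa$post_softmax))
    stop("no forward pass has been run yet")
  list(pre_softmax = psa$pre_softmax, post_softmax = psa$post_softmax)
}

#' Per-channel SEWeight attention vector
#'
#' Global average pool, bottleneck linear layer (reduction `reduction`),
#' ReLU, linear layer, sigmoid. Every returned weight is strictly in (0, 1).
#'
#' @param se an `nn_se_weight` module (e.g. a `se*` child of an `nn_psa`)
#' @param feature `(H, W, C, N)` array or 3-D single image
#' @return `C x N` matrix of weights in (0, 1)
#' @export
se_weight <- function(se, feature) {
  stopifnot(inherits(se, "nn_se_weight"))
  se$forward(as_batch(feature))
}

#' @rdname se_weight
#' @param channels channel count of the feature the module will be applied to
#' @param reduction bottleneck reduction ratio
#' @param seed integer seed for weight initialisation
#' @export
build_se_weight <- function(channels, reduction = 16L, seed = 1L) {
  set.seed(seed)
  nn_set_training(nn_se_weight(channels, reduction), FALSE)
}
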