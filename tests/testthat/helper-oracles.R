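# Independent oracles and small builders shared across tests.

# direct-convolution oracle: nested loops, zero padding
naive_conv <- function(x, w, b, stride, pad, groups) {
  d <- dim(x); k <- dim(w)[1]; cin <- d[3]; cout <- dim(w)[4]
  Cg <- cin / groups; Og <- cout / groups
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, cout, d[4]))
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, cin, d[4]))
  xp[pad + 1:d[1], pad + 1:d[2], , ] <- x
  for (n in 1:d[4]) for (co in 1:cout) {
    g <- (co - 1) %/% Og
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- 0
      for (ci in 1:Cg) for (kh in 1:k) for (kw in 1:k)
        acc <- acc + xp[(ho - 1) * stride + kh, (wo - 1) * stride + kw,
                        g * Cg + ci, n] * w[kh, kw, ci, co]
      out[ho, wo, co, n] <- acc + b[co]
    }
  }
  out
}

# central-difference gradient of a scalar function at selected indices
fd_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

# pixel-loop confusion counts + metric formulas, written independently of
# the package implementation
naive_counts <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

naive_metrics <- function(pred, truth) {
  cc <- naive_counts(pred, truth)
  with(cc, list(
    dc = 2 * tp / (2 * tp + fp + fn),
    ir = tp / (tp + fp + fn),
    rec = tp / (tp + fn),
    spec = tn / (tn + fp),
    prec = tp / (tp + fp),
    ioub = tn / (tn + fp + fn),
    ac = (tp + tn) / (tp + fp + fn + tn)))
}

# AUC oracle by pairwise concordance enumeration (Mann-Whitney identity)
naive_auc <- function(prob, truth) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# layer-by-layer parameter formula for the encoder (batch-norm has 2
# trainable scalars per channel; convs before BN carry no bias)
resnet34_expected_params <- function(w = 64) {
  block <- function(ic, oc, proj) {
    9 * ic * oc + 2 * oc + 9 * oc * oc + 2 * oc +
      if (proj) ic * oc + 2 * oc else 0
  }
  stage <- function(n, ic, oc, proj1) {
    block(ic, oc, proj1) + (n - 1) * block(oc, oc, FALSE)
  }
  7 * 7 * 3 * w + 2 * w +
    stage(3, w, w, FALSE) +
    stage(4, w, 2 * w, TRUE) +
    stage(6, 2 * w, 4 * w, TRUE) +
    stage(3, 4 * w, 8 * w, TRUE)
}

# small reduced-width model used by several tests
tiny_model <- function(seed = 5, size = c(32L, 32L), ...) {
  assemble_mhanet(model_config(width_mult = 0.25, input_size = size,
                               seed = seed, ...))
}

# small easy synthetic set
tiny_blobs <- function(n, seed = 101, size = c(64L, 64L)) {
  generate_dataset(synthetic_spec(size, "polyp"), n, seed)
}
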