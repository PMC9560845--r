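# Metric implementations against brute-force pixel-loop oracles and the
# algebraic identities linking them.

test_that("confusion counts match brute-force enumeration on the 10x10 toy", {
  truth <- matrix(0L, 10, 10)
  truth[1, 1:5] <- 1L                      # 5 true pixels
  pred <- matrix(0L, 10, 10)
  pred[1, 1:3] <- 1L                       # covers 3 of them
  pred[5, 5] <- 1L                         # plus 1 background pixel
  cc <- confusion_counts(pred, truth)
  nc <- naive_counts(pred, truth)
  expect_identical(cc$tp, nc$tp)
  expect_identical(unclass(cc), nc[c("tp", "fp", "fn", "tn")])
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(3L, 1L, 2L, 94L))
  expect_equal(dice(cc), 2 / 3)
  expect_equal(iou_poly(cc), 0.5)
  r <- metric_report(pred, truth)
  expect_equal(r$rec, 0.6)
  expect_equal(r$prec, 0.75)
  expect_equal(r$spec, 94 / 95)
  expect_equal(r$ioub, 94 / 97)
  expect_equal(r$ac, 0.97)
})

test_that("identity and complement masks hit the metric extremes", {
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  while (sum(m) == 0 || sum(m) == 64) m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  same <- confusion_counts(m, m)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  expect_equal(dice(same), 1)
  comp <- confusion_counts(1L - m, m)
  expect_identical(c(comp$tp, comp$tn), c(0L, 0L))
  expect_equal(dice(comp), 0)
  expect_equal(iou_poly(comp), 0)
})

test_that("inputs are validated", {
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 2, 3)),
               "identical shapes")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
  expect_error(metric_report(matrix(1.2, 2, 2), matrix(1, 2, 2)),
               "\\[0, 1\\]")
})

test_that("empty-vs-empty comparison warns and reports perfect agreement", {
  z <- matrix(0L, 4, 4)
  expect_warning(d <- dice(confusion_counts(z, z)), "degenerate")
  expect_equal(d, 1)
})

test_that("all metrics equal the pixel-loop oracle on random mask pairs", {
  set.seed(77)
  for (i in 1:200) {
    H <- sample(2:32, 1); W <- sample(2:32, 1)
    truth <- matrix(rbinom(H * W, 1, runif(1, 0.1, 0.9)), H, W)
    pred <- matrix(rbinom(H * W, 1, runif(1, 0.1, 0.9)), H, W)
    got <- suppressWarnings(metric_report(pred, truth))
    want <- naive_metrics(pred, truth)
    for (nm in names(want)) {
      if (!is.finite(want[[nm]])) next   # 0/0 denominators use conventions
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12,
                   label = paste("iter", i, nm))
    }
    # Dice-Jaccard identity and the mean-IoU identity
    expect_equal(got$dc, 2 * got$ir / (1 + got$ir), tolerance = 1e-12)
    expect_equal(got$miou, (got$ioup + got$ioub) / 2, tolerance = 1e-15)
    # symmetry of Dice; recall/precision swap under argument exchange
    fwd <- confusion_counts(pred, truth)
    rev <- confusion_counts(truth, pred)
    expect_equal(suppressWarnings(dice(fwd)), suppressWarnings(dice(rev)))
    expect_identical(c(fwd$fp, fwd$fn), c(rev$fn, rev$fp))
  }
})

test_that("AUC reproduces hand-enumerated and limiting cases", {
  expect_equal(auc_score(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  # perfectly separating probabilities
  expect_equal(auc_score(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # constant probabilities are chance level
  expect_equal(auc_score(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_score(runif(5), rep(1, 5)), "single class")
})

test_that("AUC equals pairwise concordance enumeration on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    if (sum(truth) %in% c(0, n)) next
    prob <- round(runif(n), 2)             # coarse grid forces ties
    expect_equal(auc_score(prob, truth), naive_auc(prob, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  truth <- rbinom(400, 1, 0.3)
  prob <- pmin(pmax(truth * 0.4 + runif(400, 0, 0.6), 0), 1)
  want <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auc_score(prob, truth), want, tolerance = 1e-10)
})

test_that("a perfect predictor scores 1 everywhere in the report", {
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  while (sum(truth) %in% c(0, 100)) truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  r <- metric_report(truth + 0, truth)
  expect_true(all(unlist(r) == 1))
})

test_that("report writer emits CSV and JSON", {
  per <- data.frame(image = c("a", "b"), dc = c(0.5, 0.7), ir = c(0.4, 0.6),
                    rec = 1, spec = 1, prec = 1, ioup = c(0.4, 0.6),
                    ioub = 1, miou = 1, ac = 1, se = 1, auc = 1)
  agg <- structure(as.list(colMeans(per[-1])), class = "metric_report")
  d <- tempfile(); dir.create(d)
  paths <- write_metric_report(per, agg, file.path(d, "m"))
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[["json"]])
  expect_equal(back$aggregate$dc, 0.6)
  expect_identical(nrow(utils::read.csv(paths[["csv"]])), 3L)
})
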