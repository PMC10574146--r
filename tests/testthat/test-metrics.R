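test_that("confusion matrix matches a per-pixel loop oracle", {
  set.seed(11)
  pred <- matrix(sample(1:4, 2500, TRUE), 50, 50)
  truth <- matrix(sample(1:4, 2500, TRUE), 50, 50)
  cm <- confusion_matrix(pred, truth)
  expect_equal(unclass(cm), oracle_confusion(pred, truth),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 2500)

  # hand-counted 2x2 example
  cm2 <- confusion_matrix(matrix(c(1, 2, 2, 2), 2),
                          matrix(c(1, 1, 2, 2), 2))
  expect_equal(cm2[1, 1], 1)
  expect_equal(cm2[2, 1], 1)
  expect_equal(cm2[2, 2], 2)

  # perfect prediction is diagonal
  cmd <- confusion_matrix(truth, truth)
  expect_true(all(cmd[row(cmd) != col(cmd)] == 0))

  expect_error(confusion_matrix(pred[1:10, ], truth), "shape")
  expect_error(confusion_matrix(pred + 4L, truth), "1..4")
})

test_that("dataset accumulation equals the summed confusion matrix", {
  set.seed(12)
  preds <- lapply(1:5, function(i) matrix(sample(1:4, 100, TRUE), 10))
  truths <- lapply(1:5, function(i) matrix(sample(1:4, 100, TRUE), 10))
  cms <- Map(confusion_matrix, preds, truths)
  total <- accumulate_confusion(cms)
  big <- confusion_matrix(do.call(rbind, preds), do.call(rbind, truths))
  expect_equal(unclass(total), unclass(big))
  g1 <- glance(metric_report(total))
  g2 <- glance(metric_report(big))
  expect_equal(g1, g2)
})

test_that("class prevalence sums to one and matches raw labels", {
  expect_equal(unname(class_prevalence(rep(1:4, each = 25))),
               rep(0.25, 4))
  expect_equal(unname(class_prevalence(rep(1:4, c(97, 1, 1, 1)))),
               c(0.97, 0.01, 0.01, 0.01))
  set.seed(13)
  lab <- sample(1:4, 400, TRUE, prob = c(0.5, 0.3, 0.1, 0.1))
  cm <- confusion_matrix(sample(1:4, 400, TRUE), lab)
  expect_equal(unname(class_prevalence(cm)),
               unname(class_prevalence(lab)))
  expect_error(class_prevalence(integer()), "empty")
})

test_that("weighted metrics and kappa match brute-force oracles", {
  for (seed in 1:20) {
    cm <- random_cm(seed)
    o <- oracle_metrics(unclass(cm))
    wm <- weighted_metrics(cm)
    kp <- kappa(cm)
    expect_equal(wm$WPA, o$WPA, tolerance = 1e-12)
    expect_equal(wm$WRE, o$WRE, tolerance = 1e-12)
    expect_equal(wm$WF1, o$WF1, tolerance = 1e-12)
    expect_equal(wm$WIoU, o$WIoU, tolerance = 1e-12)
    expect_equal(kp$WKs, o$WKs, tolerance = 1e-12)
    expect_equal(kp$Po, o$Po, tolerance = 1e-12)
    expect_equal(kp$Pe, o$Pe, tolerance = 1e-12)
  }
})

test_that("perfect and chance-level matrices hit the metric extremes", {
  perfect <- structure(diag(c(30, 20, 25, 25)),
                       class = c("confusion_matrix", "matrix", "array"))
  g <- glance(metric_report(perfect))
  expect_equal(unlist(g[c("WPA", "WRE", "WF1", "WIoU", "WKs")]),
               c(WPA = 1, WRE = 1, WF1 = 1, WIoU = 1, WKs = 1))
  expect_equal(g$band, "almost perfect")

  uniform <- structure(matrix(25, 2, 2),
                       class = c("confusion_matrix", "matrix", "array"))
  expect_equal(kappa(uniform)$WKs, 0)
})

test_that("metrics are invariant to a consistent class permutation", {
  set.seed(14)
  pred <- matrix(sample(1:4, 900, TRUE), 30)
  truth <- matrix(sample(1:4, 900, TRUE), 30)
  perm <- c(3L, 1L, 4L, 2L)
  g1 <- glance(metric_report(confusion_matrix(pred, truth)))
  g2 <- glance(metric_report(confusion_matrix(
    matrix(perm[pred], 30), matrix(perm[truth], 30))))
  expect_equal(g1, g2)
})

test_that("WIoU never exceeds WF1", {
  for (seed in 21:40) {
    wm <- weighted_metrics(random_cm(seed))
    expect_lte(wm$WIoU, wm$WF1 + 1e-12)
  }
})

test_that("empty-denominator classes contribute zero with a warning", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 50
  m[2, 2] <- 30
  m[1, 2] <- 5
  # classes 3 and 4 absent from predictions and truth
  cm <- structure(m, class = c("confusion_matrix", "matrix", "array"))
  wm <- weighted_metrics(cm)
  expect_equal(wm$precision[3:4], c(0, 0))
  expect_equal(wm$pi[3:4], c(0, 0), ignore_attr = TRUE)
  expect_gt(wm$WPA, 0.9)
  expect_error(weighted_metrics(
    structure(matrix(0, 4, 4),
              class = c("confusion_matrix", "matrix", "array"))),
    "no pixels")
})

test_that("macro averaging and the printed kappa variant stay available", {
  cm <- random_cm(99)
  wm_w <- weighted_metrics(cm, average = "weighted")
  wm_m <- weighted_metrics(cm, average = "macro")
  expect_equal(wm_m$WPA, mean(wm_m$precision))
  expect_false(isTRUE(all.equal(wm_w$WPA, wm_m$WPA)))
  kp <- kappa(cm, denominator = "pe")
  kpo <- kappa(cm, denominator = "po")
  expect_equal(kpo$WKs, (kp$Po - kp$Pe) / (1 - kp$Po))
})

test_that("kappa bands follow the five intervals with closed upper edges", {
  expect_equal(mtpi:::kappa_band(0.20), "slight")
  expect_equal(mtpi:::kappa_band(0.40), "fair")
  expect_equal(mtpi:::kappa_band(0.405), "moderate")
  expect_equal(mtpi:::kappa_band(0.60), "moderate")
  expect_equal(mtpi:::kappa_band(0.80), "substantial")
  expect_equal(mtpi:::kappa_band(0.81), "almost perfect")
})

test_that("report writers emit JSON and CSV", {
  dir <- withr::local_tempdir()
  rep <- metric_report(random_cm(5))
  path <- write_metric_report(rep, file.path(dir, "rep"))
  js <- jsonlite::read_json(path)
  expect_equal(js$WKs, rep$WKs, tolerance = 1e-9)
  csv <- utils::read.csv(file.path(dir, "rep.csv"))
  expect_equal(nrow(csv), 4)
})
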