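#' Pixel confusion matrix
#'
#' Entry (r, c) counts pixels of true class c predicted as class r. Matrices
#' from different samples accumulate by elementwise addition (see
#' [accumulate_confusion()]), and every weighted metric of a dataset equals
#' the metric of the summed matrix.
#'
#' @param pred,truth Integer class maps of identical shape, values in 1..C.
#' @param n_classes Number of classes C (default 4).
#' @return A C x C `confusion_matrix` (rows = predicted, cols = true).
#' @export
confusion_matrix <- function(pred, truth, n_classes = 4L) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    abort("`pred` and `truth` must have identical shape.")
  }
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (anyNA(p) || anyNA(t) || any(p < 1L) || any(p > n_classes) ||
      any(t < 1L) || any(t > n_classes)) {
    abort(sprintf("class values must lie in 1..%d.", n_classes))
  }
  counts <- tabulate(p + n_classes * (t - 1L), nbins = n_classes^2)
  m <- matrix(counts, n_classes, n_classes)
  cls <- rownames(vegetation_palette())[seq_len(n_classes)]
  dimnames(m) <- list(predicted = cls, true = cls)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @rdname confusion_matrix
#' @param cms A list of `confusion_matrix` objects.
#' @export
accumulate_confusion <- function(cms) {
  out <- Reduce(`+`, lapply(cms, unclass))
  structure(out, class = c("confusion_matrix", "matrix", "array"))
}

# Per-class one-vs-rest counts derived from a confusion matrix.
cm_class_counts <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  tpp <- diag(cm)
  fpp <- rowSums(cm) - tpp
  fnp <- colSums(cm) - tpp
  tnp <- total - tpp - fpp - fnp
  list(tpp = tpp, fpp = fpp, fnp = fnp, tnp = tnp, total = total)
}

#' Class prevalence weights
#'
#' The weight of class i is its share of true pixels, so the weights sum
#' to 1. Accepts a confusion matrix or a raw label map/vector.
#'
#' @param x A `confusion_matrix`, or an integer label map.
#' @param n_classes Number of classes when `x` is a label map.
#' @return A numeric weight vector summing to 1.
#' @export
class_prevalence <- function(x, n_classes = 4L) {
  if (inherits(x, "confusion_matrix")) {
    cs <- colSums(unclass(x))
    if (sum(cs) == 0) abort("empty confusion matrix.")
    return(cs / sum(cs))
  }
  v <- as.integer(x)
  if (length(v) == 0L) abort("empty label input.")
  counts <- tabulate(v, nbins = n_classes)
  setNames(counts / sum(counts), rownames(vegetation_palette())[1:n_classes])
}

#' Weighted segmentation metrics
#'
#' Prevalence-weighted pixel precision (WPA), recall (WRE), F1 (WF1) and
#' IoU (WIoU): each per-class quantity is combined with weights equal to
#' the class's true-pixel share. A class whose denominator is empty
#' contributes zero (with a warning) rather than NaN. `average = "macro"`
#' replaces the prevalence weights with uniform 1/C weights.
#'
#' @param cm A `confusion_matrix` with at least one pixel.
#' @param average `"weighted"` (prevalence weights, default) or `"macro"`.
#' @return A named list with `WPA`, `WRE`, `WF1`, `WIoU`, the per-class
#'   `precision`, `recall`, `f1`, `iou`, and the weights `pi`.
#' @export
weighted_metrics <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  cc <- cm_class_counts(cm)
  if (cc$total == 0) abort("confusion matrix has no pixels.")
  C <- length(cc$tpp)
  pi <- if (average == "weighted") {
    class_prevalence(cm)
  } else {
    rep(1 / C, C)
  }
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    ok <- den > 0
    out[ok] <- num[ok] / den[ok]
    if (any(!ok & pi > 0)) {
      warn(sprintf("class with empty %s denominator contributes 0.", what))
    }
    out
  }
  precision <- safe_div(cc$tpp, cc$tpp + cc$fpp, "precision")
  recall <- safe_div(cc$tpp, cc$tpp + cc$fnp, "recall")
  pr <- precision + recall
  f1 <- numeric(C)
  f1[pr > 0] <- 2 * precision[pr > 0] * recall[pr > 0] / pr[pr > 0]
  iou <- safe_div(cc$tpp, cc$tpp + cc$fpp + cc$fnp, "IoU")
  list(
    WPA = sum(pi * precision),
    WRE = sum(pi * recall),
    WF1 = sum(pi * f1),
    WIoU = sum(pi * iou),
    precision = precision, recall = recall, f1 = f1, iou = iou, pi = pi
  )
}

#' Weighted Cohen kappa
#'
#' Chance-corrected pixel agreement: Po is the observed agreement
#' (trace/total), Pe the expected agreement of independent raters with the
#' observed marginals, and WKs = (Po - Pe) / (1 - Pe). The consistency band
#' follows the conventional five intervals (<=0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1 almost perfect), with
#' boundary values assigned to the lower band. `denominator = "po"` selects
#' the nonstandard (Po - Pe)/(1 - Po) variant.
#'
#' @param cm A `confusion_matrix`.
#' @param denominator `"pe"` (Cohen, default) or `"po"`.
#' @return A list with `WKs`, `Po`, `Pe`, and `band`.
#' @export
kappa <- function(cm, denominator = c("pe", "po")) {
  denominator <- match.arg(denominator)
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) abort("confusion matrix has no pixels.")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  den <- if (denominator == "pe") 1 - pe else 1 - po
  if (abs(den) < 1e-12) {
    warn("degenerate confusion matrix (denominator ~ 0); WKs set to 0.")
    wks <- 0
  } else {
    wks <- (po - pe) / den
  }
  list(WKs = wks, Po = po, Pe = pe, band = kappa_band(wks))
}

kappa_band <- function(wks) {
  if (wks <= 0.20) "slight"
  else if (wks <= 0.40) "fair"
  else if (wks <= 0.60) "moderate"
  else if (wks <= 0.80) "substantial"
  else "almost perfect"
}

#' Full metric report
#'
#' Computes all five weighted metrics plus kappa intermediates for a
#' confusion matrix or an accumulated set of predictions.
#'
#' @param cm A `confusion_matrix`.
#' @inheritParams weighted_metrics
#' @inheritParams kappa
#' @return A `metric_report` object.
#' @export
metric_report <- function(cm, average = "weighted", denominator = "pe") {
  wm <- weighted_metrics(cm, average = average)
  kp <- kappa(cm, denominator = denominator)
  structure(
    list(WPA = wm$WPA, WRE = wm$WRE, WF1 = wm$WF1, WIoU = wm$WIoU,
         WKs = kp$WKs, Po = kp$Po, Pe = kp$Pe, band = kp$band,
         pi = wm$pi, per_class = tibble(
           class = names(wm$pi) %||% as.character(seq_along(wm$pi)),
           pi = as.numeric(wm$pi),
           precision = wm$precision, recall = wm$recall,
           f1 = wm$f1, iou = wm$iou),
         cm = cm),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Weighted segmentation metrics\n")
  cat(sprintf("  WPA  %.4f   WRE %.4f   WF1 %.4f\n", x$WPA, x$WRE, x$WF1))
  cat(sprintf("  WIoU %.4f   WKs %.4f (%s)\n", x$WIoU, x$WKs, x$band))
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) {
  x$per_class
}

#' @export
glance.metric_report <- function(x, ...) {
  tibble(WPA = x$WPA, WRE = x$WRE, WF1 = x$WF1, WIoU = x$WIoU,
         WKs = x$WKs, Po = x$Po, Pe = x$Pe, band = x$band)
}

#' Row-normalised confusion table
#'
#' Percentage view of a confusion matrix: each predicted-class row is
#' normalised to 100%.
#'
#' @param cm A `confusion_matrix`.
#' @return A numeric matrix of percentages.
#' @export
confusion_percent <- function(cm) {
  m <- unclass(cm)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  100 * m / rs
}

#' Write a metric report to JSON and CSV
#'
#' @param report A `metric_report`.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @return The JSON path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  js <- list(
    WPA = report$WPA, WRE = report$WRE, WF1 = report$WF1,
    WIoU = report$WIoU, WKs = report$WKs, Po = report$Po, Pe = report$Pe,
    band = report$band,
    confusion_percent = apply(confusion_percent(report$cm), 1, as.numeric,
                              simplify = FALSE)
  )
  jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(tidy(report), paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}

# Convenience: accumulated metrics of a net over scenes.
scenes_metric_report <- function(net, scenes, ...) {
  scenes <- as_scene_list(scenes)
  cms <- lapply(scenes, function(sc) {
    confusion_matrix(predict_scene(net, sc$image), sc$label)
  })
  metric_report(accumulate_confusion(cms), ...)
}
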