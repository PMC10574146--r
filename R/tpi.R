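#' Feature-probe configuration
#'
#' Controls how a layer's activations are turned into a per-pixel
#' classification (the "TPI mapping"). Scenes are split deterministically
#' into a calibration subset (used to associate channels with classes) and
#' a disjoint evaluation subset (used to score the mapping).
#'
#' @param calibration_n Scenes used to associate channels with classes.
#' @param eval_n Scenes used for the WKs evaluation.
#' @param rule `"standardised"`: each channel is assigned to the class
#'   maximising its standardised in-class mean activation (mean inside the
#'   class minus mean outside, over the activation's standard deviation),
#'   and a class's score map is the mean of its assigned channels.
#'   `"linear"`: a least-squares 1x1 linear probe from channels to class
#'   indicators fitted on calibration pixels.
#' @param seed Seed for the calibration/evaluation split.
#' @return A `probe_config` object.
#' @export
probe_config <- function(calibration_n = 50, eval_n = 200,
                         rule = c("standardised", "linear"), seed = 1L) {
  rule <- match.arg(rule)
  structure(
    list(calibration_n = as.integer(calibration_n),
         eval_n = as.integer(eval_n), rule = rule, seed = as.integer(seed)),
    class = "probe_config"
  )
}

# Deterministic disjoint calibration/evaluation split.
probe_split <- function(scenes, probe) {
  scenes <- as_scene_list(scenes)
  n <- length(scenes)
  if (n < 2L) abort("need at least 2 scenes for a probe split.")
  perm <- with_seed(probe$seed, sample.int(n))
  ncal <- min(probe$calibration_n, max(1L, floor(n / 2)))
  neval <- min(probe$eval_n, n - ncal)
  list(calibration = scenes[perm[seq_len(ncal)]],
       evaluation = scenes[perm[(ncal + 1L):(ncal + neval)]])
}

# Layer-x activations of a scene, bilinearly upsampled to label resolution
# when needed (labels are never resampled).
layer_activation <- function(net, scene, x) {
  fw <- net_forward(net, scene$image, keep_activations = TRUE)
  act <- fw$activations[[x]]
  dl <- dim(scene$label)
  if (!identical(dim(act)[1:2], dl)) act <- resize_bilinear(act, dl[1], dl[2])
  act
}

# Channel -> class association for the standardised rule. Returns an
# integer vector of length K (NA when a channel never activates).
channel_assignment <- function(acts, labels, n_classes = 4L) {
  K <- dim(acts[[1L]])[3]
  s_in <- matrix(0, K, n_classes)
  n_in <- numeric(n_classes)
  s_tot <- numeric(K)
  ss_tot <- numeric(K)
  n_tot <- 0
  for (i in seq_along(acts)) {
    a <- matrix(acts[[i]], ncol = K)
    lab <- as.integer(labels[[i]])
    for (c in seq_len(n_classes)) {
      sel <- lab == c
      if (any(sel)) {
        s_in[, c] <- s_in[, c] + colSums(a[sel, , drop = FALSE])
        n_in[c] <- n_in[c] + sum(sel)
      }
    }
    s_tot <- s_tot + colSums(a)
    ss_tot <- ss_tot + colSums(a^2)
    n_tot <- n_tot + nrow(a)
  }
  sd_k <- sqrt(pmax(ss_tot / n_tot - (s_tot / n_tot)^2, 0)) + 1e-9
  score <- matrix(-Inf, K, n_classes)
  for (c in seq_len(n_classes)) {
    if (n_in[c] == 0 || n_tot == n_in[c]) next
    mu_in <- s_in[, c] / n_in[c]
    mu_out <- (s_tot - s_in[, c]) / (n_tot - n_in[c])
    score[, c] <- (mu_in - mu_out) / sd_k
  }
  assign <- apply(score, 1, function(r) {
    if (all(!is.finite(r))) NA_integer_ else which.max(r)
  })
  as.integer(assign)
}

# Least-squares 1x1 linear probe: ridge-stabilised regression from channel
# activations to class indicators, fitted on subsampled calibration pixels.
linear_probe_fit <- function(acts, labels, n_classes = 4L,
                             max_pixels = 20000L) {
  K <- dim(acts[[1L]])[3]
  xs <- list()
  ys <- list()
  per <- max(1L, floor(max_pixels / length(acts)))
  for (i in seq_along(acts)) {
    a <- matrix(acts[[i]], ncol = K)
    lab <- as.integer(labels[[i]])
    take <- seq(1L, nrow(a), length.out = min(per, nrow(a)))
    take <- unique(as.integer(take))
    xs[[i]] <- a[take, , drop = FALSE]
    ys[[i]] <- lab[take]
  }
  X <- cbind(1, do.call(rbind, xs))
  yv <- unlist(ys)
  Y <- matrix(0, length(yv), n_classes)
  Y[cbind(seq_along(yv), yv)] <- 1
  XtX <- crossprod(X) + diag(1e-6, ncol(X))
  solve(XtX, crossprod(X, Y))
}

#' Per-layer feature mapping (TPI mapping)
#'
#' Turns the activations of transfer point `x` into per-pixel class maps:
#' the probe is calibrated on a held-out calibration subset, then applied
#' to the given scenes. Classes that attract no channel get an all-zero
#' score map (logged via a message).
#'
#' @param net A trained `seg_net`.
#' @param x Transfer point (activation layer index).
#' @param scenes Survey tibble or scene list.
#' @param probe A [probe_config()].
#' @return A list of integer class maps for the evaluation subset, with
#'   attributes `evaluation` (the scenes mapped) and `assignment`.
#' @export
tpi_mapping <- function(net, x, scenes, probe = probe_config()) {
  sp <- probe_split(scenes, probe)
  cal_acts <- lapply(sp$calibration, function(sc) layer_activation(net, sc, x))
  cal_labs <- lapply(sp$calibration, function(sc) sc$label)
  model <- fit_probe(cal_acts, cal_labs, net$spec$n_classes, probe$rule)
  maps <- lapply(sp$evaluation, function(sc) {
    apply_probe(layer_activation(net, sc, x), model, net$spec$n_classes)
  })
  attr(maps, "evaluation") <- sp$evaluation
  attr(maps, "assignment") <- model
  maps
}

fit_probe <- function(acts, labs, n_classes, rule) {
  if (rule == "standardised") {
    assign <- channel_assignment(acts, labs, n_classes)
    missing <- setdiff(seq_len(n_classes), assign[!is.na(assign)])
    if (length(missing)) {
      inform(sprintf("no channel assigned to class %s; score map is zero.",
                     paste(missing, collapse = ", ")))
    }
    list(rule = "standardised", assign = assign)
  } else {
    list(rule = "linear",
         W = linear_probe_fit(acts, labs, n_classes))
  }
}

apply_probe <- function(act, model, n_classes) {
  d <- dim(act)
  A <- matrix(act, ncol = d[3])
  if (model$rule == "standardised") {
    scores <- matrix(0, nrow(A), n_classes)
    for (c in seq_len(n_classes)) {
      ch <- which(model$assign == c)
      if (length(ch)) {
        scores[, c] <- rowMeans(A[, ch, drop = FALSE])
      }
    }
  } else {
    scores <- cbind(1, A) %*% model$W
  }
  matrix(max.col(scores, ties.method = "first"), d[1], d[2])
}

#' Accuracy potential of a transfer point
#'
#' Weighted Cohen kappa between the TPI mapping of layer `x` and the labels
#' on the evaluation subset, clipped below at 0 (its stated range is 0..1).
#'
#' @inheritParams tpi_mapping
#' @return A number in [0, 1].
#' @export
tpi_wks <- function(net, x, scenes, probe = probe_config()) {
  maps <- tpi_mapping(net, x, scenes, probe)
  ev <- attr(maps, "evaluation")
  cms <- lapply(seq_along(maps), function(i) {
    confusion_matrix(maps[[i]], ev[[i]]$label, net$spec$n_classes)
  })
  max(kappa(accumulate_confusion(cms))$WKs, 0)
}

#' Time-cost level of a transfer point
#'
#' Bins the trainable-parameter fraction LSx/LS0 into `nlevel` discrete
#' cost levels: `min(nlevel, floor(LSx/LS0 * nlevel) + 1)`, so freezing
#' deeper never increases the cost level. `form = "literal"` uses the
#' frozen fraction (LS0-LSx)/LS0 instead, which makes the level rise as
#' the trainable size shrinks.
#'
#' @param lsx Trainable parameter count(s) at the transfer point.
#' @param ls0 Total trainable parameter count.
#' @param nlevel Number of cost levels (>= 2).
#' @param form `"fraction"` (default) or `"literal"`.
#' @return Integer level(s) in 1..nlevel.
#' @export
tpi_tp <- function(lsx, ls0, nlevel = 10L, form = c("fraction", "literal")) {
  form <- match.arg(form)
  if (nlevel < 2) abort("`nlevel` must be at least 2.")
  if (any(lsx < 0) || any(lsx > ls0)) {
    abort("`lsx` must satisfy 0 <= lsx <= ls0.")
  }
  frac <- if (form == "fraction") lsx / ls0 else (ls0 - lsx) / ls0
  as.integer(pmin(nlevel, floor(frac * nlevel) + 1))
}

#' Transfer potential index
#'
#' TPI = accuracy potential / time-cost level; larger is better (higher
#' final accuracy promise at lower retraining cost).
#'
#' @param wks Accuracy potential in [0, 1].
#' @param tp_level Cost level (>= 1).
#' @return A number in [0, 1].
#' @export
tpi <- function(wks, tp_level) {
  if (any(tp_level < 1)) abort("`tp_level` must be >= 1.")
  if (any(wks < 0) || any(wks > 1)) abort("`wks` must lie in [0, 1].")
  wks / tp_level
}

#' TPI curve over all transfer points
#'
#' One record per transfer point 1..T with the trainable size LSx, cost
#' level, accuracy potential, and their ratio TPI. Activations are computed
#' once per scene and reused across layers.
#'
#' @param net A trained `seg_net`.
#' @param scenes Scenes of the (possibly shifted) dataset to evaluate.
#' @param probe A [probe_config()].
#' @param nlevel Cost levels for [tpi_tp()].
#' @param form Cost-level form, see [tpi_tp()].
#' @param dataset Optional dataset id recorded on the curve.
#' @return A `tpi_curve` tibble with columns `x`, `ls`, `tpi_tp`,
#'   `tpi_wks`, `tpi`.
#' @export
tpi_curve <- function(net, scenes, probe = probe_config(), nlevel = 10L,
                      form = "fraction", dataset = NA_character_) {
  sp <- probe_split(scenes, probe)
  T <- length(net$convs)
  lst <- layer_sizes(net)
  ls0 <- ls_at(lst, 0L)
  cal_fw <- lapply(sp$calibration, function(sc) {
    net_forward(net, sc$image, keep_activations = TRUE)$activations
  })
  ev_fw <- lapply(sp$evaluation, function(sc) {
    net_forward(net, sc$image, keep_activations = TRUE)$activations
  })
  cal_labs <- lapply(sp$calibration, function(sc) sc$label)
  rows <- lapply(seq_len(T), function(x) {
    model <- fit_probe(lapply(cal_fw, `[[`, x), cal_labs,
                       net$spec$n_classes, probe$rule)
    cms <- lapply(seq_along(ev_fw), function(i) {
      map <- apply_probe(ev_fw[[i]][[x]], model, net$spec$n_classes)
      confusion_matrix(map, sp$evaluation[[i]]$label, net$spec$n_classes)
    })
    wks <- max(kappa(accumulate_confusion(cms))$WKs, 0)
    lsx <- ls_at(lst, x)
    lvl <- tpi_tp(lsx, ls0, nlevel, form)
    tibble(x = x, ls = lsx, tpi_tp = lvl, tpi_wks = wks,
           tpi = tpi(wks, lvl))
  })
  out <- bind_rows(rows)
  attr(out, "nlevel") <- nlevel
  attr(out, "dataset") <- dataset
  class(out) <- c("tpi_curve", class(out))
  out
}

#' Average TPI curves across datasets
#'
#' Pointwise arithmetic mean of the TPI (and accuracy-potential) values of
#' curves sharing one transfer-point catalog.
#'
#' @param curves List of `tpi_curve` objects.
#' @return A `tpi_curve`.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) abort("no curves to average.")
  x0 <- curves[[1L]]$x
  ls0 <- curves[[1L]]$ls
  for (cv in curves) {
    if (!identical(cv$x, x0) || !identical(cv$ls, ls0)) {
      abort("curves do not share the same transfer-point catalog.")
    }
  }
  out <- curves[[1L]]
  out$tpi_wks <- rowMeans(vapply(curves, function(cv) cv$tpi_wks,
                                 numeric(length(x0))))
  out$tpi <- rowMeans(vapply(curves, function(cv) cv$tpi,
                             numeric(length(x0))))
  attr(out, "dataset") <- "average"
  out
}

#' Select the transfer point TP0
#'
#' The transfer point with maximum TPI; ties break toward the largest x
#' (the cheapest transfer among equals).
#'
#' @param curve A `tpi_curve`.
#' @return The selected transfer point (integer).
#' @export
select_tp0 <- function(curve) {
  if (!nrow(curve)) abort("empty TPI curve.")
  best <- which(curve$tpi == max(curve$tpi))
  as.integer(curve$x[max(best)])
}

#' Transfer dataset size rule
#'
#' Assumes sample requirement scales linearly with trainable parameters:
#' the pre-training ratio kpre = TDSpre / LSpre is carried over (kt = kpre,
#' the lowest-error-risk choice), giving TDS0 = round(kpre * LS_TP0),
#' floored at 1 and capped at the available transfer data (with a warning).
#'
#' @param ls_tp0 Trainable parameters at the selected transfer point.
#' @param tds_pre Pre-training dataset size.
#' @param ls_pre Pre-training trainable parameter count (LS0).
#' @param available Number of transfer samples available.
#' @param tp0 Optional transfer point recorded in the condition.
#' @return An `mtpi_condition` with `tp0`, `tds0`, `kpre`, `kt`, and the
#'   bookkeeping inputs.
#' @export
tds_rule <- function(ls_tp0, tds_pre, ls_pre, available = Inf,
                     tp0 = NA_integer_) {
  if (any(c(ls_tp0, tds_pre, ls_pre) <= 0)) {
    abort("`ls_tp0`, `tds_pre` and `ls_pre` must all be positive.")
  }
  kpre <- tds_pre / ls_pre
  tds0 <- max(1, round(kpre * ls_tp0))
  capped <- FALSE
  if (tds0 > available) {
    warn(sprintf("TDS0 = %d exceeds available transfer data (%d); capped.",
                 tds0, available))
    tds0 <- available
    capped <- TRUE
  }
  structure(
    list(tp0 = as.integer(tp0), tds0 = as.integer(tds0), kpre = kpre,
         kt = kpre, tds_pre = tds_pre, ls_pre = ls_pre, ls_tp0 = ls_tp0,
         capped = capped),
    class = "mtpi_condition"
  )
}

#' @export
print.mtpi_condition <- function(x, ...) {
  cat(sprintf(
    "MTPI condition: TP0 = %s, TDS0 = %d (kpre = kt = %.3g, LS_TP0 = %d)\n",
    ifelse(is.na(x$tp0), "?", x$tp0), x$tds0, x$kpre, x$ls_tp0))
  invisible(x)
}

#' @export
glance.mtpi_condition <- function(x, ...) {
  tibble(tp0 = x$tp0, tds0 = x$tds0, kpre = x$kpre, kt = x$kt,
         tds_pre = x$tds_pre, ls_pre = x$ls_pre, ls_tp0 = x$ls_tp0,
         capped = x$capped)
}

#' Screen a dataset against a pre-trained network
#'
#' Datasets on which the pre-trained net keeps WKs >= `skip_threshold` need
#' no transfer; WKs < `transfer_threshold` triggers transfer training; the
#' band in between is flagged for the operator.
#'
#' @param net A trained `seg_net`.
#' @param scenes Scenes of the dataset.
#' @param skip_threshold,transfer_threshold Screening thresholds (0.8/0.6).
#' @return A list with `WKs`, `decision` (one of `"skip"`, `"transfer"`,
#'   `"borderline"`), and the full `report`.
#' @export
screen_dataset <- function(net, scenes, skip_threshold = 0.8,
                           transfer_threshold = 0.6) {
  rep <- scenes_metric_report(net, scenes)
  list(WKs = rep$WKs,
       decision = screen_decision(rep$WKs, skip_threshold,
                                  transfer_threshold),
       report = rep)
}

# The screening band itself: >= skip -> keep the pre-trained net; < transfer
# -> retrain; the band in between is undefined by the protocol and flagged.
screen_decision <- function(wks, skip_threshold = 0.8,
                            transfer_threshold = 0.6) {
  if (wks >= skip_threshold) {
    "skip"
  } else if (wks < transfer_threshold) {
    "transfer"
  } else {
    "borderline"
  }
}

#' Shift calibration diagnostic
#'
#' Evaluates a source-trained network on source and target scene sets and
#' reports the screening decision for each, plus any classes absent from
#' either set.
#'
#' @param net A trained `seg_net`.
#' @param source,target Scene sets (survey tibbles or lists).
#' @return A tibble with one row per domain: `domain`, `WKs`, `decision`,
#'   `absent_classes`.
#' @export
calibrate_shift <- function(net, source, target) {
  srcs <- as_scene_list(source)
  tgts <- as_scene_list(target)
  if (!length(srcs) || !length(tgts)) {
    abort("`source` and `target` must each contain at least one scene.")
  }
  row_for <- function(scenes, domain) {
    counts <- Reduce(`+`, lapply(scenes, function(sc) {
      tabulate(as.integer(sc$label), nbins = net$spec$n_classes)
    }))
    absent <- rownames(vegetation_palette())[which(counts == 0)]
    sc <- screen_dataset(net, scenes)
    tibble(domain = domain, WKs = sc$WKs, decision = sc$decision,
           absent_classes = list(absent))
  }
  bind_rows(row_for(srcs, "source"), row_for(tgts, "target"))
}
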