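#' Toy segmentation network specification
#'
#' A small fully-convolutional encoder: `depth` stages of 3x3 convolution +
#' ReLU at constant resolution, followed by a 1x1 classification head.
#' Channel widths taper geometrically (`base_channels * taper^(stage-1)`,
#' floored at 4), concentrating parameters in the early stages the way
#' backbone-heavy segmentation networks do — which is what makes the
#' transfer-cost curve informative. The transfer-point machinery is
#' architecture-agnostic: any net exposing ordered activation layers and
#' per-layer parameter groups plugs in unchanged.
#'
#' @param depth Number of conv+ReLU stages (>= 2).
#' @param base_channels Channels of stage 1.
#' @param taper Geometric channel taper per stage (1 = constant width).
#' @param residual Add identity skips where consecutive stage widths match.
#' @param n_classes Number of output classes.
#' @param input_size Minimum accepted input side, in pixels (>= 48; the
#'   full-scale contract of the emulated backbones is 224).
#' @param seed Seed for deterministic He-style initialisation.
#' @param channels Optional explicit per-stage channel vector overriding
#'   the taper rule.
#' @return A `net_spec` object.
#' @export
net_spec <- function(depth = 5, base_channels = 16, taper = 0.75,
                     residual = FALSE, n_classes = 4, input_size = 64,
                     seed = 1L, channels = NULL) {
  if (depth < 2) abort("`depth` must be at least 2.")
  if (input_size < 48) abort("`input_size` must be at least 48.")
  if (is.null(channels)) {
    channels <- pmax(round(base_channels * taper^(seq_len(depth) - 1)), 4L)
  }
  if (length(channels) != depth) {
    abort("`channels` must have one entry per stage.")
  }
  structure(
    list(depth = as.integer(depth), base_channels = base_channels,
         taper = taper, channels = as.integer(channels),
         residual = isTRUE(residual), n_classes = as.integer(n_classes),
         input_size = as.integer(input_size), seed = as.integer(seed)),
    class = "net_spec"
  )
}

he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  array(rnorm(k * k * cin * cout, 0, sd), dim = c(k, k, cin, cout))
}

#' Build a network from a specification
#'
#' Weights are drawn deterministically from the specification's seed; two
#' builds from
#' the same spec are bit-identical.
#'
#' @param spec A [net_spec()].
#' @return A `seg_net` object.
#' @export
build_net <- function(spec = net_spec()) {
  with_seed(spec$seed, {
    cin <- 3L
    convs <- vector("list", spec$depth)
    for (s in seq_len(spec$depth)) {
      cout <- spec$channels[s]
      convs[[s]] <- list(w = he_init(3L, cin, cout), b = numeric(cout),
                         trainable = TRUE)
      cin <- cout
    }
    head <- list(w = he_init(1L, cin, spec$n_classes),
                 b = numeric(spec$n_classes), trainable = TRUE)
    structure(list(spec = spec, convs = convs, head = head,
                   frozen_to = 0L),
              class = "seg_net")
  })
}

conv_param_count <- function(layer) length(layer$w) + length(layer$b)

#' Enumerate transfer points
#'
#' One entry per activation (ReLU) layer in forward order, counted from the
#' input side, with the cumulative parameter count frozen when layers 1..x
#' are frozen. x = 0 (freeze nothing) and x = -1 (freeze everything but the
#' classification head) are virtual entries handled by [freeze()] and
#' [layer_sizes()].
#'
#' @param net A `seg_net`.
#' @return A tibble with columns `tp`, `layer`, `params`, `cum_frozen`.
#' @export
enumerate_tps <- function(net) {
  params <- vapply(net$convs, conv_param_count, 0)
  tibble(
    tp = seq_along(net$convs),
    layer = sprintf("relu_%d", seq_along(net$convs)),
    params = params,
    cum_frozen = cumsum(params)
  )
}

#' Trainable-parameter table over transfer points
#'
#' LSx is the number of parameters that remain trainable when layers 1..x
#' are frozen; LS0 is the full parameter count and LS(-1) the
#' classification-head count. LSx is non-increasing in x.
#'
#' @param net A `seg_net`.
#' @param catalog Optional catalog from [enumerate_tps()].
#' @return A tibble with columns `x` (-1, 0, 1..T) and `ls`.
#' @export
layer_sizes <- function(net, catalog = enumerate_tps(net)) {
  total <- sum(catalog$params) + conv_param_count(net$head)
  head_only <- conv_param_count(net$head)
  tibble(
    x = c(-1L, 0L, catalog$tp),
    ls = c(head_only, total, total - catalog$cum_frozen)
  )
}

ls_at <- function(lst, x) lst$ls[match(x, lst$x)]

#' Inverse-frequency class weights
#'
#' Loss weights proportional to 1 / (pixel count of the class over the
#' training labels), normalised to sum to the number of classes, so
#' balanced data gives unit weights. Every class must be present.
#'
#' @param labels A survey tibble, list of scenes, or integer label data.
#' @param n_classes Number of classes.
#' @return A numeric weight vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes = 4L) {
  if (is_tibble(labels) || (is.list(labels) && !is.null(labels[[1L]]$label)) ||
      inherits(labels, "mtpi_scene")) {
    scenes <- as_scene_list(labels)
    counts <- Reduce(`+`, lapply(scenes, function(sc) {
      tabulate(as.integer(sc$label), nbins = n_classes)
    }))
  } else {
    counts <- tabulate(as.integer(labels), nbins = n_classes)
  }
  if (any(counts == 0)) {
    cls <- rownames(vegetation_palette())[which(counts == 0)]
    abort(sprintf("class absent from training labels: %s.",
                  paste(cls, collapse = ", ")))
  }
  w <- 1 / counts
  w * n_classes / sum(w)
}

#' Freeze layers up to a transfer point
#'
#' Marks the parameters of stages 1..x non-trainable. `x = 0` freezes
#' nothing; `x = -1` freezes every stage, leaving only the classification
#' head trainable. Frozen parameters are never touched by [train_net()].
#'
#' @param net A `seg_net`.
#' @param x Transfer point in {-1, 0, 1..T}.
#' @return The net with updated trainable flags.
#' @export
freeze <- function(net, x) {
  T <- length(net$convs)
  if (!x %in% c(-1L, 0L, seq_len(T))) {
    abort(sprintf("`x` must be in {-1, 0, 1..%d}.", T))
  }
  upto <- if (x == -1L) T else x
  for (s in seq_len(T)) net$convs[[s]]$trainable <- s > upto
  net$head$trainable <- TRUE
  net$frozen_to <- as.integer(x)
  net
}

#' Count trainable parameters
#' @param net A `seg_net`.
#' @return Integer count.
#' @export
trainable_params <- function(net) {
  sum(vapply(net$convs, function(l) {
    if (l$trainable) conv_param_count(l) else 0
  }, 0)) + conv_param_count(net$head)
}

# Forward pass. Images enter in [0,255] and are scaled to zero-centred
# [-0.5, 0.5]. Returns logits (H x W x C) and, optionally, all stage
# activations.
net_forward <- function(net, image, keep_activations = FALSE) {
  x <- image / 255 - 0.5
  acts <- if (keep_activations) vector("list", length(net$convs)) else NULL
  pre <- vector("list", length(net$convs))
  for (s in seq_along(net$convs)) {
    l <- net$convs[[s]]
    z <- conv2d_fwd_cpp(x, l$w, l$b)
    if (net$spec$residual && s > 1L &&
        dim(z)[3] == dim(x)[3]) {
      z <- z + x
    }
    pre[[s]] <- z
    x <- z * (z > 0)
    if (keep_activations) acts[[s]] <- x
  }
  d <- dim(x)
  a <- matrix(x, d[1] * d[2], d[3])
  wh <- matrix(net$head$w, d[3], net$spec$n_classes)
  logits <- a %*% wh
  logits <- sweep(logits, 2, net$head$b, "+")
  list(logits = array(logits, c(d[1], d[2], net$spec$n_classes)),
       last_act = x, pre = pre, activations = acts)
}

#' Predict a class map for one image
#'
#' Per-pixel argmax over class scores; ties break toward the lower class
#' index for reproducibility.
#'
#' @param net A trained `seg_net`.
#' @param image H x W x 3 array in [0,255].
#' @return An integer class map.
#' @export
predict_scene <- function(net, image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) abort("image must be H x W x 3.")
  fw <- net_forward(net, image)
  lg <- matrix(fw$logits, d[1] * d[2], net$spec$n_classes)
  matrix(max.col(lg, ties.method = "first"), d[1], d[2])
}

#' @export
predict.seg_net <- function(object, image, ...) predict_scene(object, image)

#' Training configuration
#'
#' @param max_iterations Iteration budget (one batch per iteration).
#' @param batch_size Scenes per iteration.
#' @param learning_rate,momentum SGD-with-momentum hyperparameters.
#' @param validation_cadence Validate every this many iterations.
#' @param conv_tol,conv_window Convergence rule: stop once the relative
#'   improvement of the mean loss between two consecutive windows of
#'   `conv_window` iterations falls below `conv_tol`.
#' @param clip_norm Global gradient-norm clip per iteration (guards the
#'   plain-ReLU stages against collapse); `Inf` disables.
#' @param class_weights Per-class loss weights; `NULL` derives
#'   inverse-frequency weights from the training labels.
#' @param seed Seed for shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(max_iterations = 400, batch_size = 2,
                         learning_rate = 0.02, momentum = 0.9,
                         validation_cadence = 100, conv_tol = 0.005,
                         conv_window = 40, class_weights = NULL,
                         clip_norm = 5, seed = 1L) {
  vals <- c(max_iterations, batch_size, learning_rate, momentum + 1,
            validation_cadence, conv_tol, conv_window)
  if (any(vals <= 0)) abort("training config values must be positive.")
  structure(
    list(max_iterations = as.integer(max_iterations),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, momentum = momentum,
         validation_cadence = as.integer(validation_cadence),
         conv_tol = conv_tol, conv_window = as.integer(conv_window),
         class_weights = class_weights, clip_norm = clip_norm,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Weighted softmax cross-entropy over pixels. Returns loss and the logits
# gradient. `wc` indexes by true class.
softmax_ce <- function(logits, label, wc) {
  d <- dim(logits)
  n <- d[1] * d[2]
  lg <- matrix(logits, n, d[3])
  lg <- lg - apply(lg, 1, max)
  e <- exp(lg)
  p <- e / rowSums(e)
  t <- as.integer(label)
  wt <- wc[t]
  wsum <- sum(wt)
  idx <- cbind(seq_len(n), t)
  loss <- -sum(wt * log(pmax(p[idx], 1e-12))) / wsum
  g <- p * (wt / wsum)
  g[idx] <- g[idx] - wt / wsum
  list(loss = loss, grad = array(g, d))
}

# Backward pass for one sample given forward cache. `min_stage` is the
# shallowest stage whose gradients are needed; the chain below the deepest
# frozen layer is skipped entirely.
net_backward <- function(net, image, fw, gl, min_stage = 1L) {
  d <- dim(fw$last_act)
  n <- d[1] * d[2]
  G <- matrix(gl, n, net$spec$n_classes)
  A <- matrix(fw$last_act, n, d[3])
  gw_head <- array(crossprod(A, G), dim = dim(net$head$w))
  gb_head <- colSums(G)
  gx <- array(G %*% t(matrix(net$head$w, d[3], net$spec$n_classes)),
              c(d[1], d[2], d[3]))
  gconvs <- vector("list", length(net$convs))
  for (s in rev(seq_along(net$convs))) {
    if (s < min_stage) break
    z <- fw$pre[[s]]
    gz <- gx * (z > 0)
    xin <- if (s == 1L) image / 255 - 0.5 else
      fw$pre[[s - 1L]] * (fw$pre[[s - 1L]] > 0)
    bw <- conv2d_bwd_cpp(xin, net$convs[[s]]$w, gz)
    gx_new <- bw$gx
    if (net$spec$residual && s > 1L &&
        dim(z)[3] == dim(xin)[3]) {
      gx_new <- gx_new + gz
    }
    gconvs[[s]] <- list(gw = bw$gw, gb = bw$gb)
    gx <- gx_new
  }
  list(convs = gconvs, head = list(gw = gw_head, gb = gb_head))
}

#' Train a segmentation network
#'
#' Minimises class-weighted softmax cross-entropy with momentum SGD,
#' honouring freeze flags (frozen parameters are left bit-identical).
#' Shuffling, and therefore the whole run, is reproducible from the config
#' seed. Stops at the convergence rule or the iteration budget.
#'
#' @param net A `seg_net` (optionally pre-frozen via [freeze()]).
#' @param train_scenes Survey tibble or list of scenes (all one size).
#' @param config A [train_config()].
#' @param val_scenes Optional validation scenes, evaluated every
#'   `validation_cadence` iterations.
#' @return A list with `net` (trained) and `trace` (a `train_trace`).
#' @export
train_net <- function(net, train_scenes, config = train_config(),
                      val_scenes = NULL) {
  scenes <- as_scene_list(train_scenes)
  nsc <- length(scenes)
  if (nsc == 0L) abort("no training scenes.")
  wc <- config$class_weights %||% tryCatch(
    class_weights(scenes, net$spec$n_classes),
    error = function(e) rep(1, net$spec$n_classes))
  vel <- list(
    convs = lapply(net$convs, function(l) list(w = l$w * 0, b = l$b * 0)),
    head = list(w = net$head$w * 0, b = net$head$b * 0)
  )
  losses <- numeric(0)
  val_rows <- list()
  converged_at <- NA_integer_
  trainable_stages <- which(vapply(net$convs, function(l) l$trainable, TRUE))
  min_stage <- if (length(trainable_stages)) min(trainable_stages) else
    length(net$convs) + 1L
  with_seed(config$seed, {
    order_pool <- sample.int(nsc)
    pos <- 1L
    for (iter in seq_len(config$max_iterations)) {
      take <- integer(config$batch_size)
      for (b in seq_len(config$batch_size)) {
        if (pos > nsc) {
          order_pool <- sample.int(nsc)
          pos <- 1L
        }
        take[b] <- order_pool[pos]
        pos <- pos + 1L
      }
      gacc <- NULL
      loss <- 0
      for (si in take) {
        sc <- scenes[[si]]
        fw <- net_forward(net, sc$image)
        ce <- softmax_ce(fw$logits, sc$label, wc)
        if (!is.finite(ce$loss)) {
          abort("training diverged (non-finite loss).")
        }
        loss <- loss + ce$loss
        bw <- net_backward(net, sc$image, fw, ce$grad, min_stage)
        if (is.null(gacc)) {
          gacc <- bw
        } else {
          for (s in seq_along(bw$convs)) {
            if (is.null(bw$convs[[s]])) next
            gacc$convs[[s]]$gw <- gacc$convs[[s]]$gw + bw$convs[[s]]$gw
            gacc$convs[[s]]$gb <- gacc$convs[[s]]$gb + bw$convs[[s]]$gb
          }
          gacc$head$gw <- gacc$head$gw + bw$head$gw
          gacc$head$gb <- gacc$head$gb + bw$head$gb
        }
      }
      nb <- length(take)
      losses[iter] <- loss / nb
      clip <- config$clip_norm %||% Inf
      if (is.finite(clip)) {
        gn2 <- sum(gacc$head$gw^2) + sum(gacc$head$gb^2)
        for (s in seq_along(net$convs)) {
          if (!net$convs[[s]]$trainable || is.null(gacc$convs[[s]])) next
          gn2 <- gn2 + sum(gacc$convs[[s]]$gw^2) + sum(gacc$convs[[s]]$gb^2)
        }
        gn <- sqrt(gn2) / nb
        if (gn > clip) {
          sc <- clip / gn
          for (s in seq_along(net$convs)) {
            if (is.null(gacc$convs[[s]])) next
            gacc$convs[[s]]$gw <- gacc$convs[[s]]$gw * sc
            gacc$convs[[s]]$gb <- gacc$convs[[s]]$gb * sc
          }
          gacc$head$gw <- gacc$head$gw * sc
          gacc$head$gb <- gacc$head$gb * sc
        }
      }
      lr <- config$learning_rate
      mu <- config$momentum
      for (s in seq_along(net$convs)) {
        if (!net$convs[[s]]$trainable) next
        vel$convs[[s]]$w <- mu * vel$convs[[s]]$w - lr * gacc$convs[[s]]$gw / nb
        vel$convs[[s]]$b <- mu * vel$convs[[s]]$b - lr * gacc$convs[[s]]$gb / nb
        net$convs[[s]]$w <- net$convs[[s]]$w + vel$convs[[s]]$w
        net$convs[[s]]$b <- net$convs[[s]]$b + vel$convs[[s]]$b
      }
      vel$head$w <- mu * vel$head$w - lr * gacc$head$gw / nb
      vel$head$b <- mu * vel$head$b - lr * gacc$head$gb / nb
      net$head$w <- net$head$w + vel$head$w
      net$head$b <- net$head$b + vel$head$b
      if (!is.null(val_scenes) && iter %% config$validation_cadence == 0L) {
        rep <- scenes_metric_report(net, val_scenes)
        val_rows[[length(val_rows) + 1L]] <-
          tibble(iteration = iter, val_po = rep$Po, val_wks = rep$WKs)
      }
      w <- config$conv_window
      if (is.na(converged_at) && iter >= 2L * w) {
        m1 <- mean(losses[(iter - w + 1L):iter])
        m0 <- mean(losses[(iter - 2L * w + 1L):(iter - w)])
        if (m0 > 0 && (m0 - m1) / m0 < config$conv_tol) {
          converged_at <- iter
          break
        }
      }
    }
  })
  trace <- structure(
    list(loss = losses,
         validation = if (length(val_rows)) bind_rows(val_rows) else
           tibble(iteration = integer(), val_po = numeric(),
                  val_wks = numeric()),
         iterations = length(losses),
         converged_at = if (is.na(converged_at)) length(losses) else
           converged_at,
         converged = !is.na(converged_at)),
    class = "train_trace"
  )
  list(net = net, trace = trace)
}

#' @export
tidy.train_trace <- function(x, ...) {
  tibble(iteration = seq_along(x$loss), loss = x$loss)
}

#' @export
glance.train_trace <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         converged_at = x$converged_at,
         final_loss = x$loss[length(x$loss)])
}

#' @export
tidy.seg_net <- function(x, ...) {
  bind_rows(
    tibble(layer = sprintf("conv_%d", seq_along(x$convs)),
           params = vapply(x$convs, conv_param_count, 0),
           trainable = vapply(x$convs, function(l) l$trainable, TRUE)),
    tibble(layer = "head", params = conv_param_count(x$head),
           trainable = x$head$trainable)
  )
}

#' @export
glance.seg_net <- function(x, ...) {
  lst <- layer_sizes(x)
  tibble(depth = x$spec$depth, total_params = ls_at(lst, 0L),
         head_params = ls_at(lst, -1L), frozen_to = x$frozen_to,
         trainable = trainable_params(x))
}

#' @export
print.seg_net <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Toy segmentation net: depth %d, %d params (%d trainable, TP frozen to %d)\n",
    g$depth, g$total_params, g$trainable, g$frozen_to))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Checkpoints hold the parameter arrays, spec, transfer-point catalog,
#' layer-size table, and a hash of the training configuration.
#'
#' @param net A `seg_net`.
#' @param path File path.
#' @param config Optional training config stored as a hash.
#' @return `save_net()` the path invisibly; `load_net()` a `seg_net`.
#' @export
save_net <- function(net, path, config = NULL) {
  obj <- list(net = net, catalog = enumerate_tps(net),
              layer_sizes = layer_sizes(net),
              config_hash = if (!is.null(config)) hash(config) else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) readRDS(path)$net
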