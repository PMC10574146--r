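# Shared fixtures, built in code at test time.

toy_params <- function(seed = 1L, size = 64L, ...) {
  scene_params(height = size, width = size, seed = seed, ...)
}

# A flat-colour scene whose pixels are exactly the palette colours, one
# quadrant per class. Used by the probe-oracle tests.
palette_scene <- function(size = 48L) {
  half <- size %/% 2L
  label <- matrix(1L, size, size)
  label[(half + 1):size, 1:half] <- 2L
  label[1:half, (half + 1):size] <- 3L
  label[(half + 1):size, (half + 1):size] <- 4L
  image <- encode_label(label)
  mtpi:::new_scene(image, label, scene_params(height = size, width = size),
                   seed = 0L)
}

# Brute-force confusion matrix: per-pixel double loop.
oracle_confusion <- function(pred, truth, C = 4L) {
  m <- matrix(0, C, C)
  for (k in seq_along(pred)) {
    m[pred[k], truth[k]] <- m[pred[k], truth[k]] + 1
  }
  m
}

# Brute-force weighted metrics from one-vs-rest counts.
oracle_metrics <- function(m) {
  C <- nrow(m)
  total <- sum(m)
  pi <- colSums(m) / total
  prec <- rec <- f1 <- iou <- numeric(C)
  for (i in seq_len(C)) {
    tp <- m[i, i]
    fp <- sum(m[i, ]) - tp
    fn <- sum(m[, i]) - tp
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else {
      0
    }
    iou[i] <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
  }
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  list(WPA = sum(pi * prec), WRE = sum(pi * rec), WF1 = sum(pi * f1),
       WIoU = sum(pi * iou), WKs = (po - pe) / (1 - pe), Po = po, Pe = pe)
}

random_cm <- function(seed, C = 4L, lambda = 40) {
  set.seed(seed)
  m <- matrix(rpois(C * C, lambda), C, C) + diag(rpois(C, 4 * lambda))
  cm <- structure(m, class = c("confusion_matrix", "matrix", "array"))
  cm
}

# A 2-stage net whose first-layer channels are exact one-vs-rest
# indicators of the palette colours (centre-tap linear separation of the
# four palette points in RGB space); stage 2 passes them through.
indicator_net <- function() {
  spec <- net_spec(depth = 2, channels = c(4L, 4L), input_size = 48,
                   seed = 1L)
  net <- build_net(spec)
  w1 <- array(0, dim = c(3, 3, 3, 4))
  # weights act on centred inputs (x/255 - 0.5); palette points are 0/255
  # per channel, i.e. -0.5 / +0.5 after centring.
  sep <- rbind(tree  = c(-1, -1,  1),
               shrub = c(-1,  1, -1),
               grass = c( 1, -1, -1),
               NVA   = c( 1, -1,  1))
  bias <- rep(-0.75, 4)
  for (c in 1:4) w1[2, 2, , c] <- sep[c, ]
  net$convs[[1]]$w <- w1
  net$convs[[1]]$b <- bias
  w2 <- array(0, dim = c(3, 3, 4, 4))
  for (c in 1:4) w2[2, 2, c, c] <- 1
  net$convs[[2]]$w <- w2
  net$convs[[2]]$b <- numeric(4)
  net
}
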