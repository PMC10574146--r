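# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so runs are reproducible from (params, seed) alone.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed derived from (seed, index); computed in doubles
# (exact below 2^53) and reduced into 32-bit signed integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scene <- function(scene) {
  if (!is.list(scene) || is.null(scene$image) || is.null(scene$label)) {
    abort("expected a scene with `image` and `label` components.")
  }
  di <- dim(scene$image)
  dl <- dim(scene$label)
  if (length(di) != 3L || di[3] != 3L) abort("scene image must be H x W x 3.")
  if (!identical(di[1:2], dl[1:2])) {
    abort("scene image and label must share spatial dimensions.")
  }
  invisible(scene)
}

# 2-D Gaussian smoothing by FFT with circular boundary; used for the
# correlated random fields behind scene labels.
gaussian_smooth_fft <- function(x, sigma) {
  h <- nrow(x)
  w <- ncol(x)
  gi <- exp(-0.5 * (pmin(0:(h - 1), h - (0:(h - 1)))^2) / sigma^2)
  gj <- exp(-0.5 * (pmin(0:(w - 1), w - (0:(w - 1)))^2) / sigma^2)
  k <- outer(gi, gj)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / (h * w)
}

# Bilinear resize of an H x W x C array via the affine warp kernel.
resize_bilinear <- function(img, h_out, w_out) {
  d <- dim(img)
  if (length(d) == 2L) {
    img <- array(img, dim = c(d, 1L))
    d <- dim(img)
  }
  m <- matrix(c((d[1] - 1) / max(h_out - 1, 1), 0, 0,
                0, (d[2] - 1) / max(w_out - 1, 1), 0),
              nrow = 2, byrow = TRUE)
  warp_affine_cpp(img, m, 1L, rep(0, d[3]),
                  c(as.integer(h_out), as.integer(w_out)))
}
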