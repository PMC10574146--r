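#' Class palette
#'
#' RGB palette used for label rasters: tree = blue (0,0,255), shrub = green
#' (0,255,0), grass = red (255,0,0), NVA = magenta (255,0,255).
#'
#' @return A 4x3 integer matrix with class rownames.
#' @export
vegetation_palette <- function() {
  m <- rbind(tree  = c(0L, 0L, 255L),
             shrub = c(0L, 255L, 0L),
             grass = c(255L, 0L, 0L),
             NVA   = c(255L, 0L, 255L))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Palette label codec
#'
#' `encode_label()` turns an integer class map (values 1..4) into an RGB
#' raster using [vegetation_palette()]; `decode_label()` inverts it.
#' `decode(encode(x))` is the identity, bit-exactly. Decoding an off-palette
#' pixel is an error naming the first offending pixel coordinate.
#'
#' @param class_map Integer matrix with values in 1..4.
#' @param raster H x W x 3 array with values in {0, 255}.
#' @return `encode_label()`: an H x W x 3 array; `decode_label()`: an
#'   integer matrix.
#' @export
encode_label <- function(class_map) {
  if (!all(class_map %in% 1:4)) {
    abort("label values must all lie in 1..4.")
  }
  pal <- vegetation_palette()
  h <- nrow(class_map)
  w <- ncol(class_map)
  out <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(pal[class_map, ch], h, w)
  out
}

#' @rdname encode_label
#' @export
decode_label <- function(raster) {
  d <- dim(raster)
  if (length(d) != 3L || d[3] != 3L) abort("label raster must be H x W x 3.")
  pal <- vegetation_palette()
  key <- raster[, , 1L] * 1e6 + raster[, , 2L] * 1e3 + raster[, , 3L]
  palkey <- pal[, 1L] * 1e6 + pal[, 2L] * 1e3 + pal[, 3L]
  idx <- match(as.vector(key), palkey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    i <- (bad - 1L) %% d[1L] + 1L
    j <- (bad - 1L) %/% d[1L] + 1L
    abort(sprintf(
      "off-palette pixel at (%d, %d): RGB = (%d, %d, %d).",
      i, j, raster[i, j, 1L], raster[i, j, 2L], raster[i, j, 3L]))
  }
  matrix(idx, d[1L], d[2L])
}

#' Random crops from a large image/label pair
#'
#' Emulates assembling a dataset of fixed-size samples from large survey
#' rasters: `n` crops at uniformly random top-left positions, with image and
#' label cropped through identical windows.
#'
#' @param image H x W x 3 array.
#' @param label H x W integer class map.
#' @param size Crop side in pixels; must be >= `min_size` and fit in the
#'   input. The default floor of 224 follows the minimum input size of the
#'   backbone networks the full-scale datasets were built for.
#' @param n Number of crops.
#' @param seed Integer seed.
#' @param min_size Lower bound on `size`.
#' @return A survey tibble of `n` scenes.
#' @export
crop_samples <- function(image, label, size = 400, n = 1, seed = 1L,
                         min_size = 224) {
  d <- dim(image)
  if (size < min_size) {
    abort(sprintf("crop `size` must be at least %d pixels.", min_size))
  }
  if (size > d[1L] || size > d[2L]) {
    abort("crop `size` exceeds the image dimensions.")
  }
  with_seed(seed, {
    i0 <- sample.int(d[1L] - size + 1L, n, replace = TRUE)
    j0 <- sample.int(d[2L] - size + 1L, n, replace = TRUE)
    scenes <- lapply(seq_len(n), function(k) {
      ri <- i0[k]:(i0[k] + size - 1L)
      rj <- j0[k]:(j0[k] + size - 1L)
      new_scene(image[ri, rj, , drop = FALSE], label[ri, rj, drop = FALSE],
                NULL, seed)
    })
    tibble(
      scene_id = sprintf("crop_%05d", seq_len(n)),
      seed = derive_seed(seed, seq_len(n)),
      domain = "source",
      scene = scenes
    )
  })
}

#' Split a dataset into train / validation / test
#'
#' Random disjoint partition in the given proportions (default 4:1:1), with
#' any remainder assigned to the training split. Deterministic per seed.
#'
#' @param ds A survey/dataset tibble.
#' @param ratios Three positive weights.
#' @param seed Integer seed.
#' @return A named list of tibbles (`train`, `validation`, `test`), each
#'   with a `role` column.
#' @export
split_dataset <- function(ds, ratios = c(4, 1, 1), seed = 1L) {
  n <- nrow(ds)
  if (n < 6L) abort("dataset too small to split: need at least 6 samples.")
  if (length(ratios) != 3L || any(ratios <= 0)) {
    abort("`ratios` must be 3 positive numbers.")
  }
  sizes <- floor(n * ratios / sum(ratios))
  sizes[1L] <- n - sizes[2L] - sizes[3L]
  perm <- with_seed(seed, sample.int(n))
  roles <- c("train", "validation", "test")
  bounds <- cumsum(c(0, sizes))
  out <- lapply(1:3, function(k) {
    idx <- sort(perm[(bounds[k] + 1L):bounds[k + 1L]])
    part <- ds[idx, , drop = FALSE]
    part$role <- roles[k]
    part
  })
  setNames(out, roles)
}

#' Augmentation configuration
#'
#' The seven augmentation methods: symmetry (random x/y mirror), panning
#' (+/-5% of the side), HSV channel jitter (x0.9..1.1), scaling
#' (x0.9..1.1), rotation (+/-5 degrees), Gaussian noise (mean 0, variance
#' 0.1 on [0,1]-scaled intensities), and cropping (a random sub-window
#' resized back to full size). Each augmented variant composes 1..3 methods
#' drawn uniformly. Geometric methods move image and label through the same
#' affine map (image bilinear, label nearest-neighbour); photometric
#' methods never touch the label. Regions exposed by a geometric move are
#' filled with NVA (label) and the NVA base colour (image).
#'
#' @param pan_range Max |pan| as a fraction of the side.
#' @param hsv_range Multiplicative HSV jitter range.
#' @param rot_range Max |rotation| in degrees.
#' @param noise_mean,noise_var Gaussian noise moments on [0,1] intensities.
#' @param scale_range Scale factor range.
#' @param crop_range Sub-window fraction range for the cropping method.
#' @param expansion_factor Outputs per input sample (original + factor-1
#'   variants).
#' @param seed Stream seed; sample i uses a stream derived from (seed, i).
#' @return An `augment_config` object.
#' @export
augment_config <- function(pan_range = 0.05, hsv_range = c(0.9, 1.1),
                           rot_range = 5, noise_mean = 0, noise_var = 0.1,
                           scale_range = c(0.9, 1.1),
                           crop_range = c(0.85, 1),
                           expansion_factor = 6, seed = 1L) {
  if (expansion_factor < 1) abort("`expansion_factor` must be >= 1.")
  structure(
    list(pan_range = pan_range, hsv_range = hsv_range,
         rot_range = rot_range, noise_mean = noise_mean,
         noise_var = noise_var, scale_range = scale_range,
         crop_range = crop_range,
         expansion_factor = as.integer(expansion_factor),
         seed = as.integer(seed)),
    class = "augment_config"
  )
}

aug_methods <- c("symmetry", "pan", "hsv", "scale", "rotate", "noise", "crop")

# 3x3 homogeneous forward transforms about the image centre (zero-based
# pixel coordinates: row, col).
affine_identity <- function() diag(3)

affine_about_center <- function(core, h, w) {
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  t1 <- rbind(c(1, 0, -cy), c(0, 1, -cx), c(0, 0, 1))
  t2 <- rbind(c(1, 0, cy), c(0, 1, cx), c(0, 0, 1))
  t2 %*% core %*% t1
}

draw_geom_transform <- function(method, h, w, config) {
  switch(method,
    symmetry = {
      ax <- sample(c("x", "y"), 1L)
      core <- if (ax == "x") diag(c(-1, 1, 1)) else diag(c(1, -1, 1))
      list(mat = affine_about_center(core, h, w),
           info = list(axis = ax))
    },
    pan = {
      dy <- round(runif(1, -config$pan_range, config$pan_range) * h)
      dx <- round(runif(1, -config$pan_range, config$pan_range) * w)
      list(mat = rbind(c(1, 0, dy), c(0, 1, dx), c(0, 0, 1)),
           info = list(dy = dy, dx = dx))
    },
    scale = {
      s <- runif(1, config$scale_range[1L], config$scale_range[2L])
      list(mat = affine_about_center(diag(c(s, s, 1)), h, w),
           info = list(s = s))
    },
    rotate = {
      a <- runif(1, -config$rot_range, config$rot_range) * pi / 180
      core <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
      list(mat = affine_about_center(core, h, w),
           info = list(degrees = a * 180 / pi))
    },
    crop = {
      s <- runif(1, config$crop_range[1L], config$crop_range[2L])
      # random sub-window of fraction s zoomed back to full size:
      # out = (src - corner) / s
      cy <- runif(1, 0, (h - 1) * (1 - s))
      cx <- runif(1, 0, (w - 1) * (1 - s))
      mat <- rbind(c(1 / s, 0, -cy / s),
                   c(0, 1 / s, -cx / s),
                   c(0, 0, 1))
      list(mat = mat, info = list(s = s, cy = cy, cx = cx))
    },
    NULL
  )
}

# Apply the recorded affine map (a forward 3x3 matrix) to an image or label.
warp_scene_raster <- function(raster, forward, interp, fill) {
  d <- dim(raster)
  if (length(d) == 2L) {
    out <- warp_scene_raster(array(raster, c(d, 1L)), forward, interp, fill)
    return(matrix(out, d[1L], d[2L]))
  }
  inv <- solve(forward)
  m <- inv[1:2, , drop = FALSE]
  warp_affine_cpp(raster, m, as.integer(interp == "bilinear") , fill,
                  d[1:2])
}

#' Replay the geometric part of a recorded augmentation on a label
#'
#' Used to check image/label congruence: warping the source label through
#' the transform recorded in an augmented scene must reproduce that scene's
#' label exactly.
#'
#' @param label Source integer class map.
#' @param transform The `transform` element of an augmented scene.
#' @return An integer class map.
#' @export
replay_transform <- function(label, transform) {
  out <- warp_scene_raster(label, transform$affine, "nearest", 4)
  matrix(as.integer(out), nrow(label), ncol(label))
}

#' Augment one scene
#'
#' Produces the original plus `expansion_factor - 1` augmented variants.
#' Every variant records the composed affine map and the methods used in
#' its `transform` element.
#'
#' @param scene A scene.
#' @param config An [augment_config()].
#' @param seed Stream seed for this sample.
#' @param materialise If `FALSE`, draw the identical seeded method
#'   compositions and transforms but skip the pixel work, returning an
#'   inventory of the variants (with `transform` records and `NULL`
#'   rasters). Useful for manifests and count audits of large surveys.
#' @return A list of `expansion_factor` scenes, all of the input size.
#' @export
augment_sample <- function(scene, config = augment_config(),
                           seed = config$seed, materialise = TRUE) {
  stopifnot_scene(scene)
  h <- nrow(scene$label)
  w <- ncol(scene$label)
  nva_fill <- scene$params$base_color["NVA", ] %||% default_base_colors()["NVA", ]
  orig <- scene
  orig$transform <- list(affine = affine_identity(), methods = character())
  variants <- vector("list", config$expansion_factor)
  variants[[1L]] <- orig
  if (config$expansion_factor == 1L) return(variants)
  with_seed(seed, {
    for (v in 2:config$expansion_factor) {
      k <- sample(1:3, 1L)
      methods <- sample(aug_methods, k)
      forward <- affine_identity()
      img <- scene$image
      geom_used <- FALSE
      hsv_f <- NULL
      noise_drawn <- FALSE
      for (mth in methods) {
        if (mth %in% c("symmetry", "pan", "scale", "rotate", "crop")) {
          g <- draw_geom_transform(mth, h, w, config)
          forward <- g$mat %*% forward
          geom_used <- TRUE
        } else if (mth == "hsv") {
          hsv_f <- runif(3, config$hsv_range[1L], config$hsv_range[2L])
        } else if (mth == "noise") {
          noise_drawn <- TRUE
        }
      }
      lab <- scene$label
      noise_seed <- if (noise_drawn) runif(1) else NULL
      if (materialise) {
        if (geom_used) {
          # bilinear output of an in-range image stays in range; no clamp
          img <- warp_scene_raster(img, forward, "bilinear", nva_fill)
          lab <- matrix(as.integer(
            warp_scene_raster(scene$label, forward, "nearest", 4)), h, w)
        }
        if (!is.null(hsv_f)) {
          img <- hsv_scale_cpp(img, hsv_f[1L], hsv_f[2L], hsv_f[3L])
        }
        if (noise_drawn) {
          img <- gauss_noise_add_cpp(img, config$noise_mean * 255,
                                     sqrt(config$noise_var) * 255,
                                     noise_seed)
        }
      } else {
        img <- NULL
        lab <- NULL
      }
      out <- scene
      out$image <- img
      out$label <- lab
      out$size <- c(h, w)
      out$transform <- list(affine = forward, methods = methods,
                            hsv = hsv_f,
                            noise = noise_drawn)
      variants[[v]] <- out
    }
  })
  variants
}

#' Augment a dataset
#'
#' Expands every sample by `expansion_factor` (default 6, taking 2,500
#' originals to 15,000). Per-sample random streams are derived from
#' (config seed, sample index), so the expansion is reproducible and
#' order-independent.
#'
#' @param ds A survey tibble.
#' @param config An [augment_config()].
#' @return A tibble with `expansion_factor * nrow(ds)` rows and columns
#'   `scene_id`, `source_id`, `variant`, `domain`, `scene`.
#' @export
augment_dataset <- function(ds, config = augment_config()) {
  if (nrow(ds) == 0L) abort("dataset is empty.")
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    vs <- augment_sample(ds$scene[[i]], config,
                         seed = derive_seed(config$seed, i))
    tibble(
      scene_id = sprintf("%s_a%d", ds$scene_id[i],
                         seq_along(vs) - 1L),
      source_id = ds$scene_id[i],
      variant = seq_along(vs) - 1L,
      domain = ds$domain[i],
      scene = vs
    )
  })
  bind_rows(rows)
}
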