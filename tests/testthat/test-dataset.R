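test_that("palette codec round-trips and rejects off-palette pixels", {
  pal <- vegetation_palette()
  expect_equal(unname(pal["tree", ]), c(0, 0, 255))
  expect_equal(unname(pal["NVA", ]), c(255, 0, 255))
  expect_equal(anyDuplicated(pal), 0)

  set.seed(3)
  lab <- matrix(sample(1:4, 30 * 20, TRUE), 30, 20)
  enc <- encode_label(lab)
  expect_identical(decode_label(enc), lab)
  expect_equal(enc[1, 1, ], unname(pal[lab[1, 1], ]))

  # single named pixel: (0,0,255) is tree
  one <- array(c(0, 0, 255), c(1, 1, 3))
  expect_equal(decode_label(one)[1, 1], 1L)

  bad <- enc
  bad[3, 5, ] <- c(10, 10, 10)
  expect_error(decode_label(bad), "\\(3, 5\\)")
  expect_error(encode_label(matrix(5L, 2, 2)), "1..4")
})

test_that("random crops take identical image/label windows", {
  set.seed(8)
  big_lab <- matrix(sample(1:4, 450 * 500, TRUE), 450, 500)
  big_img <- encode_label(big_lab)
  crops <- crop_samples(big_img, big_lab, size = 400, n = 5, seed = 2)
  expect_equal(nrow(crops), 5)
  for (k in 1:5) {
    sc <- crops$scene[[k]]
    expect_equal(dim(sc$image), c(400L, 400L, 3L))
    expect_identical(decode_label(sc$image), sc$label)
  }
  same <- crop_samples(big_img, big_lab, size = 400, n = 2, seed = 9)
  again <- crop_samples(big_img, big_lab, size = 400, n = 2, seed = 9)
  expect_identical(same$scene[[1]]$image, again$scene[[1]]$image)

  full <- crop_samples(big_img[1:400, 1:400, ], big_lab[1:400, 1:400],
                       size = 400, n = 3, seed = 1)
  expect_identical(full$scene[[1]]$label, full$scene[[3]]$label)

  expect_error(crop_samples(big_img, big_lab, size = 223), "224")
  expect_error(crop_samples(big_img, big_lab, size = 460), "exceeds")
})

test_that("splits form a seeded 4:1:1 partition with remainder to train", {
  ds <- tibble::tibble(scene_id = sprintf("s%05d", 1:15000),
                       scene = as.list(1:15000))
  sp <- split_dataset(ds, seed = 3)
  expect_equal(vapply(sp, nrow, 0),
               c(train = 10000, validation = 2500, test = 2500))
  ids <- sort(unname(unlist(lapply(sp, `[[`, "scene_id"))))
  expect_equal(ids, sort(ds$scene_id))

  tiny <- split_dataset(ds[1:6, ], seed = 1)
  expect_equal(unname(vapply(tiny, nrow, 0)), c(4, 1, 1))

  odd <- split_dataset(ds[1:20, ], seed = 1)
  expect_equal(unname(vapply(odd, nrow, 0)), c(14, 3, 3))

  expect_identical(split_dataset(ds[1:60, ], seed = 5),
                   split_dataset(ds[1:60, ], seed = 5))
  expect_error(split_dataset(ds[1:5, ]), "at least 6")
})

test_that("augmentation yields the expansion factor at the input size", {
  sc <- generate_scene(toy_params(seed = 2, size = 64L), 2)
  vs <- augment_sample(sc, augment_config(seed = 4), seed = 11)
  expect_length(vs, 6)
  for (v in vs) {
    expect_equal(dim(v$image), c(64L, 64L, 3L))
    expect_equal(dim(v$label), c(64L, 64L))
    expect_true(all(v$label %in% 1:4))
  }
  expect_identical(vs[[1]]$image, sc$image)
  vs2 <- augment_sample(sc, augment_config(seed = 4), seed = 11)
  expect_identical(vs, vs2)
})

test_that("every augmented pair is image/label congruent via its transform", {
  sc <- generate_scene(toy_params(seed = 6, size = 64L), 6)
  for (s in 1:5) {
    vs <- augment_sample(sc, augment_config(seed = s), seed = s)
    for (v in vs) {
      expect_identical(replay_transform(sc$label, v$transform), v$label)
    }
  }
})

test_that("photometric-only variants keep the label bit-identical", {
  sc <- generate_scene(toy_params(seed = 12, size = 64L), 12)
  geom <- c("symmetry", "pan", "scale", "rotate", "crop")
  found <- FALSE
  for (s in 1:10) {
    vs <- augment_sample(sc, augment_config(seed = s), seed = s)
    for (v in vs[-1]) {
      if (!any(v$transform$methods %in% geom)) {
        found <- TRUE
        expect_identical(v$label, sc$label)
      }
    }
  }
  expect_true(found)
})

test_that("a symmetry warp is an involution", {
  sc <- generate_scene(toy_params(seed = 13, size = 48L), 13)
  m <- mtpi:::affine_about_center(diag(c(-1, 1, 1)), 48, 48)
  once <- mtpi:::warp_scene_raster(sc$image, m, "nearest", c(0, 0, 0))
  twice <- mtpi:::warp_scene_raster(once, m, "nearest", c(0, 0, 0))
  expect_equal(twice, sc$image)
})

test_that("dataset augmentation multiplies counts and is reproducible", {
  sv <- generate_survey(toy_params(size = 48L), n_scenes = 3, seed = 5)
  cfg <- augment_config(seed = 7)
  aug <- augment_dataset(sv, cfg)
  expect_equal(nrow(aug), 18)
  expect_equal(unname(table(aug$source_id)), rep(6L, 3),
               ignore_attr = TRUE)
  aug2 <- augment_dataset(sv, cfg)
  expect_identical(aug$scene[[10]], aug2$scene[[10]])

  one <- augment_dataset(sv[2, ], augment_config(expansion_factor = 6,
                                                 seed = 7))
  expect_equal(nrow(one), 6)
  idty <- augment_dataset(sv, augment_config(expansion_factor = 1))
  expect_equal(nrow(idty), 3)
  expect_identical(idty$scene[[2]]$image, sv$scene[[2]]$image)
})
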