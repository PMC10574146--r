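test_that("scene generation is a pure function of params and seed", {
  p <- toy_params(seed = 3)
  s1 <- generate_scene(p, 7)
  s2 <- generate_scene(p, 7)
  expect_identical(s1, s2)
  s3 <- generate_scene(p, 8)
  expect_false(identical(s1$image, s3$image))
})

test_that("realised class areas track the requested mixture", {
  p <- toy_params(size = 96L)
  for (seed in 1:20) {
    lab <- generate_scene(p, seed)$label
    frac <- tabulate(lab, 4) / length(lab)
    expect_true(all(abs(frac - 0.25) < 0.10))
  }
  skewed <- scene_params(height = 96, width = 96,
                         class_mix = c(0.55, 0.2, 0.15, 0.1))
  frac <- tabulate(generate_scene(skewed, 5)$label, 4) / 96^2
  expect_true(all(abs(frac - c(0.55, 0.2, 0.15, 0.1)) < 0.10))
})

test_that("degenerate mixtures and invalid parameters are handled", {
  one <- scene_params(height = 64, width = 64, class_mix = c(1, 0, 0, 0))
  expect_true(all(generate_scene(one, 2)$label == 1L))
  expect_error(scene_params(class_mix = c(0.5, 0.5, 0.5, -0.5)), "class_mix")
  expect_error(scene_params(class_mix = c(0.3, 0.3, 0.3, 0.2)), "class_mix")
  expect_error(scene_params(height = 32), "48")
})

test_that("the identity shift is bit-exact and labels are never touched", {
  sc <- generate_scene(toy_params(seed = 9), 9)
  expect_identical(apply_season_shift(sc, identity_shift()), sc)
  sh <- season_shift(60, 0.8, 0.9, 1.4)
  out <- apply_season_shift(sc, sh)
  expect_identical(out$label, sc$label)
  expect_false(identical(out$image, sc$image))
})

test_that("unflagged classes keep their pixels bit-exactly", {
  sc <- generate_scene(toy_params(seed = 4), 4)
  sh <- season_shift(90, 0.7, 0.8, 1.5,
                     per_class_flags = c(TRUE, TRUE, TRUE, FALSE))
  out <- apply_season_shift(sc, sh)
  nva <- sc$label == 4L
  for (ch in 1:3) {
    expect_identical(out$image[, , ch][nva], sc$image[, , ch][nva])
  }
  expect_false(identical(out$image[, , 1][!nva], sc$image[, , 1][!nva]))
})

test_that("a brightness gain below one strictly darkens flagged pixels", {
  sc <- generate_scene(toy_params(seed = 5), 5)
  sh <- season_shift(0, 0.6, 1, 1, per_class_flags = rep(TRUE, 4))
  out <- apply_season_shift(sc, sh)
  v_in <- apply(sc$image, c(1, 2), max)
  v_out <- apply(out$image, c(1, 2), max)
  expect_lt(mean(v_out), mean(v_in))
})

test_that("surveys are reproducible with per-scene derived seeds", {
  p <- toy_params(size = 48L)
  s1 <- generate_survey(p, n_scenes = 4, seed = 21)
  s2 <- generate_survey(p, n_scenes = 4, seed = 21)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 4)
  expect_equal(nrow(generate_survey(p, n_scenes = 1, seed = 1)), 1)
  expect_error(generate_survey(p, n_scenes = 0), "at least 1")
  # scene i is re-derivable in isolation
  lone <- generate_scene(p, seed = mtpi:::derive_seed(21, 3))
  expect_identical(s1$scene[[3]]$image, lone$image)
})

test_that("surveys round-trip through paired PNGs", {
  dir <- withr::local_tempdir()
  sv <- generate_survey(toy_params(size = 48L), n_scenes = 2, seed = 2)
  write_survey(sv, dir)
  expect_true(file.exists(file.path(dir, "scene_00001.img.png")))
  back <- read_survey(dir)
  expect_equal(nrow(back), 2)
  expect_identical(back$scene[[1]]$label, sv$scene[[1]]$label)
  expect_equal(back$scene[[1]]$image, round(sv$scene[[1]]$image),
               tolerance = 1e-8)
})

test_that("the default shift configuration loads from the versioned file", {
  sh <- default_season_shift()
  expect_s3_class(sh, "season_shift")
  expect_false(mtpi:::is_identity_shift(sh))
  expect_false(sh$per_class_flags[4])
})

test_that("stronger texture-contrast distortion never helps a source net", {
  # a fixed source-trained net, evaluated on targets whose shift differs
  # only in the texture-contrast gain: WKs must not increase with the gain
  for (seed in 1:3) {
    p <- scene_params(height = 48, width = 48, seed = seed)
    sv <- generate_survey(p, n_scenes = 24, seed = mtpi:::derive_seed(seed, 1L))
    net <- build_net(net_spec(depth = 3, base_channels = 8, taper = 1,
                              input_size = 48, seed = mtpi:::derive_seed(seed, 2L)))
    fit <- train_net(net, sv, train_config(max_iterations = 150,
                                           conv_tol = 1e-9,
                                           seed = mtpi:::derive_seed(seed, 3L)))
    base <- default_season_shift()
    wks <- vapply(c(1, 1.6, 2.4), function(g) {
      sh <- season_shift(base$hue_shift, base$brightness_gain,
                         base$saturation_gain, g)
      tg <- generate_survey(p, n_scenes = 6, shift = sh,
                            seed = mtpi:::derive_seed(seed, 4L))
      screen_dataset(fit$net, tg)$WKs
    }, 0)
    expect_true(all(diff(wks) <= 0.02))
  }
})
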