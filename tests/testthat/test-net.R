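test_that("builds are deterministic and parameter counts are analytic", {
  spec <- net_spec(depth = 3, base_channels = 8, taper = 1, input_size = 48,
                   seed = 5)
  n1 <- build_net(spec)
  n2 <- build_net(spec)
  expect_identical(n1, n2)

  # hand-computed: conv1 3->8 (224), conv2/3 8->8 (584 each), head 8->4 (36)
  lst <- layer_sizes(n1)
  expect_equal(mtpi:::ls_at(lst, 0L), 224 + 584 + 584 + 36)
  expect_equal(mtpi:::ls_at(lst, -1L), 36)
  expect_equal(mtpi:::ls_at(lst, 1L), 584 + 584 + 36)

  fw <- mtpi:::net_forward(n1, array(0, c(48, 48, 3)))
  expect_true(all(is.finite(fw$logits)))
  expect_equal(dim(fw$logits), c(48L, 48L, 4L))
})

test_that("transfer-point catalog follows forward order with cumulative sums", {
  net <- build_net(net_spec(depth = 4, input_size = 48, seed = 2))
  cat <- enumerate_tps(net)
  expect_equal(cat$tp, 1:4)
  expect_equal(cat$layer, sprintf("relu_%d", 1:4))
  expect_equal(cat$cum_frozen, cumsum(cat$params))

  lst <- layer_sizes(net, cat)
  ls <- lst$ls[lst$x >= 0]
  expect_true(all(diff(ls) <= 0))
  expect_true(all(lst$ls >= mtpi:::ls_at(lst, -1L)))
  # brute-force group walk: LSx = sum of unfrozen parameter groups
  for (x in 0:4) {
    frozen <- seq_len(x)
    manual <- sum(vapply(seq_along(net$convs), function(s) {
      if (s %in% frozen) 0 else length(net$convs[[s]]$w) +
        length(net$convs[[s]]$b)
    }, 0)) + length(net$head$w) + length(net$head$b)
    expect_equal(mtpi:::ls_at(lst, x), manual)
  }
})

test_that("class weights are inverse-frequency, normalised, scale-free", {
  expect_equal(class_weights(rep(1:4, each = 100)), rep(1, 4))
  w <- class_weights(rep(1:4, c(900, 50, 25, 25)))
  counts <- c(900, 50, 25, 25)
  expect_equal(w, (1 / counts) * 4 / sum(1 / counts))
  expect_equal(which.max(w), 3L)
  expect_equal(class_weights(rep(1:4, 2 * counts)), w)
  expect_error(class_weights(rep(1:3, 10)), "NVA")
})

test_that("freezing matches the layer-size table at every transfer point", {
  net <- build_net(net_spec(depth = 5, input_size = 48, seed = 7))
  lst <- layer_sizes(net)
  for (x in c(-1L, 0L, 1L, 2L, 3L, 4L, 5L)) {
    expect_equal(trainable_params(freeze(net, x)), mtpi:::ls_at(lst, x))
  }
  fr <- freeze(net, -1L)
  expect_true(all(!vapply(fr$convs, function(l) l$trainable, TRUE)))
  expect_true(fr$head$trainable)
  expect_error(freeze(net, 6L), "must be in")
  expect_error(freeze(net, -2L), "must be in")
})

test_that("training lowers the loss, is seed-reproducible, honours freezes", {
  p <- toy_params(seed = 31, size = 48L)
  scenes <- generate_survey(p, n_scenes = 6, seed = 31)
  net <- build_net(net_spec(depth = 3, base_channels = 8, taper = 1,
                            input_size = 48, seed = 8))
  cfg <- train_config(max_iterations = 60, conv_tol = 1e-9, seed = 3)
  fit1 <- train_net(net, scenes, cfg)
  fit2 <- train_net(net, scenes, cfg)
  expect_identical(fit1$trace$loss, fit2$trace$loss)
  expect_identical(fit1$net, fit2$net)
  expect_lt(mean(tail(fit1$trace$loss, 10)), fit1$trace$loss[1])

  frozen <- freeze(net, 2L)
  fit3 <- train_net(frozen, scenes, cfg)
  expect_identical(fit3$net$convs[[1]]$w, net$convs[[1]]$w)
  expect_identical(fit3$net$convs[[2]]$w, net$convs[[2]]$w)
  expect_false(identical(fit3$net$convs[[3]]$w, net$convs[[3]]$w))
  expect_false(identical(fit3$net$head$w, net$head$w))
})

test_that("prediction is a deterministic argmax into 1..4", {
  sc <- generate_scene(toy_params(seed = 41, size = 48L), 41)
  net <- build_net(net_spec(depth = 2, input_size = 48, seed = 9))
  p1 <- predict_scene(net, sc$image)
  expect_identical(p1, predict_scene(net, sc$image))
  expect_true(all(p1 %in% 1:4))
  expect_equal(dim(p1), dim(sc$label))
  expect_error(predict_scene(net, sc$label), "H x W x 3")
  # ties break toward the lower class index
  tied <- net
  for (s in seq_along(tied$convs)) {
    tied$convs[[s]]$w[] <- 0
    tied$convs[[s]]$b[] <- 0
  }
  tied$head$w[] <- 0
  tied$head$b[] <- 0
  expect_true(all(predict_scene(tied, sc$image) == 1L))
})

test_that("checkpoints round-trip through save/load", {
  dir <- withr::local_tempdir()
  net <- build_net(net_spec(depth = 2, input_size = 48, seed = 10))
  path <- file.path(dir, "net.rds")
  save_net(net, path, config = train_config())
  expect_identical(load_net(path), net)
})
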