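test_that("the cost level bins the trainable fraction into 1..Nlevel", {
  expect_equal(tpi_tp(100, 100, 10), 10L)
  expect_equal(tpi_tp(0, 100, 10), 1L)
  expect_equal(tpi_tp(25, 100, 10), 3L)
  expect_equal(tpi_tp(c(100, 50, 0), 100, 10), c(10L, 6L, 1L))
  # literal printed form: frozen fraction instead of trainable fraction
  expect_equal(tpi_tp(100, 100, 10, form = "literal"), 1L)
  expect_equal(tpi_tp(0, 100, 10, form = "literal"), 10L)
  expect_equal(tpi_tp(75, 100, 10, form = "literal"), 3L)
  expect_error(tpi_tp(101, 100), "lsx")
  expect_error(tpi_tp(10, 100, nlevel = 1), "nlevel")
})

test_that("TPI is the accuracy potential over the cost level", {
  expect_equal(tpi(0.8, 4), 0.2)
  expect_equal(tpi(0, 7), 0)
  expect_equal(tpi(1, 1), 1)
  expect_error(tpi(0.5, 0), ">= 1")
  expect_error(tpi(1.2, 2), "0, 1")
})

test_that("TP0 is the TPI argmax with ties toward the deepest point", {
  cv <- tibble::tibble(x = 1:3, ls = c(30, 20, 10), tpi_tp = c(3, 2, 1),
                       tpi_wks = c(0.3, 1, 0.3), tpi = c(0.1, 0.5, 0.3))
  expect_equal(select_tp0(cv), 2L)
  cv$tpi <- c(0.1, 0.5, 0.5)
  expect_equal(select_tp0(cv), 3L)
  expect_error(select_tp0(cv[0, ]), "empty")
})

test_that("the sample-size rule carries the pre-training ratio over", {
  cond <- tds_rule(500000, 10000, 5000000)
  expect_equal(cond$tds0, 1000L)
  expect_equal(cond$kpre, 0.002)
  expect_equal(tds_rule(5000000, 10000, 5000000)$tds0, 10000L)
  expect_equal(tds_rule(10, 10, 5000000)$tds0, 1L)
  expect_warning(cond2 <- tds_rule(500000, 10000, 5000000, available = 100),
                 "capped")
  expect_equal(cond2$tds0, 100L)
  expect_true(cond2$capped)
  expect_error(tds_rule(-1, 10, 10), "positive")
})

test_that("screening maps the kappa bands onto the three decisions", {
  expect_equal(mtpi:::screen_decision(0.85), "skip")
  expect_equal(mtpi:::screen_decision(0.8), "skip")
  expect_equal(mtpi:::screen_decision(0.7), "borderline")
  expect_equal(mtpi:::screen_decision(0.59), "transfer")
})

test_that("an indicator net maps its layer to the exact label", {
  net <- indicator_net()
  scenes <- lapply(1:4, function(i) palette_scene(48L))
  probe <- probe_config(calibration_n = 2, eval_n = 2, seed = 1)
  maps <- tpi_mapping(net, 1L, scenes, probe)
  ev <- attr(maps, "evaluation")
  for (i in seq_along(maps)) {
    expect_identical(maps[[i]], ev[[i]]$label)
  }
  expect_equal(tpi_wks(net, 1L, scenes, probe), 1)
  # the pass-through second stage preserves the indicators
  expect_equal(tpi_wks(net, 2L, scenes, probe), 1)
  # the linear probe alternative also recovers the label exactly
  expect_equal(tpi_wks(net, 1L, scenes,
                       probe_config(calibration_n = 2, eval_n = 2,
                                    rule = "linear", seed = 1)), 1)
})

test_that("randomly permuted channel assignments destroy the mapping", {
  net <- indicator_net()
  sc <- palette_scene(48L)
  act <- mtpi:::layer_activation(net, sc, 1L)
  wks <- numeric(20)
  set.seed(42)
  for (r in 1:20) {
    perm <- sample(1:4)
    model <- list(rule = "standardised", assign = perm)
    map <- mtpi:::apply_probe(act, model, 4L)
    cm <- confusion_matrix(map, sc$label)
    wks[r] <- kappa(cm)$WKs
  }
  # identity or partially-fixed permutations score higher; the average
  # over random permutations sits near chance level
  expect_lt(mean(wks), 0.3)
  expect_lt(median(wks), 0.1)
})

test_that("TPI curves have one in-range record per transfer point", {
  net <- indicator_net()
  scenes <- lapply(1:6, function(i) {
    sc <- generate_scene(toy_params(seed = i, size = 48L), i)
    sc
  })
  probe <- probe_config(calibration_n = 3, eval_n = 3, seed = 2)
  cv <- tpi_curve(net, scenes, probe, nlevel = 10)
  expect_equal(nrow(cv), 2)
  expect_equal(cv$x, 1:2)
  expect_true(all(cv$tpi >= 0 & cv$tpi <= 1))
  expect_true(all(cv$tpi_tp %in% 1:10))
  expect_true(all(diff(cv$tpi_tp) <= 0))
  expect_equal(cv$tpi, cv$tpi_wks / cv$tpi_tp)
})

test_that("curve averaging is pointwise and permutation-invariant", {
  net <- indicator_net()
  base <- tibble::tibble(x = 1:2, ls = c(100, 10), tpi_tp = c(5L, 1L))
  mk <- function(w) {
    cv <- dplyr::mutate(base, tpi_wks = w, tpi = w / tpi_tp)
    class(cv) <- c("tpi_curve", class(cv))
    cv
  }
  a <- mk(c(0.2, 0.4))
  b <- mk(c(0.4, 0.8))
  avg <- average_curves(list(a, b))
  expect_equal(avg$tpi, (a$tpi + b$tpi) / 2)
  expect_equal(average_curves(list(b, a))$tpi, avg$tpi)
  expect_equal(average_curves(list(a, a))$tpi, a$tpi)
  bad <- mk(c(0.1, 0.1))
  bad$ls <- c(1, 1)
  expect_error(average_curves(list(a, bad)), "catalog")
})
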