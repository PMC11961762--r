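# U-shaped generator: parameter accounting, shape contracts, determinism.

test_that("analytic parameter count matches the built model exactly", {
  cfg <- tiny_gen_config()
  g <- build_generator(cfg, seed = 1L)
  expect_identical(count_parameters(g), generator_param_count(cfg))
  cfg2 <- generator_config("syn")
  g2 <- build_generator(cfg2, seed = 1L)
  expect_identical(count_parameters(g2), generator_param_count(cfg2))
})

test_that("trivial convolution parameter counts are exact", {
  c1 <- catintell:::new_conv(1L, 3L, 3L)
  expect_identical(catintell:::n_params(catintell:::collect_params(c1)), 12)
  c2 <- catintell:::new_conv(5L, 3L, 32L)
  expect_identical(catintell:::n_params(catintell:::collect_params(c2)), 2432)
})

test_that("parameter count scales quadratically-dominated with width", {
  n16 <- generator_param_count(generator_config("res", base_width = 16L))
  n32 <- generator_param_count(generator_config("res", base_width = 32L))
  n48 <- generator_param_count(generator_config("res", base_width = 48L))
  expect_gt(n32 / n16, 2); expect_lt(n32 / n16, 4)
  expect_gt(n48 / n32, 1.5); expect_lt(n48 / n32, 2.25)
})

test_that("encoder channel ladder doubles per stage", {
  g <- build_generator(generator_config("res"), seed = 0L)
  C <- g$config$base_width
  for (i in seq_len(g$config$stages))
    expect_identical(g$enc[[i]][[1]]$conv5a$cout, C * 2L^(i - 1L))
  expect_identical(g$bott[[1]]$conv5a$cout, C * 2L^g$config$stages)
})

test_that("forward preserves arbitrary spatial sizes and clamps output", {
  g <- build_generator(tiny_gen_config(), seed = 2L)   # 2 stages, stride 4
  for (sz in list(c(16, 16), c(18, 30), c(33, 47))) {
    img <- array(runif(prod(sz) * 3), c(sz, 3))
    out <- gen_forward(g, img)
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
    expect_true(all(is.finite(out)))
  }
  expect_error(gen_forward(g, array(0, c(2, 2, 3))), "at least")
  expect_error(gen_forward(g, array(0, c(16, 16, 2))), "H x W x 3")
})

test_that("an all-zero input yields a finite output", {
  g <- build_generator(tiny_gen_config(), seed = 3L)
  out <- gen_forward(g, array(0, c(16, 16, 3)), clamp = FALSE)
  expect_true(all(is.finite(out)))
})

test_that("initialisation and forward are deterministic for a fixed seed", {
  g1 <- build_generator(tiny_gen_config(), seed = 7L)
  g2 <- build_generator(tiny_gen_config(), seed = 7L)
  expect_identical(g1$in_proj$w$val, g2$in_proj$w$val)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(gen_forward(g1, img), gen_forward(g2, img))
  g3 <- build_generator(tiny_gen_config(), seed = 8L)
  expect_false(identical(g1$in_proj$w$val, g3$in_proj$w$val))
})

test_that("pad_to_stride round-trips exactly", {
  img <- array(runif(250 * 250 * 3), c(250, 250, 3))
  p <- pad_to_stride(img, 16L)
  expect_identical(dim(p$image)[1:2], c(256L, 256L))
  expect_identical(crop_from_pad(p$image, p$crop), img)
  # already divisible: unchanged
  img2 <- array(runif(256 * 256 * 3), c(256, 256, 3))
  p2 <- pad_to_stride(img2, 16L)
  expect_identical(p2$image, img2)
})

test_that("invalid group configurations are rejected", {
  expect_error(generator_config("res", base_width = 5L, dcb_expansion = 1.5),
               "divisible")
  expect_error(catintell:::new_conv(3L, 5L, 4L, groups = 2L), "divisible")
})

test_that("calibration search ranks the frozen defaults first", {
  # small confirmation grid around the frozen defaults
  grid <- expand.grid(gsa = c(8L, 16L), gsb = c(4L, 8L), e = c(2, 4),
                      eg = c(1L, 2L), kd = c(2L, 4L), ku = c(4L, 6L),
                      ss = c("conv", "add"), sm = c("concat", "add"),
                      ln2 = c(TRUE, FALSE), stringsAsFactors = FALSE)
  res <- calibrate_generator_knobs(grid)
  best <- res[1, ]
  expect_identical(best$n_exact, 5L)
  expect_identical(c(best$gsa, best$gsb), c(16L, 4L))
  expect_identical(best$e, 4)
  expect_identical(best$counts, "12.72 3.78 26.82 3.71 46.27")
  # and only one setting in the grid is fully exact
  expect_identical(sum(res$n_exact == 5L), 1L)
})
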