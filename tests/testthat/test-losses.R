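# Pixel, perceptual, identity and adversarial losses, and their totals.

test_that("smooth L1 matches its closed forms and basic properties", {
  a <- array(0.3, c(4, 4, 3))
  expect_identical(smooth_l1(a, a), 0)
  expect_identical(smooth_l1(a, a - 1), 0.5)       # knee
  expect_identical(smooth_l1(a, a - 2), 1.5)       # linear branch
  expect_identical(smooth_l1(a, a + 0.5), 0.125)   # quadratic branch
  expect_error(smooth_l1(a, array(0, c(3, 3, 3))), "shape")
  # non-negative, zero iff identical
  set.seed(1)
  x <- array(runif(48), c(4, 4, 3)); y <- array(runif(48), c(4, 4, 3))
  expect_gt(smooth_l1(x, y), 0)
})

test_that("gram matrix has its closed forms, symmetry and PSD", {
  f <- array(0.7, c(5, 6, 1))
  expect_equal(gram(f), matrix(0.49, 1, 1), tolerance = 1e-12)
  # two orthogonal sign-alternating channels: zero off-diagonal
  f2 <- array(0, c(2, 2, 2))
  f2[, , 1] <- matrix(c(1, 1, -1, -1), 2)
  f2[, , 2] <- matrix(c(1, -1, 1, -1), 2)
  g2 <- gram(f2)
  # direct summation oracle
  expect_equal(g2[1, 2], sum(f2[, , 1] * f2[, , 2]) / 4, tolerance = 1e-12)
  expect_equal(g2[1, 2], 0, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:5) {
    fr <- array(rnorm(6 * 7 * 4), c(6, 7, 4))
    G <- gram(fr)
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_true(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-10))
  }
})

test_that("perceptual loss with the identity extractor reduces to MSE", {
  idext <- feature_extractor("identity")
  a <- array(0.4, c(8, 8, 3))
  expect_equal(fp_loss(a, a, idext), list(content = 0, style = 0))
  expect_equal(fp_loss(a + 0.1, a, idext)$content, 0.01, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    x <- array(runif(8 * 8 * 3), c(8, 8, 3))
    y <- array(runif(8 * 8 * 3), c(8, 8, 3))
    expect_equal(fp_loss(x, y, idext)$content, mean((x - y)^2),
                 tolerance = 1e-6)
  }
  expect_error(fp_loss(a, array(0, c(4, 4, 3)), idext), "shape")
})

test_that("the deep extractor is seeded, tapped after each pooling stage", {
  ex <- feature_extractor("vgg19", taps = 1:3, seed = 4L)
  ex2 <- feature_extractor("vgg19", taps = 1:3, seed = 4L)
  expect_identical(ex$layers[[1]]$w$val, ex2$layers[[1]]$w$val)
  x <- catintell:::ag_const(catintell:::as4d(array(runif(32 * 32 * 3),
                                                   c(32, 32, 3))))
  catintell:::ag_tape_reset(recording = FALSE)
  f <- catintell:::extractor_forward(ex, x)
  expect_length(f, 3)
  expect_identical(dim(f[[1]]$val)[1:3], c(16L, 16L, 64L))
  expect_identical(dim(f[[2]]$val)[1:3], c(8L, 8L, 128L))
  expect_identical(dim(f[[3]]$val)[1:3], c(4L, 4L, 256L))
  v1 <- fp_loss(array(runif(32 * 32 * 3), c(32, 32, 3)),
                array(runif(32 * 32 * 3), c(32, 32, 3)), ex)
  expect_true(v1$content > 0 && v1$style >= 0 && is.finite(v1$style))
})

test_that("identity loss equals the composition of forward and smooth L1", {
  g <- build_generator(tiny_gen_config(), seed = 5L)
  img <- generate_phantom(phantom_config(height = 64, width = 64,
                                         seed = 5L))$image
  expect_equal(identity_loss(g, img),
               smooth_l1(img, gen_forward(g, img, clamp = FALSE)),
               tolerance = 1e-12)
})

test_that("generator GAN loss matches BCE closed forms and is monotone", {
  expect_equal(gan_loss_generator(1, 1), 0, tolerance = 1e-5)
  expect_equal(gan_loss_generator(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(gan_loss_generator(0.5, 0.5), log(2), tolerance = 1e-12)
  # clamping keeps the loss finite at the boundary
  expect_true(is.finite(gan_loss_generator(1, 0)))
  # with hard labels, strictly decreasing in p_out
  p <- seq(0.05, 0.95, by = 0.05)
  v <- vapply(p, function(q) gan_loss_generator(0.7, q, hard_labels = TRUE), 0)
  expect_true(all(diff(v) < 0))
})

test_that("total loss applies the published weightings and is linear", {
  comp1 <- list(pixel = 1, fp = 1, ide = 1, gan = 1)
  expect_equal(total_loss(comp1, loss_weights("res"))$total, 1.12,
               tolerance = 1e-12)
  expect_equal(total_loss(comp1, loss_weights("syn"))$total, 1.21,
               tolerance = 1e-12)
  comp0 <- list(pixel = 0, fp = 0, ide = 0, gan = 0)
  expect_identical(total_loss(comp0, loss_weights("res"))$total, 0)
  expect_error(total_loss(list(pixel = 1, fp = 1, ide = 1),
                          loss_weights("res")), "gan")
  # linearity in each component
  w <- loss_weights("res")
  base <- total_loss(comp1, w)$total
  for (nm in names(comp1)) {
    comp2 <- comp1; comp2[[nm]] <- 3
    delta <- total_loss(comp2, w)$total - base
    expect_equal(delta, 2 * w[[paste0("w_", nm)]],
                 tolerance = 1e-12, info = nm)
  }
  # composite perceptual component: content + style_weight * style
  compc <- list(pixel = 0, fp = list(content = 0.2, style = 0.3), ide = 0,
                gan = 0)
  expect_equal(total_loss(compc, loss_weights("res", style_weight = 2))$total,
               0.1 * (0.2 + 2 * 0.3), tolerance = 1e-12)
})
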