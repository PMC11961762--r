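# Reverse-mode gradients checked against central finite differences.

fd_grad <- function(f, x, eps = 1e-6, idx = seq_len(min(length(x), 20))) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xp <- x; xm <- x
    xp[idx[k]] <- xp[idx[k]] + eps
    xm[idx[k]] <- xm[idx[k]] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

grad_of <- function(build_loss, param_val) {
  catintell:::ag_tape_reset(recording = TRUE)
  p <- catintell:::ag_param(param_val)
  loss <- build_loss(catintell:::ag_leaf(p))
  catintell:::ag_backward(loss)
  p$grad
}

test_that("grouped strided convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  w <- array(rnorm(3 * 3 * 2 * 4) * 0.5, c(3, 3, 2, 4))   # groups = 2
  b <- rnorm(4)
  for (stride in c(1L, 2L)) {
    f_w <- function(wv) mean(catintell:::.cpp_conv2d_fw(
      x, dim(x), wv, dim(w), b, stride, 1L, 2L, FALSE)$y^2)
    gw <- grad_of(function(wn) {
      y <- catintell:::ag_conv2d(catintell:::ag_const(x), wn,
                                 catintell:::ag_const(b), stride = stride,
                                 pad = 1L, groups = 2L)
      catintell:::ag_mse(y, catintell:::ag_const(y$val * 0))
    }, w)
    expect_equal(gw[1:20], fd_grad(f_w, w), tolerance = 1e-6,
                 info = paste("stride", stride))
  }
  # input gradient
  f_x <- function(xv) mean(catintell:::.cpp_conv2d_fw(
    xv, dim(x), w, dim(w), b, 1L, 1L, 2L, FALSE)$y^2)
  gx <- grad_of(function(xn) {
    y <- catintell:::ag_conv2d(xn, catintell:::ag_const(w),
                               catintell:::ag_const(b), stride = 1L,
                               pad = 1L, groups = 2L)
    catintell:::ag_mse(y, catintell:::ag_const(y$val * 0))
  }, x)
  expect_equal(gx[1:20], fd_grad(f_x, x), tolerance = 1e-6)
})

test_that("transposed convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  w <- array(rnorm(4 * 4 * 1 * 4) * 0.5, c(4, 4, 1, 4))   # depthwise, k4
  f_w <- function(wv) mean(catintell:::.cpp_tconv2d_fw(
    x, dim(x), wv, dim(w), numeric(0), 2L, 1L, 4L)^2)
  gw <- grad_of(function(wn) {
    y <- catintell:::ag_tconv2d(catintell:::ag_const(x), wn, NULL,
                                stride = 2L, pad = 1L, groups = 4L)
    catintell:::ag_mse(y, catintell:::ag_const(y$val * 0))
  }, w)
  expect_equal(gw[1:20], fd_grad(f_w, w), tolerance = 1e-6)
})

test_that("channel LayerNorm and GELU gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(3 * 3 * 5), c(3, 3, 5, 1))
  gmv <- runif(5, 0.5, 1.5); btv <- rnorm(5)
  f_x <- function(xv) {
    f <- catintell:::.cpp_ln_fw(xv, 9L, 5L, 1L, gmv, btv, 1e-6)
    sum(f$y^3) / 10
  }
  gx <- grad_of(function(xn) {
    y <- catintell:::ag_layernorm_c(xn, catintell:::ag_const(gmv),
                                    catintell:::ag_const(btv))
    # cube through available primitives: y * y * y via mse against 0 would
    # square; use gelu-free direct scalar node instead
    catintell:::ag_node(sum(y$val^3) / 10, list(y), function(n)
      catintell:::.acc(y, n$grad * 3 * y$val^2 / 10))
  }, x)
  expect_equal(gx[1:20], fd_grad(f_x, x), tolerance = 1e-5)
  # gelu
  xv <- rnorm(30)
  f_g <- function(v) sum(catintell:::.cpp_gelu_fw(v)$y^2)
  gg <- grad_of(function(xn) {
    y <- catintell:::ag_gelu(xn)
    catintell:::ag_node(sum(y$val^2), list(y), function(n)
      catintell:::.acc(y, n$grad * 2 * y$val))
  }, xv)
  expect_equal(gg[1:20], fd_grad(f_g, xv), tolerance = 1e-6)
})

test_that("attention-block parameter gradients match finite differences", {
  set.seed(4)
  blk <- catintell:::new_wsb(4L, 2L, 2L)
  tok <- matrix(rnorm(16 * 4), 16, 4)
  run <- function(qkv_w) {
    blk$qkv$w$val <- qkv_w
    catintell:::ag_tape_reset(recording = TRUE)
    out <- catintell:::wsb_apply(blk, catintell:::ag_const(tok), 4L, 4L,
                                 win = 2L, shift = 1L)
    sum(out$val^2)
  }
  w0 <- blk$qkv$w$val
  catintell:::ag_tape_reset(recording = TRUE)
  blk$qkv$w$grad <- NULL
  out <- catintell:::wsb_apply(blk, catintell:::ag_const(tok), 4L, 4L,
                               win = 2L, shift = 1L)
  loss <- catintell:::ag_node(sum(out$val^2), list(out), function(n)
    catintell:::.acc(out, n$grad * 2 * out$val))
  catintell:::ag_backward(loss)
  expect_equal(blk$qkv$w$grad[1:12], fd_grad(run, w0, idx = 1:12),
               tolerance = 1e-5)
})

test_that("smooth L1 and BCE node gradients are correct", {
  set.seed(5)
  a <- array(rnorm(20) * 1.5, c(4, 5))   # straddles the knee
  b <- array(rnorm(20) * 1.5, c(4, 5))
  f <- function(av) {
    d <- av - b; ad <- abs(d)
    mean(ifelse(ad < 1, 0.5 * d^2, ad - 0.5))
  }
  ga <- grad_of(function(an)
    catintell:::ag_smooth_l1(an, catintell:::ag_const(b)), a)
  expect_equal(as.numeric(ga), fd_grad(f, a, idx = 1:20), tolerance = 1e-6)
  # BCE wrt p_out
  fp <- function(p) -(0.7 * log(p) + 0.3 * log(1 - p))
  gp <- grad_of(function(pn) catintell:::ag_bce(pn, 0.7), 0.4)
  expect_equal(as.numeric(gp), fd_grad(fp, 0.4, idx = 1), tolerance = 1e-6)
})
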