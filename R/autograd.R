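# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A computation is recorded on a tape of nodes; each node holds its value,
# its parent nodes and a backward closure that routes the incoming gradient
# to the parents. Image tensors are H x W x C x N arrays (column-major),
# token matrices are T x D. Convolutions run in compiled code; everything
# else is vectorised R.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$recording <- FALSE

ag_tape_reset <- function(recording = TRUE) {
  .ag$tape <- vector("list", 0L)
  .ag$recording <- recording
  invisible(NULL)
}

ag_node <- function(val, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "ag_node"
  if (isTRUE(.ag$recording) && !is.null(backfn))
    .ag$tape[[length(.ag$tape) + 1L]] <- n
  n
}

is_ag_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag_node(x)) x$val else x

ag_const <- function(val) ag_node(val)

# Trainable parameter: a persistent environment with value, gradient
# accumulator and Adam moments.
ag_param <- function(val, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p$name <- name
  class(p) <- "ag_param"
  p
}

# Leaf node referencing a parameter; backward accumulates into the parameter.
ag_leaf <- function(param) {
  n <- ag_node(param$val, parents = list(), backfn = function(n) {
    param$grad <- if (is.null(param$grad)) n$grad else param$grad + n$grad
  })
  # leaves carry a backfn, so they are taped; that is what we want
  n
}

.acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backward pass: seed the loss node with gradient 1 and sweep the tape in
# reverse creation order (a valid reverse topological order).
ag_backward <- function(loss) {
  stopifnot(is_ag_node(loss), length(loss$val) == 1L)
  loss$grad <- 1
  for (i in rev(seq_along(.ag$tape))) {
    n <- .ag$tape[[i]]
    if (!is.null(n$grad) && !is.null(n$backfn)) n$backfn(n)
    # consumed: drop the closure (and any cached workspaces it captured)
    # and large buffers to keep the peak footprint flat
    n$backfn <- NULL
    if (length(n$val) > 1024L) n$val <- NULL
    if (length(n$grad) > 1024L) n$grad <- NULL
    n$parents <- NULL
  }
  invisible(NULL)
}

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3- or 4-d array")
  x
}

## ---- arithmetic ----

ag_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(n) {
    .acc(a, n$grad); .acc(b, n$grad)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$val - b$val, list(a, b), function(n) {
    .acc(a, n$grad); .acc(b, -n$grad)
  })
}

ag_scale <- function(a, s) {
  ag_node(a$val * s, list(a), function(n) .acc(a, n$grad * s))
}

ag_add_scalar_node <- function(a, b) {
  # a, b scalar nodes
  ag_node(a$val + b$val, list(a, b), function(n) {
    .acc(a, n$grad); .acc(b, n$grad)
  })
}

## ---- convolution family ----

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- x$val; wv <- w$val
  bv <- if (is.null(b)) numeric(0) else b$val
  f <- .cpp_conv2d_fw(xv, dim(xv), wv, dim(wv), bv,
                      as.integer(stride), as.integer(pad), as.integer(groups),
                      FALSE)
  # inputs that are plain constants (not parameters, not intermediate
  # results) need no input gradient
  need_gx <- !(is.null(x$backfn) && !length(x$parents))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(f$y, parents, function(n) {
    g <- .cpp_conv2d_bw(xv, dim(xv), wv, dim(wv), n$grad,
                        as.integer(stride), as.integer(pad), as.integer(groups),
                        !is.null(b), f$col, need_gx)
    if (need_gx) .acc(x, g$gx)
    .acc(w, g$gw)
    if (!is.null(b)) .acc(b, g$gb)
  })
}

ag_tconv2d <- function(x, w, b = NULL, stride = 2L, pad = 0L, groups = 1L) {
  xv <- x$val; wv <- w$val
  bv <- if (is.null(b)) numeric(0) else b$val
  y <- .cpp_tconv2d_fw(xv, dim(xv), wv, dim(wv), bv,
                       as.integer(stride), as.integer(pad), as.integer(groups))
  yd <- dim(y)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(n) {
    g <- .cpp_tconv2d_bw(xv, dim(xv), wv, dim(wv), n$grad, yd,
                         as.integer(stride), as.integer(pad), as.integer(groups),
                         !is.null(b))
    .acc(x, g$gx); .acc(w, g$gw)
    if (!is.null(b)) .acc(b, g$gb)
  })
}

ag_avgpool2 <- function(x) {
  xv <- x$val
  y <- .cpp_avgpool2_fw(xv, dim(xv))
  yd <- dim(y)
  ag_node(y, list(x), function(n) {
    .acc(x, .cpp_avgpool2_bw(n$grad, yd, dim(xv)))
  })
}

## ---- shape ops ----

ag_concat_c <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  av <- a$val; bv <- b$val
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- av
  y[, , da[3] + seq_len(db[3]), ] <- bv
  ag_node(y, list(a, b), function(n) {
    .acc(a, n$grad[, , seq_len(da[3]), , drop = FALSE])
    .acc(b, n$grad[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Permutation/reshape through an index map: y <- x[idx], dim(y) <- out_dim.
# idx must be a bijection of seq_along(x).
ag_gather <- function(x, idx, out_dim) {
  y <- x$val[idx]
  dim(y) <- out_dim
  xd <- dim(x$val)
  ag_node(y, list(x), function(n) {
    g <- numeric(prod(xd))
    g[idx] <- n$grad
    dim(g) <- xd
    .acc(x, g)
  })
}

## ---- normalisation and activations ----

# LayerNorm over channels at each pixel of an H x W x C x N tensor.
ag_layernorm_c <- function(x, gamma, beta, eps = 1e-6) {
  xv <- x$val
  d <- dim(xv)
  M <- d[1] * d[2]; C <- d[3]; N <- d[4]
  f <- .cpp_ln_fw(xv, M, C, N, gamma$val, beta$val, eps)
  y <- f$y
  dim(y) <- d
  ag_node(y, list(x, gamma, beta), function(n) {
    b <- .cpp_ln_bw(xv, n$grad, M, C, N, gamma$val, f$mu, f$istd)
    gx <- b$gx
    dim(gx) <- d
    .acc(x, gx)
    .acc(gamma, b$ggamma)
    .acc(beta, b$gbeta)
  })
}

# LayerNorm over the feature dimension of a T x D token matrix.
ag_layernorm_rows <- function(x, gamma, beta, eps = 1e-6) {
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- gamma$val; bv <- beta$val
  y <- sweep(xhat, 2, gv, "*")
  y <- sweep(y, 2, bv, "+")
  ag_node(y, list(x, gamma, beta), function(n) {
    g <- n$grad
    gxhat <- sweep(g, 2, gv, "*")
    m1 <- rowMeans(gxhat)
    m2 <- rowMeans(gxhat * xhat)
    gx <- (gxhat - m1 - xhat * m2) * istd
    .acc(x, gx)
    .acc(gamma, colSums(g * xhat))
    .acc(beta, colSums(g))
  })
}

ag_gelu <- function(x) {
  xv <- x$val
  f <- .cpp_gelu_fw(xv)
  ag_node(f$y, list(x), function(n) {
    .acc(x, .cpp_gelu_bw(xv, f$phi, n$grad))
  })
}

ag_relu <- function(x) {
  xv <- x$val
  pos <- xv > 0
  ag_node(xv * pos, list(x), function(n) .acc(x, n$grad * pos))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(n) .acc(x, n$grad * s * (1 - s)))
}

## ---- matrix ops (attention) ----

ag_matmul <- function(a, b) {
  av <- a$val; bv <- b$val
  ag_node(av %*% bv, list(a, b), function(n) {
    .acc(a, n$grad %*% t(bv))
    .acc(b, t(av) %*% n$grad)
  })
}

ag_linear <- function(x, w, b = NULL) {
  xv <- x$val; wv <- w$val
  y <- xv %*% wv
  if (!is.null(b)) y <- sweep(y, 2, b$val, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(n) {
    .acc(x, n$grad %*% t(wv))
    .acc(w, t(xv) %*% n$grad)
    if (!is.null(b)) .acc(b, colSums(n$grad))
  })
}

ag_softmax_rows <- function(x) {
  xv <- x$val
  e <- exp(xv - apply(xv, 1, max))
  s <- e / rowSums(e)
  ag_node(s, list(x), function(n) {
    dot <- rowSums(n$grad * s)
    .acc(x, s * (n$grad - dot))
  })
}

ag_mean_rows <- function(x) {
  xv <- x$val
  ag_node(matrix(colMeans(xv), 1), list(x), function(n) {
    .acc(x, matrix(n$grad, nrow(xv), ncol(xv), byrow = TRUE) / nrow(xv))
  })
}

## ---- reductions / losses ----

ag_mean_all <- function(x) {
  xv <- x$val
  ag_node(mean(xv), list(x), function(n) {
    .acc(x, array(n$grad / length(xv), dim(xv) %||% length(xv)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth L1 (Huber with unit knee), mean reduction over all elements.
ag_smooth_l1 <- function(a, b) {
  d <- a$val - b$val
  ad <- abs(d)
  inner <- ad < 1
  v <- mean(0.5 * d * d * inner + (ad - 0.5) * !inner)
  ag_node(v, list(a, b), function(n) {
    g <- (d * inner + sign(d) * !inner) * (n$grad / length(d))
    dim(g) <- dim(a$val)
    .acc(a, g); .acc(b, -g)
  })
}

ag_mse <- function(a, b) {
  d <- a$val - b$val
  v <- mean(d * d)
  ag_node(v, list(a, b), function(n) {
    g <- 2 * d * (n$grad / length(d))
    dim(g) <- dim(a$val)
    .acc(a, g); .acc(b, -g)
  })
}

# Generator-side BCE against a (detached) reference probability.
ag_bce <- function(p_out, p_real, eps = 1e-7) {
  p <- min(max(p_out$val, eps), 1 - eps)
  v <- -(p_real * log(p) + (1 - p_real) * log(1 - p))
  ag_node(v, list(p_out), function(n) {
    .acc(p_out, n$grad * (-(p_real / p) + (1 - p_real) / (1 - p)))
  })
}

## ---- parameter collection / optimiser ----

collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "ag_param")) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

n_params <- function(params) sum(vapply(params, function(p) length(p$val), 0))

# Adam step with optional global-norm gradient clipping (fused C++ loop,
# in-place). Returns the pre-clip global gradient norm, invisibly.
adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1L, clip = NULL) {
  invisible(.cpp_adam_step(params, lr, beta1, beta2, eps, as.integer(t),
                           if (is.null(clip)) -1 else clip))
}

# Seeded truncated-normal initialiser (resample outside +-2 sigma).
init_trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}
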