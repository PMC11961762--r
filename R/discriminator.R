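# Window self-attention discriminator.
#
# A lightweight SWIN-style classifier: patch embedding, four stages of
# window-based self-attention blocks (WSB: windowed multi-head attention and
# an MLP, each behind LayerNorm with residual connections; windows shifted
# by half on alternating blocks), 2x2 patch merging between stages, global
# average pooling and a single-logit sigmoid head. Scores are the
# probability that an image belongs to the discriminator's "real" class.

#' Discriminator configuration
#'
#' @param input_size images are bilinearly resized to this square size
#'   before scoring; defaults to the 256-pixel training patch.
#' @param patch_size patch-embedding patch (and stride).
#' @param embed_dim channels after patch embedding; doubles at each merge.
#' @param blocks_per_stage,heads_per_stage per-stage WSB counts and heads.
#' @param window attention window side, in tokens.
#' @param mlp_ratio MLP expansion of the WSB.
#' @return object of class `disc_config`.
#' @export
discriminator_config <- function(input_size = 256L, patch_size = 4L,
                                 embed_dim = 32L,
                                 blocks_per_stage = c(2L, 2L, 2L, 2L),
                                 heads_per_stage = c(1L, 2L, 4L, 8L),
                                 window = 8L, mlp_ratio = 4L) {
  stopifnot(length(blocks_per_stage) == length(heads_per_stage),
            input_size %% (patch_size * 2L^(length(blocks_per_stage) - 1L)) == 0)
  dims <- embed_dim * 2L^(seq_along(blocks_per_stage) - 1L)
  if (any(dims %% heads_per_stage != 0))
    stop("stage dims must be divisible by heads_per_stage")
  structure(list(input_size = as.integer(input_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 heads_per_stage = as.integer(heads_per_stage),
                 window = as.integer(window), mlp_ratio = mlp_ratio),
            class = "disc_config")
}

new_linear <- function(din, dout, bias = TRUE, sd = 0.02) {
  list(w = ag_param(matrix(init_trunc_normal(din * dout, sd), din, dout)),
       b = if (bias) ag_param(numeric(dout)))
}

lin_apply <- function(l, x) ag_linear(x, ag_leaf(l$w), if (!is.null(l$b)) ag_leaf(l$b))

new_wsb <- function(dim, heads, mlp_ratio) {
  list(ln1 = list(g = ag_param(rep(1, dim)), b = ag_param(numeric(dim))),
       qkv = new_linear(dim, 3L * dim),
       proj = new_linear(dim, dim),
       ln2 = list(g = ag_param(rep(1, dim)), b = ag_param(numeric(dim))),
       fc1 = new_linear(dim, mlp_ratio * dim),
       fc2 = new_linear(mlp_ratio * dim, dim),
       heads = heads, dim = dim)
}

#' Build a discriminator
#'
#' @param config a [discriminator_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `disc_model`.
#' @export
build_discriminator <- function(config = discriminator_config(), seed = 0L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ns <- length(config$blocks_per_stage)
  dims <- config$embed_dim * 2L^(seq_len(ns) - 1L)
  stages <- list(); merges <- list()
  for (s in seq_len(ns)) {
    stages[[s]] <- lapply(seq_len(config$blocks_per_stage[s]), function(b)
      new_wsb(dims[s], config$heads_per_stage[s], config$mlp_ratio))
    if (s < ns) merges[[s]] <- new_linear(4L * dims[s], dims[s + 1L])
  }
  model <- list(config = config, seed = as.integer(seed),
                embed = new_conv(config$patch_size, 3L, config$embed_dim,
                                 bias = TRUE),
                stages = stages, merges = merges,
                head_ln = list(g = ag_param(rep(1, dims[ns])),
                               b = ag_param(numeric(dims[ns]))),
                head = new_linear(dims[ns], 1L))
  class(model) <- "disc_model"
  model
}

#' @export
print.disc_model <- function(x, ...) {
  cat(sprintf("window-attention discriminator: %d stages, embed %d, window %d, %.2f M parameters\n",
              length(x$config$blocks_per_stage), x$config$embed_dim,
              x$config$window, count_parameters(x) / 1e6))
  invisible(x)
}

# token index helpers: tokens stored as (H*W) x D matrices, column-major in h
.win_index <- function(H, W, win) {
  # order tokens window by window; returns permutation of 1:(H*W)
  idx <- integer(H * W)
  pos <- 1L
  for (wy in seq_len(W %/% win)) for (wx in seq_len(H %/% win)) {
    for (y in seq_len(win)) {
      h0 <- (wx - 1L) * win; w0 <- (wy - 1L) * win + y - 1L
      idx[pos:(pos + win - 1L)] <- h0 + seq_len(win) + w0 * H
      pos <- pos + win
    }
  }
  idx
}

.roll_index <- function(H, W, sh, sw) {
  # cyclic shift: token at (h, w) moves to ((h - sh) mod H, (w - sw) mod W)
  h <- (seq_len(H) - 1L + sh) %% H
  w <- (seq_len(W) - 1L + sw) %% W
  as.vector(outer(h + 1L, w * H, "+"))
}

wsb_apply <- function(blk, x, H, W, win, shift) {
  d <- blk$dim; nh <- blk$heads; dh <- d %/% nh
  shortcut <- x
  h <- ag_layernorm_rows(x, ag_leaf(blk$ln1$g), ag_leaf(blk$ln1$b))
  if (shift > 0L)
    h <- ag_gather(h, rep(.roll_index(H, W, shift, shift), d) +
                     rep((seq_len(d) - 1L) * H * W, each = H * W), dim(h$val))
  qkv <- lin_apply(blk$qkv, h)
  wi <- .win_index(H, W, win)
  nw <- (H %/% win) * (W %/% win)
  T <- win * win
  # reorder rows window-by-window
  rowperm <- function(node, perm) {
    dmat <- dim(node$val)
    ag_gather(node, rep(perm, dmat[2]) + rep((seq_len(dmat[2]) - 1L) * dmat[1],
                                             each = dmat[1]), dmat)
  }
  qkvw <- rowperm(qkv, wi)
  outs <- vector("list", nw * nh)
  scale <- 1 / sqrt(dh)
  for (w0 in seq_len(nw)) {
    rows <- ((w0 - 1L) * T + 1L):(w0 * T)
    for (hh in seq_len(nh)) {
      cq <- ((hh - 1L) * dh + 1L):(hh * dh)
      q <- ag_slice(qkvw, rows, cq)
      k <- ag_slice(qkvw, rows, d + cq)
      v <- ag_slice(qkvw, rows, 2L * d + cq)
      att <- ag_softmax_rows(ag_scale(ag_matmul(q, ag_transpose(k)), scale))
      outs[[(w0 - 1L) * nh + hh]] <- ag_matmul(att, v)
    }
  }
  h <- ag_block_rows(outs, nw, nh, T, dh)
  h <- rowperm(h, order(wi))
  h <- lin_apply(blk$proj, h)
  if (shift > 0L)
    h <- ag_gather(h, rep(.roll_index(H, W, -shift, -shift), d) +
                     rep((seq_len(d) - 1L) * H * W, each = H * W), dim(h$val))
  x <- ag_add(shortcut, h)
  shortcut <- x
  h <- ag_layernorm_rows(x, ag_leaf(blk$ln2$g), ag_leaf(blk$ln2$b))
  h <- lin_apply(blk$fc2, ag_gelu(lin_apply(blk$fc1, h)))
  ag_add(shortcut, h)
}

# submatrix view with gradient routing
ag_slice <- function(x, rows, cols) {
  xv <- x$val
  y <- xv[rows, cols, drop = FALSE]
  ag_node(y, list(x), function(n) {
    g <- array(0, dim(xv))
    g[rows, cols] <- n$grad
    .acc(x, g)
  })
}

ag_transpose <- function(x) {
  ag_node(t(x$val), list(x), function(n) .acc(x, t(n$grad)))
}

# reassemble per-window per-head outputs into a (nw*T) x (nh*dh) matrix
ag_block_rows <- function(outs, nw, nh, T, dh) {
  val <- matrix(0, nw * T, nh * dh)
  for (w0 in seq_len(nw)) for (hh in seq_len(nh))
    val[((w0 - 1L) * T + 1L):(w0 * T), ((hh - 1L) * dh + 1L):(hh * dh)] <-
      outs[[(w0 - 1L) * nh + hh]]$val
  ag_node(val, outs, function(n) {
    for (w0 in seq_len(nw)) for (hh in seq_len(nh))
      .acc(outs[[(w0 - 1L) * nh + hh]],
           n$grad[((w0 - 1L) * T + 1L):(w0 * T),
                  ((hh - 1L) * dh + 1L):(hh * dh), drop = FALSE])
  })
}

.merge_index <- function(H, W) {
  # 2x2 neighbourhoods: rows of the merged token matrix gather 4 tokens
  h2 <- H %/% 2L; w2 <- W %/% 2L
  base <- as.vector(outer(seq(1L, H, by = 2L), (seq(1L, W, by = 2L) - 1L) * H, "+"))
  list(base, base + 1L, base + H, base + H + 1L)
}

# Forward to a probability node; x is an image node (Hp x Wp x 3 x 1).
disc_forward_node <- function(model, x) {
  cfg <- model$config
  f <- conv_apply(model$embed, x, stride = cfg$patch_size, pad = 0L)
  d <- dim(f$val)
  H <- d[1]; W <- d[2]; C <- d[3]
  # (H, W, C, 1) -> (H*W) x C token matrix (column-major flatten)
  tok <- ag_gather(f, seq_len(H * W * C), c(H * W, C))
  ns <- length(cfg$blocks_per_stage)
  for (s in seq_len(ns)) {
    win <- min(cfg$window, H, W)
    for (b in seq_along(model$stages[[s]])) {
      shift <- if (b %% 2L == 0L && win < min(H, W)) win %/% 2L else 0L
      tok <- wsb_apply(model$stages[[s]][[b]], tok, H, W, win, shift)
    }
    if (s < ns) {
      idx <- .merge_index(H, W)
      dmat <- dim(tok$val)
      parts <- lapply(idx, function(ii)
        ag_gather(tok, rep(ii, dmat[2]) + rep((seq_len(dmat[2]) - 1L) * dmat[1],
                                              each = length(ii)),
                  c(length(ii), dmat[2])))
      tok <- ag_cbind(parts)
      tok <- lin_apply(model$merges[[s]], tok)
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  tok <- ag_layernorm_rows(tok, ag_leaf(model$head_ln$g), ag_leaf(model$head_ln$b))
  pooled <- ag_mean_rows(tok)
  logit <- lin_apply(model$head, pooled)
  ag_sigmoid(logit)
}

ag_cbind <- function(parts) {
  vals <- lapply(parts, function(p) p$val)
  val <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  ag_node(val, parts, function(n) {
    for (i in seq_along(parts))
      .acc(parts[[i]], n$grad[, (ends[i] - widths[i] + 1L):ends[i], drop = FALSE])
  })
}

#' Score images with the discriminator
#'
#' Images of arbitrary size are bilinearly resized to the configured square
#' input before scoring.
#'
#' @param model a built discriminator.
#' @param images an H x W x 3 array or a list of such arrays.
#' @return numeric vector of probabilities in (0, 1).
#' @export
disc_score <- function(model, images) {
  if (is.array(images)) images <- list(images)
  vapply(images, function(im) {
    d <- dim(im)
    if (is.null(d) || length(d) != 3L || d[3] != 3L)
      stop("discriminator input must be H x W x 3")
    sz <- model$config$input_size
    if (d[1] != sz || d[2] != sz) im <- resize_bilinear(im, sz, sz)
    ag_tape_reset(recording = FALSE)
    disc_forward_node(model, ag_const(as4d(im)))$val[1]
  }, 0)
}
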