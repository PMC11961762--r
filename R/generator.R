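# U-shaped dense-convolution generator.
#
# Macro-structure: a 5x5 input projection to `base_width` channels; S encoder
# stages (channels double, spatial size halves at each), each three Dense
# Conv Blocks wrapped by a stage skip and followed by a stride-2 downsampling
# convolution; three bottleneck blocks; S decoder stages, each a stride-2
# upsampling halving the channels followed by one Dense Conv Block, with the
# encoder feature of equal spatial size merged in; a 5x5 output projection
# back to RGB.
#
# A Dense Conv Block (DCB) at width c is:
#   grouped 5x5 conv -> LayerNorm (per pixel over channels) ->
#   1x1 expansion -> GELU -> 1x1 contraction ->
#   dense skip (block input concatenated) -> grouped 5x5 conv -> LayerNorm
#   -> residual add of the block input.
#
# The block-internal knobs (group sizes, expansion, sampler forms, skip
# forms) are not published; they are frozen by calibrate_generator_knobs()
# against the five published model sizes, which they reproduce exactly.

.dcb_defaults <- list(
  group_size_a = 16L,   # channels per group, first 5x5 conv
  group_size_b = 4L,    # channels per group, second (dense) 5x5 conv
  expansion = 4L,       # 1x1 pair channel multiplier
  expand_groups = 2L,   # groups of the 1x1 pair
  ln2 = TRUE,           # LayerNorm after the second 5x5 conv
  down_kernel = 4L,     # stride-2 downsampling conv kernel
  up_kernel = 6L,       # stride-2 depthwise transposed conv kernel
  stage_skip = "conv",  # encoder stage skip: groups-2 1x1 conv, added
  skip_merge = "concat" # encoder-decoder skips concatenated into the DCB
)

#' Generator configuration
#'
#' Configuration of the restoration ("res", 4 stages, width 32) or
#' degradation-synthesis ("syn", 3 stages, width 16) generator. Channel
#' count at encoder stage i (0-based) is `2^i * base_width`; the bottleneck
#' runs at `2^stages * base_width`. Block-internal knobs default to the
#' values frozen by [calibrate_generator_knobs()].
#'
#' @param model "res" or "syn"; sets the `stages`/`base_width` defaults
#'   (4/32 and 3/16).
#' @param stages number of encoder/decoder stages S.
#' @param base_width channels C after the input projection.
#' @param enc_blocks_per_stage,bottleneck_blocks,dec_blocks_per_stage DCB
#'   counts per section.
#' @param proj_kernel,dcb_kernel odd kernels of the projections and the DCB
#'   spatial convolutions.
#' @param dcb_group_size_a,dcb_group_size_b channels per group of the two
#'   grouped 5x5 convolutions.
#' @param dcb_expansion channel multiplier of the 1x1 pair.
#' @param dcb_expand_groups group count of the 1x1 pair.
#' @param down_kernel even kernel of the stride-2 downsampling convolution
#'   (input: stage output concatenated with the stage input).
#' @param up_kernel even kernel of the stride-2 depthwise transposed
#'   upsampling convolution (followed by a 1x1 halving the channels).
#' @param stage_skip "conv" (groups-2 1x1, added) or "add" for the encoder
#'   stage skip.
#' @param skip_merge "concat" or "add" for the encoder-decoder skips.
#' @param ln2 second LayerNorm after the dense 5x5 convolution.
#' @return an object of class `gen_config`.
#' @export
generator_config <- function(model = c("res", "syn"),
                             stages = NULL, base_width = NULL,
                             enc_blocks_per_stage = 3L,
                             bottleneck_blocks = 3L,
                             dec_blocks_per_stage = 1L,
                             proj_kernel = 5L, dcb_kernel = 5L,
                             dcb_group_size_a = .dcb_defaults$group_size_a,
                             dcb_group_size_b = .dcb_defaults$group_size_b,
                             dcb_expansion = .dcb_defaults$expansion,
                             dcb_expand_groups = .dcb_defaults$expand_groups,
                             down_kernel = .dcb_defaults$down_kernel,
                             up_kernel = .dcb_defaults$up_kernel,
                             stage_skip = .dcb_defaults$stage_skip,
                             skip_merge = .dcb_defaults$skip_merge,
                             ln2 = .dcb_defaults$ln2) {
  model <- match.arg(model)
  if (is.null(stages)) stages <- if (model == "res") 4L else 3L
  if (is.null(base_width)) base_width <- if (model == "res") 32L else 16L
  stopifnot(stages >= 1L, base_width >= 2L,
            proj_kernel %% 2 == 1L, dcb_kernel %% 2 == 1L,
            down_kernel %% 2 == 0L, up_kernel %% 2 == 0L,
            dcb_expansion >= 1)
  if ((dcb_expansion * base_width) %% dcb_expand_groups != 0)
    stop("expanded width must be divisible by dcb_expand_groups")
  stage_skip <- match.arg(stage_skip, c("conv", "add"))
  skip_merge <- match.arg(skip_merge, c("concat", "add"))
  structure(list(model = model, stages = as.integer(stages),
                 base_width = as.integer(base_width),
                 enc_blocks_per_stage = as.integer(enc_blocks_per_stage),
                 bottleneck_blocks = as.integer(bottleneck_blocks),
                 dec_blocks_per_stage = as.integer(dec_blocks_per_stage),
                 proj_kernel = as.integer(proj_kernel),
                 dcb_kernel = as.integer(dcb_kernel),
                 dcb_group_size_a = as.integer(dcb_group_size_a),
                 dcb_group_size_b = as.integer(dcb_group_size_b),
                 dcb_expansion = as.numeric(dcb_expansion),
                 dcb_expand_groups = as.integer(dcb_expand_groups),
                 down_kernel = as.integer(down_kernel),
                 up_kernel = as.integer(up_kernel),
                 stage_skip = stage_skip, skip_merge = skip_merge,
                 ln2 = isTRUE(ln2)),
            class = "gen_config")
}

#' @export
print.gen_config <- function(x, ...) {
  cat(sprintf("generator config (%s): S=%d C=%d, %d/%d/%d DCBs, merge=%s\n",
              x$model, x$stages, x$base_width, x$enc_blocks_per_stage,
              x$bottleneck_blocks, x$dec_blocks_per_stage, x$skip_merge))
  cat(sprintf("  DCB: k=%d group sizes %d/%d, expansion %gx (g%d), ln2=%s\n",
              x$dcb_kernel, x$dcb_group_size_a, x$dcb_group_size_b,
              x$dcb_expansion, x$dcb_expand_groups, x$ln2))
  cat(sprintf("  samplers: down k%d, up k%d depthwise + 1x1; stage skip %s\n",
              x$down_kernel, x$up_kernel, x$stage_skip))
  cat(sprintf("  parameters: %.2f M\n",
              round(generator_param_count(x) / 1e6, 2)))
  invisible(x)
}

# groups of a grouped conv with `size` channels of the base width per group
.grp <- function(c, size) max(1L, as.integer(c %/% size))

## ---- layer constructors ----

new_conv <- function(k, cin, cout, groups = 1L, bias = TRUE, sd = 0.02) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop(sprintf("channels (%d -> %d) not divisible by groups (%d)",
                 cin, cout, groups))
  w <- array(init_trunc_normal(k * k * (cin / groups) * cout, sd),
             c(k, k, as.integer(cin / groups), cout))
  list(type = "conv", w = ag_param(w),
       b = if (bias) ag_param(numeric(cout)),
       k = as.integer(k), cin = cin, cout = cout, groups = as.integer(groups))
}

new_tconv <- function(k, cin, cout, groups = 1L, bias = TRUE, sd = 0.02) {
  # weight stored as (k, k, cout/groups, cin): adjoint of a cout -> cin conv
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("tconv channels not divisible by groups")
  w <- array(init_trunc_normal(k * k * (cout / groups) * cin, sd),
             c(k, k, as.integer(cout / groups), cin))
  list(type = "tconv", w = ag_param(w),
       b = if (bias) ag_param(numeric(cout)),
       k = as.integer(k), cin = cin, cout = cout, groups = as.integer(groups))
}

new_ln <- function(c) {
  list(type = "ln", g = ag_param(rep(1, c)), b = ag_param(numeric(c)))
}

conv_apply <- function(l, x, stride = 1L, pad = (l$k - 1L) %/% 2L) {
  ag_conv2d(x, ag_leaf(l$w), if (!is.null(l$b)) ag_leaf(l$b),
            stride = stride, pad = pad, groups = l$groups)
}

ln_apply <- function(l, x) ag_layernorm_c(x, ag_leaf(l$g), ag_leaf(l$b))

new_dcb <- function(c, cfg, cin_mult = 1L) {
  e <- cfg$dcb_expansion
  ce <- as.integer(e * c)
  list(type = "dcb", cin_mult = as.integer(cin_mult),
       conv5a = new_conv(cfg$dcb_kernel, cin_mult * c, c,
                         groups = .grp(c, cfg$dcb_group_size_a)),
       ln1 = new_ln(c),
       expand = new_conv(1L, c, ce, groups = .grp_ok(c, ce, cfg$dcb_expand_groups)),
       contract = new_conv(1L, ce, c, groups = .grp_ok(ce, c, cfg$dcb_expand_groups)),
       conv5b = new_conv(cfg$dcb_kernel, (cin_mult + 1L) * c, c,
                         groups = .grp(c, cfg$dcb_group_size_b)),
       ln2 = if (cfg$ln2) new_ln(c))
}

.grp_ok <- function(cin, cout, g) if (cin %% g == 0 && cout %% g == 0) g else 1L

dcb_apply <- function(blk, x) {
  h <- conv_apply(blk$conv5a, x)
  h <- ln_apply(blk$ln1, h)
  h <- conv_apply(blk$expand, h)
  h <- ag_gelu(h)
  h <- conv_apply(blk$contract, h)
  h <- conv_apply(blk$conv5b, ag_concat_c(x, h))
  if (!is.null(blk$ln2)) h <- ln_apply(blk$ln2, h)
  if (blk$cin_mult == 1L) ag_add(h, x) else h
}

## ---- generator ----

#' Build a generator
#'
#' Constructs the U-shaped dense-convolution generator with seeded
#' truncated-normal (sd 0.02) weights and zero biases.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `gen_model`.
#' @export
build_generator <- function(config, seed = 0L) {
  stopifnot(inherits(config, "gen_config"))
  C <- config$base_width; S <- config$stages
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  enc <- list(); skipc <- list(); down <- list()
  for (i in seq_len(S)) {
    c <- C * 2L^(i - 1L)
    enc[[i]] <- lapply(seq_len(config$enc_blocks_per_stage),
                       function(j) new_dcb(c, config))
    skipc[[i]] <- if (config$stage_skip == "conv")
      new_conv(1L, c, c, groups = .grp_ok(c, c, 2L))
    down[[i]] <- new_conv(config$down_kernel, 2L * c, 2L * c)
  }
  cb <- C * 2L^S
  bott <- lapply(seq_len(config$bottleneck_blocks),
                 function(j) new_dcb(cb, config))
  updw <- list(); uppw <- list(); dec <- list()
  for (i in seq_len(S)) {
    c <- C * 2L^(S - i)
    updw[[i]] <- new_tconv(config$up_kernel, 2L * c, 2L * c,
                           groups = 2L * c, bias = FALSE)
    uppw[[i]] <- new_conv(1L, 2L * c, c)
    first_mult <- if (config$skip_merge == "concat") 2L else 1L
    dec[[i]] <- c(list(new_dcb(c, config, cin_mult = first_mult)),
                  if (config$dec_blocks_per_stage > 1L)
                    lapply(seq_len(config$dec_blocks_per_stage - 1L),
                           function(j) new_dcb(c, config)))
  }
  model <- list(config = config, seed = as.integer(seed),
                in_proj = new_conv(config$proj_kernel, 3L, C),
                enc = enc, skipc = skipc, down = down, bott = bott,
                updw = updw, uppw = uppw, dec = dec,
                out_proj = new_conv(config$proj_kernel, C, 3L))
  class(model) <- "gen_model"
  model
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, globalenv())
  invisible(NULL)
}

#' Count trainable parameters
#'
#' @param model a built model (generator or discriminator).
#' @param millions report millions rounded to two decimals.
#' @return numeric scalar.
#' @export
count_parameters <- function(model, millions = FALSE) {
  n <- n_params(collect_params(model))
  if (millions) round(n / 1e6, 2) else n
}

#' Analytic generator parameter count
#'
#' Closed-form count mirroring [build_generator()] layer by layer; agrees
#' exactly with [count_parameters()] on the built model.
#'
#' @param config a [generator_config()].
#' @return integer parameter count.
#' @export
generator_param_count <- function(config) {
  C <- config$base_width; S <- config$stages
  k <- config$dcb_kernel; e <- config$dcb_expansion
  ncv <- function(kk, cin, cout, g = 1, bias = TRUE)
    kk * kk * (cin / g) * cout + if (bias) cout else 0
  dcb <- function(c, m = 1) {
    ce <- e * c
    ncv(k, m * c, c, .grp(c, config$dcb_group_size_a)) + 2 * c +
      ncv(1, c, ce, .grp_ok(c, ce, config$dcb_expand_groups)) +
      ncv(1, ce, c, .grp_ok(ce, c, config$dcb_expand_groups)) +
      ncv(k, (m + 1) * c, c, .grp(c, config$dcb_group_size_b)) +
      if (config$ln2) 2 * c else 0
  }
  tot <- ncv(config$proj_kernel, 3, C)
  for (i in seq_len(S)) {
    c <- C * 2^(i - 1)
    tot <- tot + config$enc_blocks_per_stage * dcb(c) +
      (if (config$stage_skip == "conv") ncv(1, c, c, .grp_ok(c, c, 2)) else 0) +
      ncv(config$down_kernel, 2 * c, 2 * c)
  }
  tot <- tot + config$bottleneck_blocks * dcb(C * 2^S)
  for (i in seq_len(S)) {
    c <- C * 2^(S - i)
    tot <- tot + ncv(config$up_kernel, 2 * c, 2 * c, g = 2 * c, bias = FALSE) +
      ncv(1, 2 * c, c) +
      dcb(c, if (config$skip_merge == "concat") 2 else 1) +
      (config$dec_blocks_per_stage - 1) * dcb(c)
  }
  tot + ncv(config$proj_kernel, C, 3)
}

#' Reflect-pad an image so both spatial dimensions divide a stride
#'
#' @param image H x W x 3 array.
#' @param stride required divisor (2^S for an S-stage generator).
#' @return list with `image` (padded) and `crop` (original `h`, `w`).
#' @export
pad_to_stride <- function(image, stride) {
  d <- dim(image)
  ph <- (stride - d[1] %% stride) %% stride
  pw <- (stride - d[2] %% stride) %% stride
  out <- image
  if (ph > 0) {
    ref <- out[d[1] - seq_len(ph), , , drop = FALSE]
    out <- abind3(out, ref, along = 1L)
  }
  if (pw > 0) {
    d2 <- dim(out)
    ref <- out[, d2[2] - seq_len(pw), , drop = FALSE]
    out <- abind3(out, ref, along = 2L)
  }
  list(image = out, crop = c(h = d[1], w = d[2]))
}

#' @rdname pad_to_stride
#' @param padded the padded image.
#' @param crop the `crop` element returned by `pad_to_stride`.
#' @export
crop_from_pad <- function(padded, crop) {
  padded[seq_len(crop[["h"]]), seq_len(crop[["w"]]), , drop = FALSE]
}

abind3 <- function(a, b, along) {
  da <- dim(a); db <- dim(b)
  if (along == 1L) {
    out <- array(0, c(da[1] + db[1], da[2], da[3]))
    out[seq_len(da[1]), , ] <- a
    out[da[1] + seq_len(db[1]), , ] <- b
  } else {
    out <- array(0, c(da[1], da[2] + db[2], da[3]))
    out[, seq_len(da[2]), ] <- a
    out[, da[2] + seq_len(db[2]), ] <- b
  }
  out
}

# Forward pass on an ag node (H x W x 3 x N), spatial dims divisible by 2^S.
gen_forward_node <- function(model, x) {
  cfg <- model$config
  h <- conv_apply(model$in_proj, x)
  skips <- list()
  for (i in seq_len(cfg$stages)) {
    s0 <- h
    for (blk in model$enc[[i]]) h <- dcb_apply(blk, h)
    h <- if (cfg$stage_skip == "conv")
      ag_add(h, conv_apply(model$skipc[[i]], s0)) else ag_add(h, s0)
    skips[[i]] <- h
    # downsample sees the refined stage output alongside the stage input
    h <- conv_apply(model$down[[i]], ag_concat_c(h, s0), stride = 2L,
                    pad = (cfg$down_kernel - 2L) %/% 2L)
  }
  for (blk in model$bott) h <- dcb_apply(blk, h)
  for (i in seq_len(cfg$stages)) {
    h <- ag_tconv2d(h, ag_leaf(model$updw[[i]]$w), NULL, stride = 2L,
                    pad = (cfg$up_kernel - 2L) %/% 2L,
                    groups = model$updw[[i]]$groups)
    h <- conv_apply(model$uppw[[i]], h)
    sk <- skips[[cfg$stages - i + 1L]]
    h <- if (cfg$skip_merge == "concat") ag_concat_c(h, sk) else ag_add(h, sk)
    for (blk in model$dec[[i]]) h <- dcb_apply(blk, h)
  }
  conv_apply(model$out_proj, h)
}

#' Run a generator on an image
#'
#' Accepts any height/width of at least `2^stages`; inputs are reflect-padded
#' to a multiple of the generator stride and cropped back; outputs are
#' clamped to `[0, 1]` at inference.
#'
#' @param model a built generator.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param clamp clamp the output to `[0, 1]`.
#' @return image array of the same size.
#' @export
gen_forward <- function(model, image, clamp = TRUE) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 image array")
  stride <- 2L^model$config$stages
  if (d[1] < stride || d[2] < stride)
    stop(sprintf("image must be at least %d x %d for a %d-stage generator",
                 stride, stride, model$config$stages))
  p <- pad_to_stride(image, stride)
  ag_tape_reset(recording = FALSE)
  x <- ag_const(as4d(p$image))
  y <- gen_forward_node(model, x)
  out <- y$val[, , , 1L]
  out <- crop_from_pad(out, p$crop)
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' @export
print.gen_model <- function(x, ...) {
  cat(sprintf("%s generator: S=%d C=%d, %.2f M parameters (seed %d)\n",
              x$config$model, x$config$stages, x$config$base_width,
              count_parameters(x) / 1e6, x$seed))
  invisible(x)
}

#' Calibrate block-internal knobs against the published model sizes
#'
#' The published ablations fix the generator parameter count at five design
#' points: 12.72 M (S=4, C=32), 3.78 M (C=16), 26.82 M (C=48), 3.71 M (S=3)
#' and 46.27 M (S=5). The block-internal knobs are not published; this
#' search scores knob combinations by how many design points they reproduce
#' exactly at the printed precision, requiring the headline 12.72 M model to
#' match, with total absolute error as tie-break. The package defaults are
#' the unique fully-exact setting found by this search.
#'
#' @param grid optional data frame of knob combinations; by default a grid
#'   over group sizes, expansion/groups, sampler kernels, skip forms.
#' @return data frame of settings, best first.
#' @export
calibrate_generator_knobs <- function(grid = NULL) {
  pts <- list(list(stages = 4L, width = 32L, target = 12.72),
              list(stages = 4L, width = 16L, target = 3.78),
              list(stages = 4L, width = 48L, target = 26.82),
              list(stages = 3L, width = 32L, target = 3.71),
              list(stages = 5L, width = 32L, target = 46.27))
  if (is.null(grid))
    grid <- expand.grid(gsa = c(4L, 8L, 16L), gsb = c(2L, 4L, 8L),
                        e = c(1, 2, 4), eg = c(1L, 2L),
                        kd = c(2L, 4L), ku = c(4L, 6L),
                        ss = c("conv", "add"), sm = c("concat", "add"),
                        ln2 = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tgt <- vapply(pts, `[[`, 0, "target")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cnt <- vapply(pts, function(p) {
      cfg <- generator_config("res", stages = p$stages, base_width = p$width,
                              dcb_group_size_a = g$gsa, dcb_group_size_b = g$gsb,
                              dcb_expansion = g$e, dcb_expand_groups = g$eg,
                              down_kernel = g$kd, up_kernel = g$ku,
                              stage_skip = g$ss, skip_merge = g$sm, ln2 = g$ln2)
      round(generator_param_count(cfg) / 1e6, 2)
    }, 0)
    data.frame(g, n_exact = sum(cnt == tgt), headline = cnt[1] == tgt[1],
               total_err = sum(abs(cnt - tgt)),
               counts = paste(sprintf("%.2f", cnt), collapse = " "))
  })
  out <- do.call(rbind, res)
  out[order(-out$headline, -out$n_exact, out$total_err), , drop = FALSE]
}
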