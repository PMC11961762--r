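# Adversarial training of the two stages: the synthesis model on unpaired
# high-quality/degraded pools, and the restoration model on paired data.
# One discriminator step then one generator step per iteration; Adam with
# linear warmup and cosine (training) or linear (fine-tuning) decay; all
# randomness (batch order, crops, flips, initialisation) flows from the
# config seed.

#' Training configuration
#'
#' Published defaults: 80,000 iterations, batch 8, learning rate 1e-5 with
#' 1000-iteration warmup and cosine decay; fine-tuning (restoration model
#' only) at 1e-6 with linear decay; images resized to 768 and randomly
#' cropped to paired 256 patches with shared flips.
#'
#' @param iterations training iterations.
#' @param batch batch size.
#' @param base_lr peak learning rate after warmup.
#' @param warmup_iters linear warmup length.
#' @param decay "cosine" or "linear" decay to zero at `iterations`.
#' @param finetune_lr,finetune_iters fine-tuning phase (restoration only);
#'   set `finetune_iters = 0` to skip.
#' @param patch training crop side.
#' @param resize images are resized to this square size before cropping
#'   (NULL keeps the native size).
#' @param seed master seed for all randomness.
#' @param checkpoint_every iterations between checkpoints (0: only final).
#' @param beta1,beta2,adam_eps Adam moments.
#' @param clip global-norm gradient clip (NULL disables).
#' @param fp_extractor feature extractor for the perceptual loss; defaults
#'   to the seeded VGG-19-topology extractor. Pass
#'   `feature_extractor("vgg19", taps = 1:3)` (or "identity") to reduce cost
#'   at small problem sizes.
#' @param hard_labels use hard (1) instead of soft discriminator labels in
#'   the generator GAN loss.
#' @param out_dir optional directory for checkpoints and the loss CSV.
#' @return object of class `train_config`.
#' @export
train_config <- function(iterations = 80000L, batch = 8L, base_lr = 1e-5,
                         warmup_iters = 1000L, decay = c("cosine", "linear"),
                         finetune_lr = 1e-6, finetune_iters = 20000L,
                         patch = 256L, resize = 768L, seed = 0L,
                         checkpoint_every = 0L, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, clip = 1.0,
                         fp_extractor = NULL, hard_labels = FALSE,
                         out_dir = NULL) {
  decay <- match.arg(decay)
  stopifnot(warmup_iters < iterations, batch >= 1L,
            is.null(resize) || patch <= resize)
  structure(list(iterations = as.integer(iterations), batch = as.integer(batch),
                 base_lr = base_lr, warmup_iters = as.integer(warmup_iters),
                 decay = decay, finetune_lr = finetune_lr,
                 finetune_iters = as.integer(finetune_iters),
                 patch = as.integer(patch),
                 resize = if (is.null(resize)) NULL else as.integer(resize),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 clip = clip, fp_extractor = fp_extractor,
                 hard_labels = isTRUE(hard_labels), out_dir = out_dir),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear ramp from 0 to `base_lr` over the warmup, then cosine or linear
#' decay to 0 at the final iteration.
#'
#' @param config a [train_config()].
#' @param iteration iteration in `[0, iterations]`.
#' @return learning rate.
#' @export
lr_schedule <- function(config, iteration) {
  it <- iteration
  if (any(it < 0 | it > config$iterations))
    stop("iteration out of range [0, ", config$iterations, "]")
  w <- config$warmup_iters
  span <- config$iterations - w
  ifelse(it <= w, config$base_lr * it / w,
         if (config$decay == "cosine")
           config$base_lr * 0.5 * (1 + cos(pi * (it - w) / span))
         else config$base_lr * (1 - (it - w) / span))
}

## ---- data pipelines ----

# load, square-crop and resize one image
.prep_image <- function(path, resize) {
  im <- read_image(path)
  im <- center_crop_square(im)
  if (!is.null(resize) && (dim(im)[1] != resize || dim(im)[2] != resize))
    im <- resize_bilinear(im, resize, resize)
  im
}

# unpaired sample: random crop + flips (own randomness from current RNG)
.sample_unpaired <- function(files, cache, batch, resize, patch) {
  idx <- sample.int(length(files), batch, replace = batch > length(files))
  out <- array(0, c(patch, patch, 3, batch))
  for (j in seq_len(batch)) {
    im <- cache[[files[idx[j]]]]
    cr <- paired_random_crop(im, im, patch)$a
    out[, , , j] <- flip_image(cr, runif(1) < 0.5, runif(1) < 0.5)
  }
  out
}

.sample_paired <- function(clean_files, degraded_files, cache, batch, resize, patch) {
  idx <- sample.int(length(clean_files), batch, replace = batch > length(clean_files))
  cl <- array(0, c(patch, patch, 3, batch))
  dg <- array(0, c(patch, patch, 3, batch))
  for (j in seq_len(batch)) {
    a <- cache[[clean_files[idx[j]]]]
    b <- cache[[degraded_files[idx[j]]]]
    cr <- paired_random_crop(a, b, patch)
    fh <- runif(1) < 0.5; fv <- runif(1) < 0.5
    cl[, , , j] <- flip_image(cr$a, fh, fv)
    dg[, , , j] <- flip_image(cr$b, fh, fv)
  }
  list(clean = cl, degraded = dg)
}

.image_cache <- function(files, resize) {
  cache <- new.env(parent = emptyenv())
  for (f in files) assign(f, .prep_image(f, resize), cache)
  cache
}

## ---- loss graph helpers ----

# feature matrix (HW x C) of sample n of a feature node
.ag_feat_mat <- function(f, n) {
  d <- dim(f$val)
  base <- (n - 1L) * d[1] * d[2] * d[3]
  idx <- base + seq_len(d[1] * d[2] * d[3])
  ag_gather(f, idx, c(d[1] * d[2], d[3]))
}

# perceptual content+style between an output node and reference values
.ag_fp <- function(extractor, out_node, ref_val, style_weight) {
  fo <- extractor_forward(extractor, out_node)
  # reference features carry no gradient: keep them off the tape
  rec <- .ag$recording
  .ag$recording <- FALSE
  fr <- extractor_forward(extractor, ag_const(ref_val))
  .ag$recording <- rec
  nt <- length(fo)
  content <- NULL
  style <- NULL
  nb <- dim(out_node$val)[4]
  for (i in seq_len(nt)) {
    cterm <- ag_mse(fo[[i]], ag_const(fr[[i]]$val))
    content <- if (is.null(content)) cterm else ag_add(content, cterm)
    for (n in seq_len(nb)) {
      Fm <- .ag_feat_mat(fo[[i]], n)
      hw <- dim(Fm$val)[1]
      G <- ag_scale(ag_matmul(ag_transpose(Fm), Fm), 1 / hw)
      Gr <- gram(fr[[i]]$val[, , , n])
      sterm <- ag_scale(ag_mse(G, ag_const(Gr)), 1 / nb)
      style <- if (is.null(style)) sterm else ag_add(style, sterm)
    }
  }
  list(content = ag_scale(content, 1 / nt),
       style = ag_scale(style, style_weight / nt))
}

.ag_gan <- function(disc, out_node, p_real, hard_labels) {
  nb <- dim(out_node$val)[4]
  d <- dim(out_node$val)
  loss <- NULL
  ps <- numeric(nb)
  for (n in seq_len(nb)) {
    base <- (n - 1L) * d[1] * d[2] * d[3]
    xn <- ag_gather(out_node, base + seq_len(d[1] * d[2] * d[3]),
                    c(d[1], d[2], d[3], 1L))
    p <- disc_forward_node(disc, xn)
    ps[n] <- p$val[1]
    term <- ag_scale(ag_bce(p, if (hard_labels) 1 else p_real), 1 / nb)
    loss <- if (is.null(loss)) term else ag_add(loss, term)
  }
  list(loss = loss, p_out = ps)
}

.disc_step <- function(disc, disc_params, real_batch, fake_batch, lr, t, cfg) {
  zero_grads(disc_params)
  tape_save <- .ag$tape          # the generator graph lives on the main tape
  ag_tape_reset(recording = TRUE)
  on.exit({ .ag$tape <- tape_save; .ag$recording <- TRUE }, add = TRUE)
  d <- dim(real_batch)
  loss <- NULL
  scores <- numeric(0)
  eps <- 1e-7
  for (n in seq_len(d[4])) {
    p <- disc_forward_node(disc, ag_const(real_batch[, , , n, drop = FALSE]))
    scores <- c(scores, p$val[1])
    term <- ag_node(-log(max(p$val[1], eps)), list(p), local({
      pp <- p
      function(nn) .acc(pp, nn$grad * (-1 / max(pp$val[1], eps)))
    }))
    loss <- if (is.null(loss)) term else ag_add_scalar_node(loss, term)
  }
  for (n in seq_len(dim(fake_batch)[4])) {
    p <- disc_forward_node(disc, ag_const(fake_batch[, , , n, drop = FALSE]))
    scores <- c(scores, p$val[1])
    term <- ag_node(-log(max(1 - p$val[1], eps)), list(p), local({
      pp <- p
      function(nn) .acc(pp, nn$grad * (1 / max(1 - pp$val[1], eps)))
    }))
    loss <- ag_add_scalar_node(loss, term)
  }
  loss <- ag_scale(loss, 1 / (d[4] + dim(fake_batch)[4]))
  ag_backward(loss)
  adam_step(disc_params, lr, cfg$beta1, cfg$beta2, cfg$adam_eps, t, cfg$clip)
  list(loss = loss$val, scores = scores)
}

## ---- core loop ----

.gan_loop <- function(mode, gen, disc, data, config, weights, extractor,
                      state = NULL, phase = "train") {
  gen_params <- collect_params(gen)
  disc_params <- collect_params(disc)
  log <- if (is.null(state)) NULL else state$losses
  it0 <- if (is.null(state)) 0L else state$iteration
  collapse_run <- 0L
  t_adam <- it0 + 1L
  if (it0 >= config$iterations)
    return(.mk_state(mode, gen, disc, config, weights, it0, log, phase))
  for (it in (it0 + 1L):config$iterations) {
    lr <- lr_schedule(config, it)
    if (mode == "syn") {
      hq <- .sample_unpaired(data$hq_files, data$cache, config$batch,
                             config$resize, config$patch)
      ref <- .sample_unpaired(data$lq_files, data$cache, config$batch,
                              config$resize, config$patch)
      input <- hq; pixel_target <- hq
      ide_img <- ref[, , , 1L, drop = FALSE]   # target domain: degraded
    } else {
      s <- .sample_paired(data$clean_files, data$degraded_files, data$cache,
                          config$batch, config$resize, config$patch)
      input <- s$degraded; ref <- s$clean; pixel_target <- s$clean
      ide_img <- s$clean[, , , 1L, drop = FALSE]  # target domain: clean
    }
    # -- generator forward: identity-domain image rides along as the last
    # batch sample, so one taped pass serves all four losses --
    ag_tape_reset(recording = TRUE)
    nb <- dim(input)[4]
    joint <- array(c(input, ide_img), dim(input) + c(0, 0, 0, 1))
    x <- ag_const(joint)
    out_all <- gen_forward_node(gen, x)
    d4 <- dim(out_all$val)
    per <- prod(d4[1:3])
    out <- ag_gather(out_all, seq_len(per * nb), c(d4[1:3], nb))
    ide_out <- ag_gather(out_all, per * nb + seq_len(per), c(d4[1:3], 1L))
    # -- discriminator update on detached output --
    dres <- .disc_step(disc, disc_params, ref, out$val, lr, t_adam, config)
    # -- generator losses (graph continues on the same tape) --
    zero_grads(gen_params); zero_grads(disc_params)
    # soft GAN label: this iteration's discriminator scores of the reals
    p_real <- mean(dres$scores[seq_len(dim(ref)[4])])
    pixel <- ag_smooth_l1(ag_const(pixel_target), out)
    fp <- .ag_fp(extractor, out, ref, weights$style_weight)
    ide <- ag_smooth_l1(ag_const(ide_img), ide_out)
    gan <- .ag_gan(disc, out, p_real, config$hard_labels)
    total <- ag_add_scalar_node(
      ag_add_scalar_node(ag_scale(pixel, weights$w_pixel),
                         ag_scale(ag_add_scalar_node(fp$content, fp$style),
                                  weights$w_fp)),
      ag_add_scalar_node(ag_scale(ide, weights$w_ide),
                         ag_scale(gan$loss, weights$w_gan)))
    if (!is.finite(total$val))
      stop(sprintf("non-finite training loss at iteration %d (pixel %.3g, fp %.3g/%.3g, ide %.3g, gan %.3g)",
                   it, pixel$val, fp$content$val, fp$style$val, ide$val,
                   gan$loss$val))
    ag_backward(total)
    adam_step(gen_params, lr, config$beta1, config$beta2, config$adam_eps,
              t_adam, config$clip)
    t_adam <- t_adam + 1L
    # -- logging and mode-collapse guard --
    row <- data.frame(phase = phase, iteration = it, lr = lr,
                      total = total$val, pixel = pixel$val,
                      fp_content = fp$content$val, fp_style = fp$style$val,
                      identity = ide$val, gan = gan$loss$val,
                      disc_loss = dres$loss, p_real = p_real,
                      p_out = mean(gan$p_out),
                      disc_sd = stats::sd(dres$scores))
    log <- if (is.null(log)) row else rbind(log, row)
    collapse_run <- if (row$disc_sd < 1e-5) collapse_run + 1L else 0L
    if (collapse_run >= 100L)
      stop(sprintf(paste("mode collapse suspected: discriminator score sd <",
                         "1e-5 for 100 consecutive iterations (iteration %d,",
                         "p_real %.4f, p_out %.4f)"), it, p_real, mean(gan$p_out)))
    if (!is.null(config$out_dir) && config$checkpoint_every > 0L &&
        it %% config$checkpoint_every == 0L)
      save_checkpoint(.mk_state(mode, gen, disc, config, weights, it, log, phase),
                      file.path(config$out_dir, sprintf("iter_%06d", it)))
  }
  .mk_state(mode, gen, disc, config, weights, config$iterations, log, phase)
}

.mk_state <- function(mode, gen, disc, config, weights, iteration, log, phase) {
  structure(list(mode = mode, model = gen, disc = disc, config = config,
                 weights = weights, iteration = as.integer(iteration),
                 losses = log, phase = phase,
                 rng = .Random.seed_get()),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("%s training state: iteration %d (%s phase), final total loss %.5g\n",
              x$mode, x$iteration, x$phase,
              if (!is.null(x$losses)) utils::tail(x$losses$total, 1) else NA))
  invisible(x)
}

#' Train the degradation-synthesis model on unpaired pools
#'
#' The generator receives high-quality images; the adversarial reference is
#' the unpaired degraded pool; the identity loss keeps already-degraded
#' images unchanged; synthesis loss weights (pixel 0.01, perceptual 1,
#' identity 0.1, GAN 0.1) and the 3-stage/width-16 generator are used.
#'
#' @param hq_dir,degraded_dir directories of PNG images (non-empty).
#' @param config a [train_config()].
#' @param gen_config,disc_config optional architecture overrides.
#' @return a `train_state` (final checkpoint written to `config$out_dir`
#'   when set).
#' @export
train_syn <- function(hq_dir, degraded_dir, config = train_config(),
                      gen_config = generator_config("syn"),
                      disc_config = NULL) {
  hq_files <- list_images(hq_dir)
  lq_files <- list_images(degraded_dir)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  gen <- build_generator(gen_config, seed = config$seed)
  if (is.null(disc_config))
    disc_config <- discriminator_config(input_size = config$patch)
  disc <- build_discriminator(disc_config, seed = config$seed + 1L)
  extractor <- config$fp_extractor %||% feature_extractor("vgg19", seed = config$seed)
  weights <- loss_weights("syn")
  cache <- .image_cache(c(hq_files, lq_files), config$resize)
  st <- .gan_loop("syn", gen, disc,
                  list(hq_files = hq_files, lq_files = lq_files, cache = cache),
                  config, weights, extractor)
  .finish_state(st, config)
}

#' Train the restoration model on paired data
#'
#' Expects `pairs_dir` with `clean/` and `degraded/` subdirectories of
#' identically named PNGs (the layout written by [synthesize_pairs()] and
#' [make_phantom_dataset()]). Restoration loss weights (pixel 1, perceptual
#' 0.1, identity 0.01, GAN 0.01) and the 4-stage/width-32 generator are
#' used; after the main run, a fine-tuning phase at `finetune_lr` with
#' linear decay continues for `finetune_iters` iterations.
#'
#' @param pairs_dir paired data directory.
#' @param config a [train_config()].
#' @param gen_config,disc_config optional architecture overrides.
#' @return a `train_state`.
#' @export
train_res <- function(pairs_dir, config = train_config(),
                      gen_config = generator_config("res"),
                      disc_config = NULL) {
  clean_files <- list_images(file.path(pairs_dir, "clean"))
  degraded_files <- list_images(file.path(pairs_dir, "degraded"))
  orphans <- c(setdiff(basename(clean_files), basename(degraded_files)),
               setdiff(basename(degraded_files), basename(clean_files)))
  if (length(orphans))
    stop("unpaired files: ", paste(orphans, collapse = ", "))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  gen <- build_generator(gen_config, seed = config$seed)
  if (is.null(disc_config))
    disc_config <- discriminator_config(input_size = config$patch)
  disc <- build_discriminator(disc_config, seed = config$seed + 1L)
  extractor <- config$fp_extractor %||% feature_extractor("vgg19", seed = config$seed)
  weights <- loss_weights("res")
  cache <- .image_cache(c(clean_files, degraded_files), config$resize)
  data <- list(clean_files = clean_files, degraded_files = degraded_files,
               cache = cache)
  st <- .gan_loop("res", gen, disc, data, config, weights, extractor)
  if (config$finetune_iters > 0L) {
    ft <- config
    ft$iterations <- config$finetune_iters
    ft$base_lr <- config$finetune_lr
    ft$decay <- "linear"
    ft$warmup_iters <- min(config$warmup_iters, config$finetune_iters - 1L)
    st2 <- .gan_loop("res", st$model, st$disc, data, ft, weights, extractor,
                     phase = "finetune")
    st2$losses <- rbind(st$losses, st2$losses)
    st <- st2
  }
  .finish_state(st, config)
}

.finish_state <- function(st, config) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(st$losses, file.path(config$out_dir, "losses.csv"),
                     row.names = FALSE)
    save_checkpoint(st, file.path(config$out_dir, "final"))
  }
  st
}

#' Resume training from a saved state
#'
#' Restores models, optimiser moments and the random-number stream, then
#' continues to `config$iterations`; a save/load/continue cycle reproduces
#' the uninterrupted run bit for bit.
#'
#' @param state a `train_state` (or checkpoint path).
#' @param data_dirs for "syn": `list(hq_dir=, degraded_dir=)`; for "res":
#'   `list(pairs_dir=)`.
#' @return a `train_state`.
#' @export
resume_training <- function(state, data_dirs) {
  if (is.character(state)) state <- load_checkpoint(state)
  config <- state$config
  extractor <- config$fp_extractor %||%
    feature_extractor("vgg19", seed = config$seed)
  .Random.seed_set(state$rng)
  if (state$mode == "syn") {
    hq_files <- list_images(data_dirs$hq_dir)
    lq_files <- list_images(data_dirs$degraded_dir)
    cache <- .image_cache(c(hq_files, lq_files), config$resize)
    data <- list(hq_files = hq_files, lq_files = lq_files, cache = cache)
  } else {
    clean_files <- list_images(file.path(data_dirs$pairs_dir, "clean"))
    degraded_files <- list_images(file.path(data_dirs$pairs_dir, "degraded"))
    cache <- .image_cache(c(clean_files, degraded_files), config$resize)
    data <- list(clean_files = clean_files, degraded_files = degraded_files,
                 cache = cache)
  }
  .gan_loop(state$mode, state$model, state$disc, data, config, state$weights,
            extractor, state = state, phase = state$phase)
}

#' Synthesize paired data with a trained degradation model
#'
#' Runs the synthesis generator over every high-quality image and writes
#' (clean, synthetic-degraded) pairs preserving filenames, plus a manifest.
#'
#' @param syn a `train_state`, generator, or checkpoint path.
#' @param hq_dir directory of high-quality PNGs.
#' @param out_dir output directory (`clean/`, `degraded/`).
#' @return the manifest, invisibly.
#' @export
synthesize_pairs <- function(syn, hq_dir, out_dir) {
  gen <- .as_generator(syn)
  files <- list_images(hq_dir)
  dir.create(file.path(out_dir, "clean"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "degraded"), recursive = TRUE, showWarnings = FALSE)
  items <- lapply(files, function(f) {
    im <- read_image(f)
    deg <- gen_forward(gen, im)
    write_image(im, file.path(out_dir, "clean", basename(f)))
    write_image(deg, file.path(out_dir, "degraded", basename(f)))
    list(filename = basename(f))
  })
  manifest <- list(n = length(files), source = "synthesize_pairs",
                   items = items)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Restore a directory of degraded images
#'
#' @param res a `train_state`, generator, or checkpoint path.
#' @param in_dir directory of degraded PNGs.
#' @param out_dir output directory.
#' @return invisibly, the output file paths.
#' @export
restore_images <- function(res, in_dir, out_dir) {
  gen <- .as_generator(res)
  files <- list_images(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- vapply(files, function(f) {
    im <- read_image(f)
    write_image(gen_forward(gen, im), file.path(out_dir, basename(f)))
  }, "")
  invisible(out)
}

.as_generator <- function(x) {
  if (inherits(x, "gen_model")) return(x)
  if (is.character(x)) x <- load_checkpoint(x)
  if (inherits(x, "train_state")) return(x$model)
  stop("expected a generator, train_state, or checkpoint path")
}

## ---- checkpoints ----

.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  h
}

.param_blob <- function(params) {
  unlist(lapply(params, function(p) c(as.numeric(p$val),
                                      as.numeric(p$m %||% rep(0, length(p$val))),
                                      as.numeric(p$v %||% rep(0, length(p$val))))))
}

.fill_params <- function(params, blob) {
  off <- 0L
  for (p in params) {
    n <- length(p$val)
    p$val <- array(blob[off + seq_len(n)], dim(p$val) %||% n)
    p$m <- array(blob[off + n + seq_len(n)], dim(p$val) %||% n)
    p$v <- array(blob[off + 2L * n + seq_len(n)], dim(p$val) %||% n)
    off <- off + 3L * n
  }
  stopifnot(off == length(blob))
  invisible(NULL)
}

#' Save a training checkpoint
#'
#' Writes `<path>.bin` (weights and optimiser moments) and `<path>.json`
#' (config, iteration, seed, loss weights, config hash).
#'
#' @param state a `train_state`.
#' @param path path prefix.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  gcfg <- state$model$config
  dcfg <- state$disc$config
  meta <- list(mode = state$mode, iteration = state$iteration,
               phase = state$phase,
               gen_config = unclass(gcfg), gen_seed = state$model$seed,
               disc_config = unclass(dcfg), disc_seed = state$disc$seed,
               train_config = unclass(state$config[setdiff(names(state$config),
                                                           "fp_extractor")]),
               weights = unclass(state$weights),
               fp = if (!is.null(state$config$fp_extractor))
                 state$config$fp_extractor[c("type", "taps", "seed")],
               rng = state$rng,
               config_hash = .config_hash(unclass(gcfg)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  blob <- c(.param_blob(collect_params(state$model)),
            .param_blob(collect_params(state$disc)))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(blob, con, size = 8L)
  close(con)
  if (!is.null(state$losses))
    utils::write.csv(state$losses, paste0(path, "_losses.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a training checkpoint
#'
#' Rebuilds the models from the JSON sidecar (validating the config hash)
#' and restores weights and optimiser moments.
#'
#' @param path path prefix used in [save_checkpoint()].
#' @return a `train_state`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(paste0(path, ".json"))) stop("missing checkpoint: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gcfg <- meta$gen_config
  cfg <- generator_config(gcfg$model, stages = gcfg$stages,
                          base_width = gcfg$base_width,
                          enc_blocks_per_stage = gcfg$enc_blocks_per_stage,
                          bottleneck_blocks = gcfg$bottleneck_blocks,
                          dec_blocks_per_stage = gcfg$dec_blocks_per_stage,
                          proj_kernel = gcfg$proj_kernel,
                          dcb_kernel = gcfg$dcb_kernel,
                          dcb_group_size_a = gcfg$dcb_group_size_a,
                          dcb_group_size_b = gcfg$dcb_group_size_b,
                          dcb_expansion = gcfg$dcb_expansion,
                          dcb_expand_groups = gcfg$dcb_expand_groups,
                          down_kernel = gcfg$down_kernel,
                          up_kernel = gcfg$up_kernel,
                          stage_skip = gcfg$stage_skip,
                          skip_merge = gcfg$skip_merge, ln2 = gcfg$ln2)
  if (.config_hash(unclass(cfg)) != meta$config_hash)
    stop("checkpoint config hash mismatch")
  gen <- build_generator(cfg, seed = meta$gen_seed)
  dc <- meta$disc_config
  disc <- build_discriminator(
    discriminator_config(input_size = dc$input_size, patch_size = dc$patch_size,
                         embed_dim = dc$embed_dim,
                         blocks_per_stage = dc$blocks_per_stage,
                         heads_per_stage = dc$heads_per_stage,
                         window = dc$window, mlp_ratio = dc$mlp_ratio),
    seed = meta$disc_seed)
  con <- file(paste0(path, ".bin"), "rb")
  sz <- file.info(paste0(path, ".bin"))$size
  blob <- readBin(con, "double", n = sz / 8, size = 8L)
  close(con)
  gp <- collect_params(gen); dp <- collect_params(disc)
  ng <- 3L * n_params(gp)
  .fill_params(gp, blob[seq_len(ng)])
  .fill_params(dp, blob[ng + seq_len(3L * n_params(dp))])
  tc <- meta$train_config
  config <- train_config(iterations = tc$iterations, batch = tc$batch,
                         base_lr = tc$base_lr, warmup_iters = tc$warmup_iters,
                         decay = tc$decay, finetune_lr = tc$finetune_lr,
                         finetune_iters = tc$finetune_iters, patch = tc$patch,
                         resize = tc$resize, seed = tc$seed,
                         checkpoint_every = tc$checkpoint_every,
                         beta1 = tc$beta1, beta2 = tc$beta2,
                         adam_eps = tc$adam_eps, clip = tc$clip,
                         hard_labels = tc$hard_labels,
                         fp_extractor = if (!is.null(meta$fp))
                           feature_extractor(meta$fp$type, taps = meta$fp$taps,
                                             seed = meta$fp$seed),
                         out_dir = tc$out_dir)
  losses <- NULL
  if (file.exists(paste0(path, "_losses.csv")))
    losses <- utils::read.csv(paste0(path, "_losses.csv"))
  w <- meta$weights
  weights <- loss_weights(w$model, w$w_pixel, w$w_fp, w$w_ide, w$w_gan,
                          w$style_weight)
  structure(list(mode = meta$mode, model = gen, disc = disc, config = config,
                 weights = weights, iteration = meta$iteration,
                 losses = losses, phase = meta$phase, rng = meta$rng),
            class = "train_state")
}
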