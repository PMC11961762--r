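# Schedules, reproducibility, checkpoint resumability, and the two-stage
# training smokes at reduced problem sizes.

test_that("learning-rate schedule has the published shape", {
  cfg <- train_config(iterations = 80000L, warmup_iters = 1000L,
                      base_lr = 1e-5)
  expect_equal(lr_schedule(cfg, 1000L), 1e-5, tolerance = 1e-15)
  expect_equal(lr_schedule(cfg, 80000L), 0, tolerance = 1e-20)
  mid <- 1000L + (80000L - 1000L) %/% 2L
  expect_equal(lr_schedule(cfg, mid), 1e-5 / 2, tolerance = 1e-9)
  expect_equal(lr_schedule(cfg, 0L), 0)
  # monotone non-increasing after warmup
  lrs <- lr_schedule(cfg, seq(1000L, 80000L, by = 500L))
  expect_true(all(diff(lrs) <= 0))
  expect_error(lr_schedule(cfg, 80001L), "range")
  # linear decay variant
  cfl <- train_config(iterations = 100L, warmup_iters = 10L, decay = "linear",
                      base_lr = 1e-6, patch = 16L, resize = 16L)
  expect_equal(lr_schedule(cfl, 55L), 1e-6 * 0.5, tolerance = 1e-15)
  expect_equal(lr_schedule(cfl, 100L), 0)
})

tiny_res_args <- function(iterations = 3L, seed = 0L)
  list(config = train_config(iterations = iterations, batch = 1L,
                             base_lr = 1e-3, warmup_iters = 1L, patch = 32L,
                             resize = NULL, seed = seed, finetune_iters = 0L,
                             fp_extractor = feature_extractor("identity")),
       gen_config = tiny_gen_config(),
       disc_config = tiny_disc_config())

tiny_pairs_dir <- function() {
  d <- file.path(tempdir(), "tinypairs")
  if (!dir.exists(file.path(d, "clean")))
    make_phantom_dataset(3, phantom_config(height = 64, width = 64, seed = 9L),
                         haze_params(seed = 9L), d)
  d
}

test_that("training is reproducible from the seed", {
  d <- tiny_pairs_dir()
  a <- do.call(train_res, c(list(d), tiny_res_args()))
  b <- do.call(train_res, c(list(d), tiny_res_args()))
  expect_equal(a$losses$total, b$losses$total, tolerance = 1e-12)
  c2 <- do.call(train_res, c(list(d), tiny_res_args(seed = 1L)))
  expect_false(isTRUE(all.equal(a$losses$total, c2$losses$total)))
})

test_that("checkpoint save/load/continue reproduces the loss trace exactly", {
  d <- tiny_pairs_dir()
  full <- do.call(train_res, c(list(d), tiny_res_args(iterations = 4L)))
  # same schedule, checkpointed halfway through
  args <- tiny_res_args(iterations = 4L)
  args$config$checkpoint_every <- 2L
  args$config$out_dir <- file.path(tempdir(), "ck")
  unlink(args$config$out_dir, recursive = TRUE)
  do.call(train_res, c(list(d), args))
  ck <- file.path(args$config$out_dir, "iter_000002")
  loaded <- load_checkpoint(ck)
  expect_identical(loaded$iteration, 2L)
  resumed <- resume_training(loaded, list(pairs_dir = d))
  expect_equal(resumed$losses$total, full$losses$total, tolerance = 1e-9)
  # config hash guards against mismatched architectures
  meta <- jsonlite::read_json(paste0(ck, ".json"), simplifyVector = TRUE)
  meta$gen_config$base_width <- 8L
  jsonlite::write_json(meta, paste0(ck, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(load_checkpoint(ck), "hash")
})

test_that("restoration training needs complete pairs and non-empty inputs", {
  d <- file.path(tempdir(), "orphaned")
  unlink(d, recursive = TRUE)
  make_phantom_dataset(2, phantom_config(height = 64, width = 64, seed = 2L),
                       haze_params(seed = 2L), d)
  file.remove(file.path(d, "degraded", "0001.png"))
  expect_error(do.call(train_res, c(list(d), tiny_res_args())), "unpaired")
  expect_error(train_syn(file.path(tempdir(), "nosuchdir"),
                         file.path(tempdir(), "nosuchdir2"),
                         tiny_res_args()$config), "no PNG")
})

test_that("unpaired degradation-synthesis smoke learns at small scale", {
  base <- file.path(tempdir(), "synsmoke")
  if (!dir.exists(file.path(base, "hq", "clean"))) {
    make_phantom_dataset(8, small_phantom_config(10L), haze_params(seed = 10L),
                         file.path(base, "hq"))
    make_phantom_dataset(8, small_phantom_config(50L), haze_params(seed = 50L),
                         file.path(base, "lq"))
  }
  cfg <- train_config(iterations = 50L, batch = 1L, base_lr = 1e-3,
                      warmup_iters = 5L, patch = 64L, resize = NULL,
                      seed = 0L, finetune_iters = 0L,
                      fp_extractor = feature_extractor("vgg19", taps = 1:2,
                                                       seed = 0L))
  st <- train_syn(file.path(base, "hq", "clean"),
                  file.path(base, "lq", "degraded"), cfg)
  tt <- st$losses$total
  expect_true(all(is.finite(tt)))
  # 5-iteration moving averages: training reduces the total loss
  expect_lt(mean(utils::tail(tt, 5)), mean(utils::head(tt, 5)))
  # schedule trace covers every iteration, non-increasing after warmup
  expect_identical(nrow(st$losses), 50L)
  lrs <- st$losses$lr
  expect_true(all(diff(lrs[5:50]) <= 1e-18))
})

test_that("synthesized pairs preserve names, sizes and determinism", {
  base <- file.path(tempdir(), "synth")
  unlink(base, recursive = TRUE)
  make_phantom_dataset(3, phantom_config(height = 64, width = 64, seed = 3L),
                       haze_params(seed = 3L), file.path(base, "src"))
  g <- build_generator(tiny_gen_config(), seed = 0L)
  st <- structure(list(mode = "syn", model = g,
                       disc = build_discriminator(tiny_disc_config(), 0L),
                       config = tiny_res_args()$config,
                       weights = loss_weights("syn"), iteration = 0L,
                       losses = NULL, phase = "train", rng = NULL),
                  class = "train_state")
  m1 <- synthesize_pairs(st, file.path(base, "src", "clean"),
                         file.path(base, "out1"))
  synthesize_pairs(g, file.path(base, "src", "clean"), file.path(base, "out2"))
  f1 <- png_files(file.path(base, "out1", "degraded"))
  f2 <- png_files(file.path(base, "out2", "degraded"))
  expect_length(f1, 3)
  expect_identical(basename(f1),
                   basename(png_files(file.path(base, "src", "clean"))))
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
    expect_identical(dim(read_image(f1[i])), c(64L, 64L, 3L))
  }
})

test_that("paired crops and shared flips survive the full data pipeline", {
  # coordinate-encoding images through the sampling path used in training
  d <- file.path(tempdir(), "coordpipe")
  unlink(d, recursive = TRUE)
  dir.create(file.path(d, "clean"), recursive = TRUE)
  dir.create(file.path(d, "degraded"), recursive = TRUE)
  ci <- coord_image(64, 64)
  write_image(ci, file.path(d, "clean", "c.png"))
  write_image(ci, file.path(d, "degraded", "c.png"))
  cache <- catintell:::.image_cache(
    c(file.path(d, "clean", "c.png"), file.path(d, "degraded", "c.png")), NULL)
  set.seed(123)
  for (k in 1:10) {
    s <- catintell:::.sample_paired(file.path(d, "clean", "c.png"),
                                    file.path(d, "degraded", "c.png"),
                                    cache, 1L, NULL, 32L)
    expect_identical(s$clean, s$degraded)   # same window, same flips
  }
})
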