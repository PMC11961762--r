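# Shared fixtures: small architectures and phantom datasets built in code,
# plus a memoised 200-iteration toy restoration run shared by the
# acceptance tests.

tiny_gen_config <- function(stages = 2L, width = 4L)
  generator_config("syn", stages = stages, base_width = width)

tiny_disc_config <- function(input = 32L)
  discriminator_config(input_size = input, patch_size = 4L, embed_dim = 8L,
                       blocks_per_stage = c(2L, 2L), heads_per_stage = c(1L, 2L),
                       window = 4L)

small_phantom_config <- function(seed = 0L)
  phantom_config(height = 96L, width = 96L, seed = seed)

# coordinate-encoding image: every pixel value identifies its position
coord_image <- function(H, W) {
  arr <- array(0, c(H, W, 3))
  arr[, , 1] <- matrix(seq_len(H), H, W) / H
  arr[, , 2] <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  arr[, , 3] <- 0.5
  arr
}

toy_train_config <- function(iterations = 200L)
  train_config(iterations = iterations, batch = 1L, base_lr = 1e-3,
               warmup_iters = 20L, patch = 64L, resize = NULL, seed = 0L,
               finetune_iters = 0L,
               fp_extractor = feature_extractor("vgg19", taps = 1:2, seed = 0L))

.fixture_env <- new.env(parent = emptyenv())

toy_phantom_dirs <- function() {
  if (is.null(.fixture_env$dirs)) {
    base <- file.path(tempdir(), "catintell-toy")
    make_phantom_dataset(16, small_phantom_config(0L), haze_params(seed = 0L),
                         file.path(base, "train"))
    make_phantom_dataset(8, small_phantom_config(100L), haze_params(seed = 100L),
                         file.path(base, "test"))
    .fixture_env$dirs <- list(train = file.path(base, "train"),
                              test = file.path(base, "test"))
  }
  .fixture_env$dirs
}

# the toy restoration experiment of the acceptance suite: restoration
# architecture (4 stages, width 32), 200 iterations, 64-pixel patches,
# 16 training and 8 held-out analytic-haze phantom pairs, seed 0
toy_res_state <- function() {
  if (is.null(.fixture_env$toy_res)) {
    dirs <- toy_phantom_dirs()
    .fixture_env$toy_res <- train_res(dirs$train, toy_train_config())
  }
  .fixture_env$toy_res
}

png_files <- function(dir)
  sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))

read_pair <- function(dir, i) {
  list(clean = read_image(png_files(file.path(dir, "clean"))[i]),
       degraded = read_image(png_files(file.path(dir, "degraded"))[i]))
}
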