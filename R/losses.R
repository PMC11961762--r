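# Training losses: pixel (smooth L1), fundus perceptual (feature and Gram
# style distances through an injectable extractor), identity, and
# generator-side adversarial BCE, plus their weighted totals.

#' Smooth L1 (Huber) distance
#'
#' Mean over all elements of `0.5 d^2` where `|d| < 1` and `|d| - 0.5`
#' otherwise, with `d = target - output`.
#'
#' @param target,output equally shaped numeric arrays.
#' @return non-negative scalar.
#' @export
smooth_l1 <- function(target, output) {
  if (!identical(dim(target), dim(output)))
    stop("smooth_l1: shape mismatch")
  d <- target - output
  ad <- abs(d)
  mean(ifelse(ad < 1, 0.5 * d * d, ad - 0.5))
}

#' Gram matrix of a feature map
#'
#' Entry (a, b) is `sum_ij F_a(i,j) F_b(i,j) / (H W)`.
#'
#' @param feature H x W x C array.
#' @return C x C symmetric positive semidefinite matrix.
#' @export
gram <- function(feature) {
  d <- dim(feature)
  m <- matrix(feature, d[1] * d[2], d[3])
  crossprod(m) / (d[1] * d[2])
}

#' Feature extractor for the fundus perceptual loss
#'
#' Either the identity (a single tap returning the image itself) or a
#' VGG-19-topology convolutional extractor with taps after each of its five
#' pooling stages. Weights are seeded random by default and injectable: a
#' practitioner with an extractor fine-tuned on quality-labelled fundus
#' photographs can supply its weights through `weights` (a list of conv
#' weight/bias arrays in layer order) without changing any other code.
#'
#' @param type "identity" or "vgg19".
#' @param taps which pooling-stage taps to expose (default all five).
#' @param seed seed for the random initialisation.
#' @param weights optional externally trained conv weights.
#' @return object of class `feature_extractor`.
#' @export
feature_extractor <- function(type = c("identity", "vgg19"), taps = 1:5,
                              seed = 0L, weights = NULL) {
  type <- match.arg(type)
  if (type == "identity")
    return(structure(list(type = "identity", taps = 1L), class = "feature_extractor"))
  plan <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
               c(512, 512, 512, 512), c(512, 512, 512, 512))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  layers <- list()
  cin <- 3L
  li <- 1L
  for (b in seq_along(plan)) for (cout in plan[[b]]) {
    if (!is.null(weights)) {
      w <- weights[[li]]$w; bb <- weights[[li]]$b
      stopifnot(identical(dim(w), c(3L, 3L, cin, as.integer(cout))))
      l <- list(w = ag_param(w), b = ag_param(bb), k = 3L, cin = cin,
                cout = as.integer(cout), groups = 1L)
    } else {
      # He-style scale keeps activations bounded through 16 random layers
      sdw <- sqrt(2 / (9 * cin))
      l <- list(w = ag_param(array(rnorm(9 * cin * cout, 0, sdw),
                                   c(3L, 3L, cin, as.integer(cout)))),
                b = ag_param(numeric(cout)), k = 3L, cin = cin,
                cout = as.integer(cout), groups = 1L)
    }
    layers[[li]] <- l
    cin <- as.integer(cout)
    li <- li + 1L
  }
  structure(list(type = "vgg19", plan = plan, layers = layers,
                 taps = sort(unique(as.integer(taps))), seed = seed),
            class = "feature_extractor")
}

# Run the extractor on an image node; returns a list of feature nodes.
extractor_forward <- function(extractor, x) {
  if (extractor$type == "identity") return(list(x))
  feats <- list()
  li <- 1L
  h <- x
  for (b in seq_along(extractor$plan)) {
    for (j in seq_along(extractor$plan[[b]])) {
      h <- conv_apply(extractor$layers[[li]], h)
      h <- ag_relu(h)
      li <- li + 1L
    }
    h <- ag_avgpool2(h)
    if (b %in% extractor$taps) feats[[length(feats) + 1L]] <- h
    if (b >= max(extractor$taps)) break
  }
  feats
}

#' Fundus perceptual loss
#'
#' Content: mean squared difference of extracted features, averaged over
#' taps. Style: mean squared difference of the Gram matrices of the
#' extracted features, averaged over taps.
#'
#' @param output,reference equally shaped H x W x 3 arrays.
#' @param extractor a [feature_extractor()].
#' @return list with `content` and `style` scalars.
#' @export
fp_loss <- function(output, reference, extractor = feature_extractor("identity")) {
  if (!identical(dim(output), dim(reference))) stop("fp_loss: shape mismatch")
  ag_tape_reset(recording = FALSE)
  fo <- extractor_forward(extractor, ag_const(as4d(output)))
  fr <- extractor_forward(extractor, ag_const(as4d(reference)))
  content <- mean(vapply(seq_along(fo), function(i)
    mean((fo[[i]]$val - fr[[i]]$val)^2), 0))
  style <- mean(vapply(seq_along(fo), function(i) {
    go <- gram(fo[[i]]$val[, , , 1L])
    gr <- gram(fr[[i]]$val[, , , 1L])
    mean((go - gr)^2)
  }, 0))
  list(content = content, style = style)
}

#' Identity loss
#'
#' Smooth L1 between an image from the model's target domain and its own
#' reconstruction: restoring an already-clean image (Res), or degrading an
#' already-degraded one (Syn), should change nothing.
#'
#' @param model a built generator.
#' @param domain_image H x W x 3 array from the model's target domain.
#' @return non-negative scalar.
#' @export
identity_loss <- function(model, domain_image) {
  smooth_l1(domain_image, gen_forward(model, domain_image, clamp = FALSE))
}

#' Generator-side GAN loss (binary cross-entropy)
#'
#' `-(p_real log p_out + (1 - p_real) log(1 - p_out))`, where `p_real` is
#' the discriminator's score of a real reference image used as a soft
#' label; with `hard_labels` the label is 1.
#'
#' @param p_real,p_out probabilities in (0, 1); values at the boundary are
#'   clamped to `[1e-7, 1 - 1e-7]`.
#' @param hard_labels replace `p_real` with 1.
#' @return non-negative scalar.
#' @export
gan_loss_generator <- function(p_real, p_out, hard_labels = FALSE) {
  eps <- 1e-7
  if (hard_labels) p_real <- 1
  p_real <- pmin(pmax(p_real, eps), 1 - eps)
  p_out <- pmin(pmax(p_out, eps), 1 - eps)
  -(p_real * log(p_out) + (1 - p_real) * log(1 - p_out))
}

#' Loss weights
#'
#' Published defaults: synthesis `(pixel, fp, ide, gan) = (0.01, 1, 0.1,
#' 0.1)`; restoration `(1, 0.1, 0.01, 0.01)`. The style term enters through
#' the perceptual weight, scaled by `style_weight`.
#'
#' @param model "syn" or "res", or NULL to pass explicit weights.
#' @param w_pixel,w_fp,w_ide,w_gan non-negative reals.
#' @param style_weight multiplier of the style term inside the perceptual
#'   component.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(model = c("res", "syn"), w_pixel = NULL, w_fp = NULL,
                         w_ide = NULL, w_gan = NULL, style_weight = 1) {
  model <- match.arg(model)
  def <- if (model == "syn") c(0.01, 1, 0.1, 0.1) else c(1, 0.1, 0.01, 0.01)
  w <- c(w_pixel %||% def[1], w_fp %||% def[2], w_ide %||% def[3],
         w_gan %||% def[4])
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(list(model = model, w_pixel = w[1], w_fp = w[2], w_ide = w[3],
                 w_gan = w[4], style_weight = style_weight),
            class = "loss_weights")
}

#' Weighted total loss
#'
#' @param components named list with elements `pixel`, `fp`, `ide`, `gan`
#'   (each a scalar; `fp` may also be a list with `content` and `style`,
#'   combined as `content + style_weight * style`).
#' @param weights a [loss_weights()].
#' @return object of class `loss_value`: list with `total` and `components`.
#' @export
total_loss <- function(components, weights) {
  need <- c("pixel", "fp", "ide", "gan")
  missing <- setdiff(need, names(components))
  if (length(missing))
    stop("missing loss component(s): ", paste(missing, collapse = ", "))
  fp <- components$fp
  fpv <- if (is.list(fp)) fp$content + weights$style_weight * fp$style else fp
  comp <- c(pixel = components$pixel, fp = fpv, ide = components$ide,
            gan = components$gan)
  total <- weights$w_pixel * comp["pixel"] + weights$w_fp * comp["fp"] +
    weights$w_ide * comp["ide"] + weights$w_gan * comp["gan"]
  structure(list(total = unname(total), components = as.list(comp)),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("total %.6g (pixel %.4g, fp %.4g, ide %.4g, gan %.4g)\n",
              x$total, x$components$pixel, x$components$fp,
              x$components$ide, x$components$gan))
  invisible(x)
}
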