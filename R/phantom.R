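# Synthetic fundus phantoms and analytic haze degradation.
#
# The phantom emulates the geometry of a fundus photograph: a circular
# retinal field on a black frame, a branching vessel tree emanating from a
# bright optic disc, and a darker macula. The analytic degradation is an
# atmospheric-scattering style haze, degraded = clean * t + A * (1 - t),
# with a smooth random transmission field t that is pushed back toward its
# maximum near the optic disc (cataract haze affects the disc mildly) --
# giving every other module a fully seeded, license-free test bed.

#' Phantom configuration
#'
#' Geometry is expressed in pixels; disc and macula centres default to
#' clinically plausible positions inside the circular field.
#'
#' @param height,width image size in pixels (>= 64).
#' @param field_radius_frac field radius as a fraction of `min(H, W)/2`.
#' @param disc_center,disc_radius optic-disc centre `(row, col)` and radius.
#' @param macula_center,macula_radius macula centre and radius.
#' @param vessel_depth recursive branching levels of the vessel tree.
#' @param vessel_width0 trunk vessel width in pixels.
#' @param base_color RGB triple of the retinal background.
#' @param seed integer seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(height = 256L, width = 256L,
                           field_radius_frac = 0.95,
                           disc_center = NULL, disc_radius = NULL,
                           macula_center = NULL, macula_radius = NULL,
                           vessel_depth = 4L, vessel_width0 = 2.5,
                           base_color = c(0.82, 0.44, 0.22), seed = 0L) {
  stopifnot(height >= 64L, width >= 64L,
            field_radius_frac > 0, field_radius_frac <= 1,
            vessel_depth >= 1L, length(base_color) == 3L,
            all(base_color >= 0 & base_color <= 1))
  R <- field_radius_frac * min(height, width) / 2
  ctr <- c(height / 2, width / 2)
  if (is.null(disc_center)) disc_center <- ctr + c(0, 0.55 * R)
  if (is.null(disc_radius)) disc_radius <- 0.16 * R
  if (is.null(macula_center)) macula_center <- ctr + c(0, -0.25 * R)
  if (is.null(macula_radius)) macula_radius <- 0.22 * R
  inside <- function(p, r) sqrt(sum((p - ctr)^2)) + r <= R + 1e-9
  if (!inside(disc_center, disc_radius))
    stop("optic disc outside the circular field")
  if (!inside(macula_center, macula_radius))
    stop("macula outside the circular field")
  structure(list(height = as.integer(height), width = as.integer(width),
                 field_radius_frac = field_radius_frac,
                 disc_center = disc_center, disc_radius = disc_radius,
                 macula_center = macula_center, macula_radius = macula_radius,
                 vessel_depth = as.integer(vessel_depth),
                 vessel_width0 = vessel_width0,
                 base_color = base_color, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Haze parameters
#'
#' @param atmos_light RGB haze colour A.
#' @param t_min,t_max transmission bounds in `[0, 1]` (`t_min <= t_max`).
#' @param smoothness spatial correlation length of the transmission field,
#'   in pixels.
#' @param disc_protect factor in `[0, 1]` pulling transmission toward
#'   `t_max` near the optic disc.
#' @param seed integer seed.
#' @return object of class `haze_params`.
#' @export
haze_params <- function(atmos_light = c(0.85, 0.8, 0.72),
                        t_min = 0.35, t_max = 0.75, smoothness = 48,
                        disc_protect = 0.7, seed = 0L) {
  if (!(t_min >= 0 && t_min <= t_max && t_max <= 1))
    stop("need 0 <= t_min <= t_max <= 1")
  stopifnot(length(atmos_light) == 3L, disc_protect >= 0, disc_protect <= 1,
            smoothness >= 1)
  structure(list(atmos_light = atmos_light, t_min = t_min, t_max = t_max,
                 smoothness = smoothness, disc_protect = disc_protect,
                 seed = as.integer(seed)),
            class = "haze_params")
}

# midpoint-displacement polyline between two points
.mid_poly <- function(p0, p1, n = 3L, jitter = 0.18) {
  pts <- list(p0, p1)
  for (k in seq_len(n)) {
    new <- list(pts[[1]])
    for (i in seq_len(length(pts) - 1L)) {
      a <- pts[[i]]; b <- pts[[i + 1L]]
      m <- (a + b) / 2
      d <- b - a
      perp <- c(-d[2], d[1])
      m <- m + perp * rnorm(1, 0, jitter / 2)
      new <- c(new, list(m), list(b))
    }
    pts <- new
  }
  do.call(rbind, pts)
}

# paint a thick segment onto a logical mask (TRUE where covered)
.paint_segment <- function(mask, a, b, w) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- max(1L, floor(min(a[1], b[1]) - w)); r1 <- min(H, ceiling(max(a[1], b[1]) + w))
  c0 <- max(1L, floor(min(a[2], b[2]) - w)); c1 <- min(W, ceiling(max(a[2], b[2]) + w))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  px <- outer(rr, rep(1, length(cc)))
  py <- outer(rep(1, length(rr)), cc)
  d <- b - a
  len2 <- sum(d^2)
  if (len2 < 1e-12) {
    dist2 <- (px - a[1])^2 + (py - a[2])^2
  } else {
    t <- ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (px - (a[1] + t * d[1]))^2 + (py - (a[2] + t * d[2]))^2
  }
  hit <- dist2 <= (w / 2)^2
  mask[rr, cc] <- mask[rr, cc] | hit
  mask
}

# recursive branching vessel tree; returns the vessel mask
.vessel_tree <- function(cfg, field_r, ctr) {
  H <- cfg$height; W <- cfg$width
  mask <- matrix(FALSE, H, W)
  grow <- function(p, angle, len, w, depth) {
    if (depth <= 0L || w < 0.8 || len < 2) return(invisible(NULL))
    q <- p + len * c(sin(angle), cos(angle))
    # stay inside the field
    if (sqrt(sum((q - ctr)^2)) > 0.98 * field_r) {
      v <- q - ctr
      q <- ctr + v / sqrt(sum(v^2)) * 0.98 * field_r
    }
    poly <- .mid_poly(p, q, n = 2L, jitter = 0.12 * len)
    for (i in seq_len(nrow(poly) - 1L))
      mask <<- .paint_segment(mask, poly[i, ], poly[i + 1L, ], w)
    tip <- poly[nrow(poly), ]
    # two children, width decays by 0.7 per level
    spread <- runif(1, 0.35, 0.75)
    grow(tip, angle + spread, len * runif(1, 0.5, 0.7), w * 0.7, depth - 1L)
    grow(tip, angle - spread, len * runif(1, 0.5, 0.7), w * 0.7, depth - 1L)
  }
  n_trunk <- 6L
  angles <- seq(0, 2 * pi, length.out = n_trunk + 1L)[-(n_trunk + 1L)] +
    runif(n_trunk, -0.25, 0.25)
  for (a in angles)
    grow(cfg$disc_center, a, 0.34 * field_r * runif(1, 0.8, 1.2),
         cfg$vessel_width0, cfg$vessel_depth)
  mask
}

#' Generate a synthetic fundus phantom
#'
#' Deterministic for a fixed seed. The image is black outside the circular
#' field; the vessel tree is drawn darker than the base colour, the optic
#' disc brighter, the macula darker.
#'
#' @param config a [phantom_config()].
#' @return object of class `fundus_phantom`: list with `image` (H x W x 3),
#'   `field_mask` and `vessel_mask` (H x W logical), and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  H <- config$height; W <- config$width
  ctr <- c(H / 2, W / 2)
  R <- config$field_radius_frac * min(H, W) / 2
  px <- matrix(seq_len(H), H, W)
  py <- matrix(seq_len(W), H, W, byrow = TRUE)
  r2 <- (px - ctr[1])^2 + (py - ctr[2])^2
  field <- r2 <= R^2
  vessels <- .vessel_tree(config, R, ctr) & field
  # base colour with gentle radial falloff and low-frequency texture
  shade <- 1 - 0.25 * (r2 / R^2)
  tex <- .smooth_noise(H, W, max(8, min(H, W) / 8))
  shade <- shade * (0.95 + 0.1 * tex)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- config$base_color[c] * shade
  # optic disc: bright, soft-edged
  dd <- sqrt((px - config$disc_center[1])^2 + (py - config$disc_center[2])^2)
  disc_w <- exp(-pmax(dd - config$disc_radius, 0)^2 / (2 * (config$disc_radius / 3)^2))
  disc_w[dd <= config$disc_radius] <- 1
  disc_col <- c(0.97, 0.85, 0.55)
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - disc_w) + disc_col[c] * disc_w
  # macula: smooth darkening
  dm2 <- (px - config$macula_center[1])^2 + (py - config$macula_center[2])^2
  mac_w <- 0.45 * exp(-dm2 / (2 * config$macula_radius^2))
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - mac_w)
  # vessels: dark red, drawn over everything but the disc core
  ves_col <- c(0.45, 0.10, 0.08)
  ves_w <- ifelse(vessels, ifelse(dd <= config$disc_radius, 0.35, 0.85), 0)
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - ves_w) + ves_col[c] * ves_w
  for (c in 1:3) img[, , c][!field] <- 0
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, field_mask = field, vessel_mask = vessels,
                 config = config),
            class = "fundus_phantom")
}

#' @export
print.fundus_phantom <- function(x, ...) {
  cat(sprintf("fundus phantom %dx%d (seed %d): field %.1f%%, vessels %.1f%% of field\n",
              x$config$height, x$config$width, x$config$seed,
              100 * mean(x$field_mask),
              100 * sum(x$vessel_mask) / sum(x$field_mask)))
  invisible(x)
}

# smooth random field in [0,1]: low-resolution uniform noise, bilinear upsample
.smooth_noise <- function(H, W, corr_len) {
  nh <- max(2L, ceiling(H / corr_len) + 1L)
  nw <- max(2L, ceiling(W / corr_len) + 1L)
  g <- matrix(runif(nh * nw), nh, nw)
  resize_bilinear(array(g, c(nh, nw, 1L)), H, W)[, , 1L]
}

#' Apply analytic haze to a phantom
#'
#' `degraded = clean * t + A * (1 - t)` pixelwise inside the circular field,
#' with a smooth random transmission field `t` in `[t_min, t_max]` whose
#' spatial correlation length is `smoothness`; near the optic disc `t` is
#' pushed toward `t_max` by `disc_protect` (cataract haze degrades the disc
#' mildly). The background outside the field stays black.
#'
#' @param phantom a `fundus_phantom`.
#' @param haze a [haze_params()].
#' @return object of class `image_pair`: list with `clean`, `degraded`,
#'   `transmission`.
#' @export
apply_analytic_haze <- function(phantom, haze) {
  stopifnot(inherits(phantom, "fundus_phantom"), inherits(haze, "haze_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(haze$seed)
  img <- phantom$image
  H <- dim(img)[1]; W <- dim(img)[2]
  t <- haze$t_min + (haze$t_max - haze$t_min) * .smooth_noise(H, W, haze$smoothness)
  cfg <- phantom$config
  px <- matrix(seq_len(H), H, W)
  py <- matrix(seq_len(W), H, W, byrow = TRUE)
  dd2 <- (px - cfg$disc_center[1])^2 + (py - cfg$disc_center[2])^2
  prot <- haze$disc_protect * exp(-dd2 / (2 * (1.8 * cfg$disc_radius)^2))
  t <- t + (haze$t_max - t) * prot
  deg <- img
  for (c in 1:3) {
    ch <- img[, , c] * t + haze$atmos_light[c] * (1 - t)
    ch[!phantom$field_mask] <- 0
    deg[, , c] <- ch
  }
  structure(list(clean = img, degraded = pmin(pmax(deg, 0), 1),
                 transmission = t),
            class = "image_pair")
}

#' Paired random crop
#'
#' Crops the same `size x size` window from two equally-sized images.
#'
#' @param a,b H x W x 3 arrays of identical size.
#' @param size crop side in pixels.
#' @param seed integer seed for the window position.
#' @return list with cropped `a` and `b`.
#' @export
paired_random_crop <- function(a, b, size, seed = NULL) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:2] == db[1:2])) stop("images differ in size")
  if (size > da[1] || size > da[2])
    stop(sprintf("crop size %d exceeds image size %dx%d", size, da[1], da[2]))
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  h0 <- if (da[1] == size) 0L else sample.int(da[1] - size, 1L)
  w0 <- if (da[2] == size) 0L else sample.int(da[2] - size, 1L)
  list(a = a[h0 + seq_len(size), w0 + seq_len(size), , drop = FALSE],
       b = b[h0 + seq_len(size), w0 + seq_len(size), , drop = FALSE])
}

flip_image <- function(image, horizontal = FALSE, vertical = FALSE) {
  if (vertical) image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  if (horizontal) image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  image
}

#' Shared flip augmentation of an image pair
#'
#' Horizontal and vertical flips, each with probability 0.5, the same
#' decision applied to both images.
#'
#' @param pair an `image_pair` (or any list with `clean` and `degraded`).
#' @param seed integer seed.
#' @param horizontal,vertical override the random decisions.
#' @return augmented pair of the same class.
#' @export
augment_pair <- function(pair, seed = NULL, horizontal = NULL, vertical = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  h <- if (is.null(horizontal)) runif(1) < 0.5 else isTRUE(horizontal)
  v <- if (is.null(vertical)) runif(1) < 0.5 else isTRUE(vertical)
  pair$clean <- flip_image(pair$clean, h, v)
  pair$degraded <- flip_image(pair$degraded, h, v)
  pair
}

#' Write a phantom dataset to disk
#'
#' Writes `n` clean/degraded PNG pairs under `out_dir/clean/NNNN.png` and
#' `out_dir/degraded/NNNN.png` plus a JSON manifest recording per-image
#' seeds and haze parameters, from which the dataset can be regenerated
#' bit-identically.
#'
#' @param n number of pairs.
#' @param config a [phantom_config()]; per-image seeds are `config$seed + i - 1`.
#' @param haze a [haze_params()]; per-image haze seeds offset the same way.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
make_phantom_dataset <- function(n, config = phantom_config(),
                                 haze = haze_params(), out_dir) {
  dir.create(file.path(out_dir, "clean"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "degraded"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config; cfg_i$seed <- config$seed + i - 1L
    hz_i <- haze; hz_i$seed <- haze$seed + i - 1L
    ph <- generate_phantom(cfg_i)
    pr <- apply_analytic_haze(ph, hz_i)
    fn <- sprintf("%04d.png", i - 1L)
    write_image(pr$clean, file.path(out_dir, "clean", fn))
    write_image(pr$degraded, file.path(out_dir, "degraded", fn))
    items[[i]] <- list(filename = fn, seed = cfg_i$seed,
                       haze = hz_i[c("atmos_light", "t_min", "t_max",
                                     "smoothness", "disc_protect", "seed")])
  }
  manifest <- list(n = n,
                   phantom = config[setdiff(names(config), "seed")],
                   items = items)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
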