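# Image input/output and resizing. Images are H x W x 3 arrays of reals in
# [0, 1]; files are 8-bit RGB PNG. Quantisation on write is round-half-up;
# reading divides by 255.

#' Read an RGB image
#'
#' @param path a PNG file.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  q <- floor(image * 255 + 0.5) / 255   # round-half-up to 8-bit levels
  png::writePNG(q, path)
  invisible(path)
}

#' Bilinear resize
#'
#' Separable bilinear interpolation; for downscaling by more than 2x the
#' image is first repeatedly box-halved (antialiasing), then interpolated.
#'
#' @param image H x W x C array.
#' @param height,width output size.
#' @return resized array.
#' @export
resize_bilinear <- function(image, height, width) {
  d <- dim(image)
  while (d[1] >= 2 * height && d[2] >= 2 * width &&
         d[1] %% 2 == 0 && d[2] %% 2 == 0) {
    image <- .cpp_avgpool2_fw(as4d(image), dim(as4d(image)))[, , , 1L]
    d <- dim(image)
  }
  if (d[1] == height && d[2] == width) return(image)
  map <- function(n_out, n_in) {
    # align-centres source coordinates
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    s <- pmin(pmax(s, 1), n_in)
    i0 <- pmin(floor(s), n_in - 1L)
    list(i0 = as.integer(i0), f = s - i0)
  }
  mh <- map(height, d[1]); mw <- map(width, d[2])
  out <- array(0, c(height, width, d[3]))
  for (c in seq_len(d[3])) {
    ch <- image[, , c]
    top <- ch[mh$i0, , drop = FALSE] * (1 - mh$f) + ch[mh$i0 + 1L, , drop = FALSE] * mh$f
    out[, , c] <- top[, mw$i0, drop = FALSE] * (1 - mw$f) +
      top[, mw$i0 + 1L, drop = FALSE] * mw$f
  }
  out
}

#' Centre-crop an image to a square
#'
#' @param image H x W x C array.
#' @return square image of side `min(H, W)`.
#' @export
center_crop_square <- function(image) {
  d <- dim(image)
  s <- min(d[1], d[2])
  h0 <- (d[1] - s) %/% 2L
  w0 <- (d[2] - s) %/% 2L
  image[h0 + seq_len(s), w0 + seq_len(s), , drop = FALSE]
}

list_images <- function(dir) {
  f <- sort(list.files(dir, pattern = "\\.png$", ignore.case = TRUE,
                       full.names = TRUE))
  if (!length(f)) stop("no PNG images found in ", dir)
  f
}
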