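# Reference image-quality metrics: PSNR on RGB mean-squared error with unit
# dynamic range, and SSIM on ITU-R 601 luma with the classic 11x11 Gaussian
# window (sigma 1.5, K1 = 0.01, K2 = 0.03), averaged over valid window
# positions.

#' Peak signal-to-noise ratio
#'
#' `10 log10(1 / MSE)` for images in `[0, 1]`, with MSE over all RGB
#' elements; identical images return the documented 100 dB cap.
#'
#' @param reference,test equally shaped arrays in `[0, 1]`.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test) {
  if (!identical(dim(reference), dim(test))) stop("psnr: shape mismatch")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(100)
  min(10 * log10(1 / mse), 100)
}

.luma <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

.gauss_win <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# valid-region filtering of a matrix with a separable-equivalent 2-d kernel
.filter2_valid <- function(m, w) {
  k <- nrow(w)
  x <- array(m, c(dim(m), 1L, 1L))
  wk <- array(w, c(k, k, 1L, 1L))
  .cpp_conv2d_fw(x, dim(x), wk, dim(wk), numeric(0), 1L, 0L, 1L, FALSE)$y[, , 1L, 1L]
}

#' Structural similarity index
#'
#' Mean SSIM over valid 11x11 Gaussian-window positions, computed on the
#' ITU-R 601 luma of RGB input, with dynamic range 1.
#'
#' @param reference,test equally shaped H x W x 3 arrays, min dimension >= 11.
#' @param window,sigma,K1,K2 SSIM constants.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, window = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(reference), dim(test))) stop("ssim: shape mismatch")
  d <- dim(reference)
  if (min(d[1], d[2]) < window)
    stop(sprintf("ssim: image min dimension %d below window %d",
                 min(d[1], d[2]), window))
  x <- .luma(reference); y <- .luma(test)
  w <- .gauss_win(window, sigma)
  C1 <- K1^2; C2 <- K2^2
  mx <- .filter2_valid(x, w); my <- .filter2_valid(y, w)
  mxx <- .filter2_valid(x * x, w); myy <- .filter2_valid(y * y, w)
  mxy <- .filter2_valid(x * y, w)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Evaluate directories of prediction/reference pairs
#'
#' Matches files by name, computes per-image PSNR and SSIM and their
#' aggregates, optionally writing a CSV.
#'
#' @param pred_dir,ref_dir directories of equally named PNG images.
#' @param out_csv optional CSV path for the per-image table.
#' @return object of class `metric_report`.
#' @export
evaluate_pairs <- function(pred_dir, ref_dir, out_csv = NULL) {
  pf <- list_images(pred_dir); rf <- list_images(ref_dir)
  pn <- basename(pf); rn <- basename(rf)
  orphans <- c(setdiff(pn, rn), setdiff(rn, pn))
  if (length(orphans))
    stop("unmatched files: ", paste(orphans, collapse = ", "))
  tab <- data.frame(file = pn,
                    psnr = NA_real_, ssim = NA_real_)
  for (i in seq_along(pn)) {
    p <- read_image(pf[i])
    r <- read_image(file.path(ref_dir, pn[i]))
    tab$psnr[i] <- psnr(r, p)
    tab$ssim[i] <- ssim(r, p)
  }
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  structure(list(per_image = tab, n = nrow(tab),
                 mean_psnr = mean(tab$psnr), sd_psnr = stats::sd(tab$psnr),
                 mean_ssim = mean(tab$ssim), sd_ssim = stats::sd(tab$ssim)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%d image pair(s): PSNR %.2f dB (sd %.2f), SSIM %.4f (sd %.4f)\n",
              x$n, x$mean_psnr, ifelse(x$n > 1, x$sd_psnr, 0),
              x$mean_ssim, ifelse(x$n > 1, x$sd_ssim, 0)))
  invisible(x)
}
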