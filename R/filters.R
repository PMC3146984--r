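#' Median filtering for noise reduction
#'
#' Applies a square median filter per channel, the standard denoising step
#' before color conversion. Image borders are replicated so the output has the
#' input's shape.
#'
#' @param image A numeric matrix or a `rows x cols x channels` array.
#' @param window Odd window side in pixels; default 5 (the reference 5x5
#'   filter).
#' @return Filtered image of the same shape.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1   # single impulse
#' max(median_denoise(m, 3))            # 0: impulse removed
#' @export
median_denoise <- function(image, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  if (window == 1L) return(image)
  if (is.matrix(image)) return(median_filter_cpp(image, window))
  if (length(dim(image)) == 3) {
    out <- image
    for (ch in seq_len(dim(image)[3]))
      out[, , ch] <- median_filter_cpp(image[, , ch], window)
    return(out)
  }
  stop("'image' must be a matrix or a 3-D array", call. = FALSE)
}

# Center-aligned bilinear resampling of one matrix to nr x nc.
bilinear_resize_matrix <- function(x, nr, nc) {
  map <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5  # 1-based src coordinate
    s <- pmin(pmax(s, 1), n_in)
    i0 <- pmin(floor(s), n_in - 1L); i0[n_in == 1] <- 1
    list(i0 = as.integer(i0), w = s - i0)
  }
  r <- map(nr, nrow(x)); cl <- map(nc, ncol(x))
  xr <- x[r$i0, , drop = FALSE] * (1 - r$w) +
        x[pmin(r$i0 + 1L, nrow(x)), , drop = FALSE] * r$w
  wc <- matrix(cl$w, nr, nc, byrow = TRUE)
  xr[, cl$i0, drop = FALSE] * (1 - wc) +
    xr[, pmin(cl$i0 + 1L, ncol(x)), drop = FALSE] * wc
}

#' Bilinear downsampling to a working resolution
#'
#' Full-resolution frames are downsampled by bilinear interpolation before
#' segmentation to speed up classification (default target 826 x 826). Pixel
#' centers are aligned: output pixel `t` samples input coordinate
#' `(t - 0.5) * side / target + 0.5`.
#'
#' @param image Square numeric matrix or `side x side x channels` array.
#' @param target_side_px Target side in pixels, at most the input side.
#' @return List with `image` (resized) and `scale` (`target_side_px / side`),
#'   the factor to pass to [rescale_geometry()].
#' @export
downsample_image <- function(image, target_side_px = 826L) {
  d <- dim(image)
  if (d[1] != d[2])
    stop("'image' must be square; embed non-square frames first", call. = FALSE)
  target_side_px <- as.integer(target_side_px)
  if (target_side_px > d[1])
    stop("upsampling requested: target side exceeds image side", call. = FALSE)
  if (target_side_px == d[1]) return(list(image = image, scale = 1))
  if (is.matrix(image)) {
    out <- bilinear_resize_matrix(image, target_side_px, target_side_px)
  } else {
    out <- array(0, c(target_side_px, target_side_px, d[3]))
    for (ch in seq_len(d[3]))
      out[, , ch] <- bilinear_resize_matrix(image[, , ch],
                                            target_side_px, target_side_px)
  }
  list(image = out, scale = target_side_px / d[1])
}

# Gaussian smoothing of a numeric matrix, replicate boundary; sigma in px.
gaussian_smooth <- function(x, sigma_px) {
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  g <- dnorm(-r:r, sd = sigma_px)
  k <- outer(g, g)
  k <- k / sum(k)
  EBImage::filter2(x, k, boundary = "replicate")
}

# Embed a non-square frame into the smallest containing square, zero-padded;
# returns the padded image plus the (row, col) offset of the original corner.
embed_square <- function(image) {
  d <- dim(image)
  if (d[1] == d[2]) return(list(image = image, offset = c(0L, 0L)))
  side <- max(d[1], d[2])
  off <- c((side - d[1]) %/% 2L, (side - d[2]) %/% 2L)
  if (length(d) == 3) {
    out <- array(0, c(side, side, d[3]))
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- image
  } else {
    out <- matrix(0, side, side)
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- image
  }
  list(image = out, offset = off)
}
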