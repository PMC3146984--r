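# sRGB (IEC 61966-2-1) -> XYZ (D65) linear matrix and white point.
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
# White point taken as the image of RGB (1,1,1) under the matrix, so that
# achromatic grays map to exactly u* = v* = 0.
.d65_white <- c(X = sum(.srgb_to_xyz[1, ]), Y = sum(.srgb_to_xyz[2, ]),
                Z = sum(.srgb_to_xyz[3, ]))

# u', v' chromaticity of an XYZ triple set; denominators guarded for black.
.uv_prime <- function(X, Y, Z) {
  den <- X + 15 * Y + 3 * Z
  den[den == 0] <- 1
  list(u = 4 * X / den, v = 9 * Y / den)
}

#' Convert an 8-bit RGB image to CIE L*u*v*
#'
#' The classifier operates in the approximately perceptually uniform CIE
#' L*u*v* space. The conversion assumes sRGB primaries with the D65 white
#' point (consumer-camera acquisition): sRGB companding is inverted, linear
#' RGB is mapped to XYZ, and XYZ to L*u*v*.
#'
#' @param image Numeric array `rows x cols x 3` with values in `[0, 255]`.
#' @param geom Optional `"ics_geometry"`; when supplied, its [field_mask()] is
#'   attached so downstream stages ignore pixels outside the circular field.
#'   When `NULL`, the full frame is valid.
#' @param white White point as an `c(X, Y, Z)` triple; default D65.
#'
#' @return An object of class `"luv_image"`: list with matrices `L` (in
#'   `[0, 100]`), `u`, `v`, and logical `field_mask`.
#' @examples
#' img <- array(255, c(2, 2, 3))        # white frame
#' luv <- rgb_to_luv(img)
#' luv$L[1, 1]                          # 100
#' @export
rgb_to_luv <- function(image, geom = NULL, white = .d65_white) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("'image' must be a rows x cols x 3 RGB array", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("RGB values must lie in [0, 255]", call. = FALSE)
  d <- dim(image)[1:2]
  rgb <- matrix(as.numeric(image), ncol = 3) / 255

  # inverse sRGB companding
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz)

  Y <- xyz[, 2] / white[2]
  L <- ifelse(Y > (6 / 29)^3, 116 * Y^(1 / 3) - 16, (29 / 3)^3 * Y)
  uv  <- .uv_prime(xyz[, 1], xyz[, 2], xyz[, 3])
  uvn <- .uv_prime(white[1], white[2], white[3])
  u <- 13 * L * (uv$u - uvn$u)
  v <- 13 * L * (uv$v - uvn$v)

  mask <- if (is.null(geom)) matrix(TRUE, d[1], d[2]) else field_mask(geom)
  structure(list(
    L = matrix(L, d[1], d[2]),
    u = matrix(u, d[1], d[2]),
    v = matrix(v, d[1], d[2]),
    field_mask = mask
  ), class = "luv_image")
}

# Inverse map used by the synthetic generator: L*u*v* -> sRGB in [0,1].
luv_to_rgb <- function(L, u, v, white = .d65_white) {
  uvn <- .uv_prime(white[1], white[2], white[3])
  Y <- ifelse(L > 8, white[2] * ((L + 16) / 116)^3, white[2] * L * (3 / 29)^3)
  up <- ifelse(L > 0, u / (13 * L) + uvn$u, uvn$u)
  vp <- ifelse(L > 0, v / (13 * L) + uvn$v, uvn$v)
  vp[vp == 0] <- 1e-12
  X <- Y * 9 * up / (4 * vp)
  Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
  lin <- cbind(X, Y, Z) %*% t(solve(.srgb_to_xyz))
  lin <- pmin(pmax(lin, 0), 1)
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * lin^(1 / 2.4) - 0.055)
  pmin(pmax(srgb, 0), 1)
}

#' @export
print.luv_image <- function(x, ...) {
  cat(sprintf("L*u*v* image %d x %d, %d field pixels, L range [%.1f, %.1f]\n",
              nrow(x$L), ncol(x$L), sum(x$field_mask),
              min(x$L[x$field_mask]), max(x$L[x$field_mask])))
  invisible(x)
}
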