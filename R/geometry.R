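#' Acquisition geometry of a dermoscopic frame
#'
#' A dermoscope images a circular field of known physical diameter. All
#' length-denominated algorithm parameters (seed box sides, structuring-element
#' diameters, score bandwidths, tolerances) are stated in millimetres and
#' converted to pixels through this object, so that the same settings apply
#' across acquisition resolutions.
#'
#' @param field_diameter_mm Physical diameter of the circular imaged field, in
#'   mm. The reference acquisition setup images about 17.4 mm.
#' @param field_diameter_px Diameter of the same field in pixels (e.g. 1650 at
#'   full resolution).
#' @param image_shape Integer vector `c(rows, cols)` of the image the geometry
#'   refers to. The field center is placed at the image midpoint.
#' @param d1_radius_mm Radius, in mm, of the central disk `d1` assumed to
#'   contain (part of) the lesion; the annulus between `d1_radius_mm` and the
#'   field radius is the skin search domain `d2`. Default 5.
#'
#' @return An object of class `"ics_geometry"`: a list with `center` (row, col
#'   of the field center, 1-based pixel coordinates), `field_radius_mm`,
#'   `field_radius_px`, `px_per_mm`, `d1_radius_mm` and `image_shape`.
#' @examples
#' g <- build_geometry(17.4, 1650, c(1650, 1650))
#' g$px_per_mm          # ~94.8 px per mm
#' mm_to_px(g, 5)       # d1 radius in pixels
#' @export
build_geometry <- function(field_diameter_mm, field_diameter_px, image_shape,
                           d1_radius_mm = 5.0) {
  if (!is.numeric(field_diameter_mm) || length(field_diameter_mm) != 1 ||
      !is.finite(field_diameter_mm) || field_diameter_mm <= 0)
    stop("'field_diameter_mm' must be a positive scalar", call. = FALSE)
  if (!is.numeric(field_diameter_px) || length(field_diameter_px) != 1 ||
      !is.finite(field_diameter_px) || field_diameter_px <= 0)
    stop("'field_diameter_px' must be a positive scalar", call. = FALSE)
  image_shape <- as.integer(image_shape[1:2])
  if (any(is.na(image_shape)) || any(image_shape <= 0))
    stop("'image_shape' must be two positive integers", call. = FALSE)
  if (d1_radius_mm <= 0 || d1_radius_mm >= field_diameter_mm / 2)
    stop("'d1_radius_mm' must lie strictly inside the field radius",
         call. = FALSE)
  structure(list(
    center          = (image_shape + 1) / 2,
    field_radius_mm = field_diameter_mm / 2,
    field_radius_px = field_diameter_px / 2,
    px_per_mm       = field_diameter_px / field_diameter_mm,
    d1_radius_mm    = d1_radius_mm,
    image_shape     = image_shape
  ), class = "ics_geometry")
}

#' @export
print.ics_geometry <- function(x, ...) {
  cat(sprintf(
    "Dermoscope geometry: %.3g mm field (%.4g px/mm), image %d x %d, d1 radius %.3g mm\n",
    2 * x$field_radius_mm, x$px_per_mm, x$image_shape[1], x$image_shape[2],
    x$d1_radius_mm))
  invisible(x)
}

#' Convert between millimetres and pixels
#'
#' @param geom An `"ics_geometry"` object.
#' @param mm,px Lengths to convert.
#' @return Numeric vector of converted lengths.
#' @export
mm_to_px <- function(geom, mm) mm * geom$px_per_mm

#' @rdname mm_to_px
#' @export
px_to_mm <- function(geom, px) px / geom$px_per_mm

#' Rescale a geometry after resampling
#'
#' After the image is resampled by a linear factor (e.g. bilinear
#' downsampling), the pixel scale changes but every mm-denominated quantity is
#' unchanged.
#'
#' @param geom An `"ics_geometry"` object.
#' @param scale Linear scale factor (new side / old side).
#' @param image_shape New image shape; defaults to `round(old * scale)`.
#' @return The rescaled `"ics_geometry"`.
#' @export
rescale_geometry <- function(geom, scale, image_shape = NULL) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("'scale' must be a positive scalar", call. = FALSE)
  if (is.null(image_shape)) image_shape <- as.integer(round(geom$image_shape * scale))
  build_geometry(2 * geom$field_radius_mm,
                 2 * geom$field_radius_px * scale,
                 image_shape,
                 d1_radius_mm = geom$d1_radius_mm)
}

# Squared distance (px^2) of every pixel from the field center; reused by the
# field mask, the d1/d2 domains and the region score.
radius_sq_px <- function(geom) {
  n <- geom$image_shape
  dr <- (seq_len(n[1]) - geom$center[1])^2
  dc <- (seq_len(n[2]) - geom$center[2])^2
  outer(dr, dc, `+`)
}

#' Binary masks of the acquisition domains
#'
#' `field_mask()` marks pixels inside the circular imaged field,
#' `d1_mask()` the central disk assumed to contain the lesion, and
#' `d2_mask()` the peripheral annulus assumed to contain skin.
#'
#' @param geom An `"ics_geometry"` object.
#' @return A logical matrix of the geometry's image shape.
#' @export
field_mask <- function(geom) {
  radius_sq_px(geom) <= geom$field_radius_px^2
}

#' @rdname field_mask
#' @export
d1_mask <- function(geom) {
  radius_sq_px(geom) <= mm_to_px(geom, geom$d1_radius_mm)^2
}

#' @rdname field_mask
#' @export
d2_mask <- function(geom) {
  r2 <- radius_sq_px(geom)
  r2 > mm_to_px(geom, geom$d1_radius_mm)^2 & r2 <= geom$field_radius_px^2
}

# Axis-aligned quadrant masks about the field center, in row-major order:
# 1 top-left, 2 top-right, 3 bottom-left, 4 bottom-right.
quadrant_mask <- function(geom, q) {
  n <- geom$image_shape
  rows <- seq_len(n[1]) < geom$center[1]
  cols <- seq_len(n[2]) < geom$center[2]
  switch(q,
    outer(rows, cols, `&`),
    outer(rows, !cols, `&`),
    outer(!rows, cols, `&`),
    outer(!rows, !cols, `&`))
}
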