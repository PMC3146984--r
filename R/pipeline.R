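#' Read an 8-bit RGB image file
#'
#' Reads PNG (or TIFF, when the tiff package is available) into a
#' `rows x cols x 3` array with values in 0-255. Grayscale images are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path File path.
#' @return Numeric array `rows x cols x 3`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Run the full segmentation pipeline on an image file
#'
#' Thin orchestration around [ics()]: reads the image, resolves the
#' acquisition geometry, runs the segmenter, and (optionally) writes the
#' artifacts a shell user expects: the binary mask as a 0/255 PNG, the border
#' as a CSV in both px and mm, the seed boxes, the per-iteration trace, and a
#' machine-readable JSON run summary sufficient to reconstruct the lambda and
#' m traces.
#'
#' @param image_path Path of an 8-bit RGB PNG/TIFF.
#' @param control An [ics_control()].
#' @param px_per_mm Pixel pitch of the input; alternatively give
#'   `field_diameter_mm` and let the field span the image.
#' @param field_diameter_mm Physical field diameter; default 17.4.
#' @param out_dir Output directory; `NULL` suppresses writing.
#' @return The `"ics"` fit, invisibly; attribute `"artifacts"` lists written
#'   files.
#' @export
run_pipeline <- function(image_path, control = ics_control(),
                         px_per_mm = NULL, field_diameter_mm = 17.4,
                         out_dir = NULL) {
  img <- read_rgb(image_path)
  side <- max(dim(img)[1:2])
  geom <- if (!is.null(px_per_mm))
    build_geometry(side / px_per_mm, side, c(side, side))
  else
    build_geometry(field_diameter_mm, side, c(side, side))
  fit <- ics(img, geom, control)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    png::writePNG(fit$mask * 1, p("mask.png"))
    utils::write.csv(fit$trace, p("trace.csv"), row.names = FALSE)
    utils::write.csv(seed_table(c(fit$seeds$skin, list(fit$seeds$lesion))),
                     p("seeds.csv"), row.names = FALSE)
    paths <- c(p("mask.png"), p("trace.csv"), p("seeds.csv"))
    if (!is.null(fit$contour)) {
      mm <- contour_to_mm(fit$contour)
      utils::write.csv(
        data.frame(row_px = fit$contour[, "row"], col_px = fit$contour[, "col"],
                   x_mm = mm[, "x"], y_mm = mm[, "y"]),
        p("contour.csv"), row.names = FALSE)
      paths <- c(paths, p("contour.csv"))
    }
    summ <- list(
      image = image_path, converged = fit$converged,
      iterations = fit$iterations, flags = as.list(fit$flags),
      lambda_trace = fit$trace$lambda, m_trace = fit$trace$m,
      lesion_found = attr(fit$mask, "found"),
      lesion_area_mm2 = sum(fit$mask) / fit$geometry$px_per_mm^2,
      px_per_mm = fit$geometry$px_per_mm,
      control = unclass(fit$control))
    jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    paths <- c(paths, p("summary.json"))
  }
  attr(fit, "artifacts") <- paths
  invisible(fit)
}

#' Read and write segmentation configuration files
#'
#' A flat key-value YAML file mirroring [ics_control()]; round-trips without
#' loss.
#'
#' @param path File path.
#' @param control An `"ics_control"` to write.
#' @return `read_ics_config()` returns an `"ics_control"`.
#' @export
read_ics_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$priors)) vals$priors <- as.numeric(unlist(vals$priors))
  do.call(ics_control, vals)
}

#' @rdname read_ics_config
#' @export
write_ics_config <- function(control, path) {
  stopifnot(inherits(control, "ics_control"))
  vals <- unclass(control)
  vals$priors <- as.numeric(vals$priors)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Batch evaluation from a manifest
#'
#' Evaluates candidate masks against reference masks for a manifest CSV with
#' columns `image` (optional), `candidate` and `reference` (PNG mask paths),
#' or the `image`/`mask` manifest written by [synth_dataset()] together with
#' freshly computed segmentations.
#'
#' @param manifest A data.frame or CSV path with columns `candidate` and
#'   `reference`.
#' @param geom An `"ics_geometry"` shared by all pairs, or `NULL` to build one
#'   per pair assuming a 17.4 mm field spanning the mask.
#' @param tau_mm Contour tolerance in mm.
#' @return data.frame with one row per pair: sensitivity, specificity,
#'   Hausdorff distance (mm) and `e_tau`.
#' @export
evaluate_manifest <- function(manifest, geom = NULL, tau_mm = 0.5) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  read_mask <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    cand <- read_mask(manifest$candidate[i])
    ref <- read_mask(manifest$reference[i])
    g <- if (is.null(geom))
      build_geometry(17.4, max(dim(cand)), dim(cand)) else geom
    ev <- evaluate_masks(cand, ref, g, tau_mm)
    data.frame(candidate = manifest$candidate[i],
               reference = manifest$reference[i],
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               hausdorff_mm = ev$hausdorff_mm, e_tau = ev$e_tau)
  })
  do.call(rbind, rows)
}
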