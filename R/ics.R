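#' Control parameters for iterative classification segmentation
#'
#' Collects every tunable of the segmenter with its default. All
#' length-denominated parameters are in millimetres and are converted to
#' pixels once per run through the acquisition geometry (after any
#' downsampling), so the same settings apply across resolutions.
#'
#' @param w_skin_mm Skin seed box side (mm); default 1.
#' @param w_mole_mm Lesion seed box side (mm); default 1.5.
#' @param d1_radius_mm Radius of the central lesion-search disk (mm); default 5.
#' @param tau_conf Posterior confidence threshold for harvesting training
#'   pixels; default 0.98.
#' @param lambda_grid_step Grid resolution for the LDA/QDA mixing weight;
#'   default 0.01.
#' @param opening_mm Disk diameter for the candidate-region opening; default 1.
#' @param erode_mm,dilate_mm Disk diameters of the postprocessing erosion and
#'   dilation; defaults 0.12 and 0.3.
#' @param connect_bw_mm Gaussian bandwidth of the region-connecting filter;
#'   default 0.06 (the erosion radius).
#' @param connect_threshold Threshold on the blurred mask; default 0.1.
#' @param sigma_score_mm Bandwidth of the center-weighted region score;
#'   default 2.5.
#' @param conv_tol Relative tolerance of the convergence rule; default 0.01.
#' @param max_iterations Iteration cap; default 30.
#' @param target_side_px Downsampling target for large frames; default 826.
#' @param median_window Median filter window (odd px); default 5.
#' @param priors Class priors `c(skin, lesion)`; default equal.
#' @param rng_seed Seed governing all stochastic draws; default 0.
#' @param tau_eval_mm Contour tolerance used by evaluation helpers; default 0.5.
#' @param seed_scan_stride Stride of the seed box scans (1 = exhaustive).
#' @return An object of class `"ics_control"`.
#' @export
ics_control <- function(w_skin_mm = 1.0, w_mole_mm = 1.5, d1_radius_mm = 5.0,
                        tau_conf = 0.98, lambda_grid_step = 0.01,
                        opening_mm = 1.0, erode_mm = 0.12, dilate_mm = 0.3,
                        connect_bw_mm = 0.06, connect_threshold = 0.1,
                        sigma_score_mm = 2.5, conv_tol = 0.01,
                        max_iterations = 30L, target_side_px = 826L,
                        median_window = 5L, priors = c(0.5, 0.5),
                        rng_seed = 0L, tau_eval_mm = 0.5,
                        seed_scan_stride = 1L) {
  ctrl <- list(w_skin_mm = w_skin_mm, w_mole_mm = w_mole_mm,
               d1_radius_mm = d1_radius_mm, tau_conf = tau_conf,
               lambda_grid_step = lambda_grid_step, opening_mm = opening_mm,
               erode_mm = erode_mm, dilate_mm = dilate_mm,
               connect_bw_mm = connect_bw_mm,
               connect_threshold = connect_threshold,
               sigma_score_mm = sigma_score_mm, conv_tol = conv_tol,
               max_iterations = as.integer(max_iterations),
               target_side_px = as.integer(target_side_px),
               median_window = as.integer(median_window),
               priors = c(skin = priors[1], lesion = priors[2]),
               rng_seed = as.integer(rng_seed), tau_eval_mm = tau_eval_mm,
               seed_scan_stride = as.integer(seed_scan_stride))
  pos <- c("w_skin_mm", "w_mole_mm", "d1_radius_mm", "opening_mm", "erode_mm",
           "dilate_mm", "connect_bw_mm", "sigma_score_mm", "tau_eval_mm")
  for (p in pos) if (ctrl[[p]] <= 0)
    stop(sprintf("'%s' must be positive", p), call. = FALSE)
  for (p in c("tau_conf", "connect_threshold", "conv_tol"))
    if (ctrl[[p]] <= 0 || ctrl[[p]] >= 1)
      stop(sprintf("'%s' must lie in (0, 1)", p), call. = FALSE)
  structure(ctrl, class = "ics_control")
}

#' Segment a dermoscopic image by iterative classification
#'
#' Fits the iterative classification segmenter to one dermoscopic frame.
#' The image is median filtered, optionally downsampled, and converted to CIE
#' L*u*v*. Skin and lesion seed boxes are placed automatically from the
#' acquisition assumptions (lighter skin in the peripheral annulus, most
#' dissimilar patch in the central disk) and split into disjoint LDA/QDA
#' training halves. Each iteration fits both Gaussian discriminants, picks
#' the posterior mixing weight maximizing the minimum per-class seed accuracy,
#' classifies every field pixel, harvests high-confidence pixels (lesion
#' pixels only inside a morphologically safeguarded candidate region) and
#' refreshes half of the training set, until the count of high-confidence
#' lesion pixels stabilizes or the iteration cap is reached. The final
#' classification is cleaned, the best center-weighted region kept and
#' hole-filled, and its border traced.
#'
#' @param image An RGB array (`rows x cols x 3`, values 0-255) or the path of
#'   an 8-bit RGB PNG/TIFF file.
#' @param geometry An `"ics_geometry"`, or `NULL` to build one from
#'   `field_diameter_mm` assuming the field spans the image.
#' @param control An [ics_control()] object.
#' @param field_diameter_mm Used when `geometry` is `NULL`; default 17.4.
#' @return An object of class `"ics"`: list with `mask` (final single-lesion
#'   logical matrix), `raw_mask` (argmax classification before
#'   postprocessing), `contour` (`"ics_contour"` or `NULL`), `trace`
#'   (data.frame with one row per iteration: `k`, `lambda`, `m`,
#'   `n_train_skin`, `n_train_lesion`), `seeds`, `classifiers`, `posterior`,
#'   `luv`, `geometry`, `control`, `converged`, `iterations`, `flags`.
#' @examples
#' \donttest{
#' frame <- synth_image(synth_spec(image_side_px = 256, rng_seed = 7))
#' fit <- ics(frame$image, frame$geom)
#' fit
#' }
#' @export
ics <- function(image, geometry = NULL, control = ics_control(),
                field_diameter_mm = 17.4) {
  stopifnot(inherits(control, "ics_control"))
  if (is.character(image)) image <- read_rgb(image)
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("'image' must be a rows x cols x 3 RGB array", call. = FALSE)

  emb <- embed_square(image)
  image <- emb$image
  side <- dim(image)[1]
  if (is.null(geometry))
    geometry <- build_geometry(field_diameter_mm, side, c(side, side))

  # --- preprocessing -------------------------------------------------------
  image <- median_denoise(image, control$median_window)
  if (side > control$target_side_px) {
    ds <- downsample_image(image, control$target_side_px)
    image <- ds$image
    geometry <- rescale_geometry(geometry, ds$scale)
  }
  geometry$d1_radius_mm <- control$d1_radius_mm
  luv <- rgb_to_luv(image, geometry)

  # --- stage 1: seeds ------------------------------------------------------
  skin4 <- select_skin_seeds(luv, geometry, control$w_skin_mm,
                             stride = control$seed_scan_stride)
  skin3 <- prune_to_three(skin4)
  skin_mean_L <- {
    px <- unlist(lapply(skin3, `[[`, "pixels"))
    mean(luv$L[px])
  }
  lesion_seed <- select_lesion_seed(luv, skin_mean_L, geometry,
                                    control$w_mole_mm,
                                    stride = control$seed_scan_stride)
  split <- split_seed_samples(skin3, lesion_seed, luv)

  # --- stages 2-3: iterative classification --------------------------------
  trace <- list()
  m_prev <- NA_integer_
  converged <- FALSE
  flags <- character(0)
  post <- NULL
  fits <- NULL
  for (k in seq_len(control$max_iterations)) {
    lda <- fit_gaussian_classifier(split$lda, "lda", control$priors)
    qda <- fit_gaussian_classifier(split$qda, "qda", control$priors)
    lam <- select_lambda(split, lda, qda, control$lambda_grid_step)
    post <- hybrid_posterior(gaussian_posterior(qda, luv),
                             gaussian_posterior(lda, luv), lam)
    class_lesion <- !is.na(post$p_lesion) & post$p_lesion > 0.5
    hc <- high_confidence_map(post, control$tau_conf)
    candidate <- lesion_candidate_region(class_lesion, lesion_seed, geometry,
                                         control$opening_mm)
    m_k <- sum(hc$lesion)
    trace[[k]] <- data.frame(
      k = k, lambda = lam, m = m_k,
      n_train_skin = nrow(split$lda$skin) + nrow(split$qda$skin),
      n_train_lesion = nrow(split$lda$lesion) + nrow(split$qda$lesion))
    fits <- list(lda = lda, qda = qda, lambda = lam)
    if (m_k == 0L) {
      flags <- c(flags, "no_high_confidence_lesion")
      warning("no high-confidence lesion pixels; stopping early",
              call. = FALSE)
      break
    }
    if (!is.na(m_prev) && check_convergence(m_prev, m_k, control$conv_tol)) {
      converged <- TRUE
      break
    }
    m_prev <- m_k
    if (k == control$max_iterations) break
    split <- refresh_training_set(
      split, which(hc$skin), which(hc$lesion & candidate), luv,
      rng_seed = control$rng_seed + k)
  }
  if (!converged && !("no_high_confidence_lesion" %in% flags))
    flags <- c(flags, "max_iterations_reached")

  # --- postprocessing ------------------------------------------------------
  raw_mask <- !is.na(post$p_lesion) & post$p_lesion > 0.5
  cleaned <- clean_and_connect(raw_mask, geometry, control$erode_mm,
                               control$dilate_mm, control$connect_bw_mm,
                               control$connect_threshold)
  scores <- score_regions(cleaned, geometry, control$sigma_score_mm)
  final <- finalize_lesion_mask(cleaned, scores)
  contour <- NULL
  if (attr(final, "found")) {
    contour <- extract_contour(final, geometry)
  } else {
    flags <- c(flags, "empty_lesion")
  }

  structure(list(
    mask = final, raw_mask = raw_mask, contour = contour,
    trace = do.call(rbind, trace), seeds = list(skin = skin3,
                                                skin_all = skin4,
                                                lesion = lesion_seed),
    classifiers = fits, posterior = post, luv = luv, geometry = geometry,
    control = control, converged = converged, iterations = length(trace),
    flags = flags
  ), class = "ics")
}

#' @export
print.ics <- function(x, ...) {
  cat("Iterative classification segmentation\n")
  cat(sprintf("  image: %d x %d px (%.3g px/mm)\n",
              x$geometry$image_shape[1], x$geometry$image_shape[2],
              x$geometry$px_per_mm))
  cat(sprintf("  %d iteration(s), %s; final lambda = %.2f\n", x$iterations,
              if (x$converged) "converged" else "not converged",
              x$classifiers$lambda))
  area_mm2 <- sum(x$mask) / x$geometry$px_per_mm^2
  cat(sprintf("  lesion: %s (%.1f mm^2, %d px)\n",
              if (attr(x$mask, "found")) "found" else "none",
              area_mm2, sum(x$mask)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ics <- function(object, ...) {
  out <- list(iterations = object$iterations, converged = object$converged,
              trace = object$trace, flags = object$flags,
              lesion_found = attr(object$mask, "found"),
              lesion_area_mm2 = sum(object$mask) / object$geometry$px_per_mm^2,
              seeds = seed_table(c(object$seeds$skin,
                                   list(object$seeds$lesion))))
  class(out) <- "summary.ics"
  out
}

#' @export
print.summary.ics <- function(x, ...) {
  cat(sprintf("ICS fit: %d iteration(s), %s; lesion %s (%.1f mm^2)\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              if (x$lesion_found) "found" else "none", x$lesion_area_mm2))
  cat("\nIteration trace (lambda = QDA weight, m = high-confidence lesion px):\n")
  print(x$trace, row.names = FALSE)
  cat("\nSeed regions:\n")
  print(x$seeds, row.names = FALSE)
  if (length(x$flags)) cat("\nflags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a segmentation fit
#'
#' Renders the L* channel with the seed boxes and the final lesion border
#' overlaid.
#'
#' @param x An `"ics"` fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ics <- function(x, ...) {
  L <- x$luv$L
  graphics::image(t(L)[, nrow(L):1], col = grDevices::gray.colors(128),
                  axes = FALSE, asp = 1, ...)
  nr <- nrow(L); nc <- ncol(L)
  to_xy <- function(row, col) list(x = (col - 1) / (nc - 1),
                                   y = 1 - (row - 1) / (nr - 1))
  draw_box <- function(s, border) {
    p1 <- to_xy(s$top, s$left); p2 <- to_xy(s$top + s$side, s$left + s$side)
    graphics::rect(p1$x, p2$y, p2$x, p1$y, border = border, lwd = 2)
  }
  for (s in x$seeds$skin) draw_box(s, "green3")
  draw_box(x$seeds$lesion, "blue")
  if (!is.null(x$contour)) {
    p <- to_xy(x$contour[, "row"], x$contour[, "col"])
    graphics::lines(p$x, p$y, col = "white", lwd = 2)
  }
  invisible(x)
}

#' Classify pixels with a fitted segmenter
#'
#' Applies the final iteration's hybrid classifier to a L*u*v* image
#' (by default the fitted one), returning the posterior map or hard labels.
#'
#' @param object An `"ics"` fit.
#' @param newdata Optional `"luv_image"`; default the fitted image.
#' @param type `"posterior"` for a `"posterior_map"`, `"class"` for a logical
#'   lesion matrix.
#' @param ... Unused.
#' @export
predict.ics <- function(object, newdata = NULL,
                        type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  luv <- if (is.null(newdata)) object$luv else newdata
  post <- hybrid_posterior(
    gaussian_posterior(object$classifiers$qda, luv),
    gaussian_posterior(object$classifiers$lda, luv),
    object$classifiers$lambda)
  if (type == "posterior") post
  else !is.na(post$p_lesion) & post$p_lesion > 0.5
}

#' Final classifier parameters of a fit
#'
#' Returns the final mixing weight and the class means of the two Gaussian
#' discriminants.
#'
#' @param object An `"ics"` fit.
#' @param ... Unused.
#' @export
coef.ics <- function(object, ...) {
  list(lambda = object$classifiers$lambda,
       lda_means = object$classifiers$lda$means,
       qda_means = object$classifiers$qda$means,
       lambda_trace = object$trace$lambda)
}
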