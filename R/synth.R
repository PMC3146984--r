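#' Specification of a synthetic dermoscopic frame
#'
#' Defines the study conditions a generated frame emulates: a circular imaged
#' field of ~17.4 mm diameter on a dark surround, lighter textured background
#' skin, a darker (optionally lighter) star-convex lesion at least partially
#' inside the central 5 mm disk, a target skin-lesion luminance contrast, and
#' optional dark hair-like strokes.
#'
#' @param image_side_px Side of the square frame in px; default 384
#'   (~22 px/mm), the working scale used throughout the package's examples and
#'   tests.
#' @param field_diameter_mm Physical field diameter; default 17.4.
#' @param skin_L_mean Mean background skin luminance L*; default 75 (light
#'   skin under dermoscope illumination).
#' @param skin_texture_sd Amplitude of the smooth low-frequency skin texture,
#'   in L* units; default 3 (visible illumination/texture drift).
#' @param noise_sd Per-pixel Gaussian noise, in L* units; default 2.5
#'   (granular skin texture at dermoscope magnification).
#' @param contrast_L Target absolute difference of median L* between lesion
#'   and skin; default 40 (a clearly pigmented lesion).
#' @param lesion_radius_mm Mean lesion radius; default 3.5 (7 mm mole).
#' @param lesion_center_offset_mm Offset of the lesion center from the field
#'   center; must keep the lesion at least partially inside the central 5 mm
#'   disk. Default 1.
#' @param border_irregularity Relative amplitude of the random harmonic border
#'   modulation (0 = circle); default 0.15.
#' @param border_fade_mm Width of the diffuse lesion border: the pigmentation
#'   ramps linearly from skin to full depth across this band, centered on the
#'   true boundary (so the 50% point is the ground truth). The default
#'   (`NULL`) couples border vagueness to contrast as observed clinically --
#'   faint lesions have ill-defined borders -- via
#'   `clamp(20 / contrast_L, 0.3, 2)` mm (0.5 mm at contrast 40).
#' @param lesion_brighter If `TRUE` the lesion is lighter than skin (the
#'   challenging inverse-contrast case); default `FALSE`.
#' @param n_hairs Number of dark curvilinear hair strokes; default 0.
#' @param rng_seed Integer seed making the frame fully reproducible.
#' @return An object of class `"synth_spec"` (a validated list).
#' @export
synth_spec <- function(image_side_px = 384L, field_diameter_mm = 17.4,
                       skin_L_mean = 75, skin_texture_sd = 3, noise_sd = 2.5,
                       contrast_L = 40, lesion_radius_mm = 3.5,
                       lesion_center_offset_mm = 1.0,
                       border_irregularity = 0.15, border_fade_mm = NULL,
                       lesion_brighter = FALSE,
                       n_hairs = 0L, rng_seed = 0L) {
  spec <- list(image_side_px = as.integer(image_side_px),
               field_diameter_mm = field_diameter_mm,
               skin_L_mean = skin_L_mean, skin_texture_sd = skin_texture_sd,
               noise_sd = noise_sd, contrast_L = contrast_L,
               lesion_radius_mm = lesion_radius_mm,
               lesion_center_offset_mm = lesion_center_offset_mm,
               border_irregularity = border_irregularity,
               border_fade_mm = if (is.null(border_fade_mm))
                 min(max(20 / max(contrast_L, 1e-9), 0.3), 2)
               else border_fade_mm,
               lesion_brighter = isTRUE(lesion_brighter),
               n_hairs = as.integer(n_hairs), rng_seed = as.integer(rng_seed))
  if (spec$contrast_L < 0) stop("'contrast_L' must be >= 0", call. = FALSE)
  if (spec$lesion_center_offset_mm - spec$lesion_radius_mm >= 5)
    stop("lesion would not intersect the central 5 mm disk", call. = FALSE)
  if (spec$lesion_center_offset_mm + spec$lesion_radius_mm >=
      field_diameter_mm / 2)
    stop("lesion extends beyond the imaged field", call. = FALSE)
  structure(spec, class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic frame spec: %d px / %.3g mm field, contrast %.3g L*, lesion r = %.3g mm%s, seed %d\n",
    x$image_side_px, x$field_diameter_mm, x$contrast_L, x$lesion_radius_mm,
    if (x$lesion_brighter) " (brighter than skin)" else "", x$rng_seed))
  invisible(x)
}

# Star-convex radius profile r(theta), mm: mean radius modulated by a random
# harmonic series (3-8 harmonics), clamped to keep the blob simply connected.
star_radius <- function(theta, radius_mm, irregularity) {
  nh <- sample(3:8, 1)
  amp <- rnorm(nh) / seq_len(nh)
  phi <- runif(nh, 0, 2 * pi)
  mod <- rowSums(vapply(seq_len(nh), function(h)
    amp[h] * cos(h * theta + phi[h]), numeric(length(theta))))
  if (max(abs(mod)) > 0) mod <- mod / max(abs(mod))
  radius_mm * pmin(pmax(1 + irregularity * mod, 0.3), 1.7)
}

draw_hairs <- function(L, geom, n_hairs, depth = 30) {
  nr <- nrow(L)
  for (h in seq_len(n_hairs)) {
    pos <- geom$center + runif(2, -0.5, 0.5) * geom$field_radius_px
    ang <- runif(1, 0, 2 * pi)
    curv <- rnorm(1, 0, 0.02)
    width <- sample(1:2, 1)
    for (step in seq_len(as.integer(3 * geom$field_radius_px))) {
      ang <- ang + curv + rnorm(1, 0, 0.01)
      pos <- pos + c(sin(ang), cos(ang))
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 1 || c < 1 || r > nr || c > ncol(L)) break
      rr <- r:min(r + width - 1L, nr); cc <- c:min(c + width - 1L, ncol(L))
      L[rr, cc] <- L[rr, cc] - depth
    }
  }
  L
}

#' Generate a synthetic dermoscopic frame with ground truth
#'
#' Renders an 8-bit RGB frame following the spec: dark surround, circular
#' field, textured skin, a star-convex lesion whose luminance is shifted to
#' hit the requested median L* contrast (measured on the generated image and
#' adjusted iteratively, so RGB quantization is accounted for), optional hair
#' strokes, and the pixel-accurate ground-truth lesion mask. Identical specs
#' produce byte-identical output.
#'
#' @param spec A `"synth_spec"`.
#' @return List with `image` (array `side x side x 3`, values 0-255), `mask`
#'   (logical ground truth), `geom` (the matching `"ics_geometry"`), and
#'   `spec`.
#' @export
synth_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$image_side_px
    geom <- build_geometry(spec$field_diameter_mm, n, c(n, n))
    fm <- field_mask(geom)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)

    # lesion geometry (mm frame centered on the field center)
    ang0 <- runif(1, 0, 2 * pi)
    lc <- geom$center + spec$lesion_center_offset_mm * geom$px_per_mm *
      c(sin(ang0), cos(ang0))
    theta_grid <- seq(0, 2 * pi, length.out = 721)[-721]
    rprof <- star_radius(theta_grid, spec$lesion_radius_mm,
                         spec$border_irregularity)
    dy <- rows - lc[1]; dx <- cols - lc[2]
    theta <- atan2(dy, dx) %% (2 * pi)
    ti <- pmin(floor(theta / (2 * pi) * 720) + 1, 720)
    signed_mm <- rprof[ti] - sqrt(dx^2 + dy^2) / geom$px_per_mm  # >0 inside
    # pigmentation depth: 0 outside, 1 inside, linear ramp across the fade
    # band centered on the true boundary (50% point = ground truth)
    fade <- pmin(pmax(0.5 + signed_mm / max(spec$border_fade_mm, 1e-6), 0), 1)
    mask <- signed_mm >= 0 & fm
    fade[!fm] <- 0

    # skin luminance: base + smooth low-frequency texture + noise
    tex <- matrix(0, n, n)
    for (w in 1:3) {
      fr <- runif(2, 0.5, 2.5) * 2 * pi / n
      ph <- runif(2, 0, 2 * pi)
      tex <- tex + cos(fr[1] * rows + ph[1]) * cos(fr[2] * cols + ph[2])
    }
    tex <- tex / 3 * spec$skin_texture_sd
    noise <- matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
    L_skin <- spec$skin_L_mean + tex + noise

    sgn <- if (spec$lesion_brighter) 1 else -1
    delta <- spec$contrast_L
    # Pigmentation drives luminance and chroma together: the lesion's chroma
    # offset from skin scales with the luminance contrast, so a zero-contrast
    # lesion is genuinely indistinguishable.
    uv_skin <- c(34, 32)
    uv_lesion <- uv_skin + c(-8, -10) * min(spec$contrast_L / 40, 1.25)
    in_band <- fade > 0
    lesion_noise <- matrix(0, n, n)
    lesion_noise[in_band] <- rnorm(sum(in_band), 0, spec$noise_sd * 0.5)
    # chroma varies independently of luminance (sensor noise, skin mottle)
    u_noise <- matrix(rnorm(n * n, 0, 1.2), n, n)
    v_noise <- matrix(rnorm(n * n, 0, 1.2), n, n)
    render <- function(delta) {
      L <- L_skin + fade * (sgn * delta) + fade * lesion_noise
      if (spec$n_hairs > 0) L <- draw_hairs(L, geom, spec$n_hairs)
      L <- pmin(pmax(L, 2), 98)
      u <- (uv_skin[1] + fade * (uv_lesion[1] - uv_skin[1])) *
        L / spec$skin_L_mean + u_noise
      v <- (uv_skin[2] + fade * (uv_lesion[2] - uv_skin[2])) *
        L / spec$skin_L_mean + v_noise
      rgb01 <- luv_to_rgb(as.numeric(L), as.numeric(u), as.numeric(v))
      img <- array(round(rgb01 * 255), c(n, n, 3))
      img[!fm] <- 8   # dark surround outside the field
      img
    }
    img <- render(delta)
    if (spec$contrast_L > 0) {
      for (adj in 1:4) {   # correct the realized median contrast
        luv <- rgb_to_luv(img, geom)
        got <- abs(median(luv$L[mask]) - median(luv$L[fm & !mask]))
        if (abs(got - spec$contrast_L) < 0.5 || got == 0) break
        delta <- delta * spec$contrast_L / got
        img <- render(delta)
      }
    }
    list(image = img, mask = mask, geom = geom, spec = spec)
  })
}

#' Generate a benchmark dataset of synthetic frames
#'
#' Writes `n` image/mask PNG pairs cycling through the requested contrast
#' levels, plus a CSV manifest describing each frame.
#'
#' @param base_spec A `"synth_spec"` supplying all parameters except contrast
#'   and seed.
#' @param n Number of frames.
#' @param contrast_levels Numeric vector of target contrasts to cycle through.
#' @param rng_seed Base seed; frame `i` uses `rng_seed + i`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest `data.frame` (also written to
#'   `manifest.csv` in `dir`).
#' @export
synth_dataset <- function(base_spec, n, contrast_levels = c(40, 20, 9),
                          rng_seed = 0L, dir = tempfile("synthset")) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lev <- contrast_levels[(i - 1L) %% length(contrast_levels) + 1L]
    sp <- base_spec
    sp$contrast_L <- lev
    sp$rng_seed <- as.integer(rng_seed + i)
    out <- synth_image(sp)
    ipath <- file.path(dir, sprintf("frame_%03d.png", i))
    mpath <- file.path(dir, sprintf("frame_%03d_mask.png", i))
    png::writePNG(out$image / 255, ipath)
    png::writePNG(out$mask * 1, mpath)
    rows[[i]] <- data.frame(
      image = ipath, mask = mpath, contrast_L = lev,
      rng_seed = sp$rng_seed, image_side_px = sp$image_side_px,
      field_diameter_mm = sp$field_diameter_mm,
      lesion_radius_mm = sp$lesion_radius_mm,
      lesion_brighter = sp$lesion_brighter, n_hairs = sp$n_hairs)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
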