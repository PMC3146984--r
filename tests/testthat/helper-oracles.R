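# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Reference colorimetry: scalar sRGB (0-255) -> CIE L*u*v* under D65.
oracle_rgb_to_luv <- function(rgb255) {
  inv <- function(c) {
    c <- c / 255
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  r <- inv(rgb255[1]); g <- inv(rgb255[2]); b <- inv(rgb255[3])
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  Xn <- 0.95047; Yn <- 1; Zn <- 1.08883
  yr <- Y / Yn
  L <- if (yr > (6 / 29)^3) 116 * yr^(1 / 3) - 16 else (29 / 3)^3 * yr
  den <- X + 15 * Y + 3 * Z
  dn <- Xn + 15 * Yn + 3 * Zn
  if (den == 0) return(c(L = L, u = 0, v = 0))
  u <- 13 * L * (4 * X / den - 4 * Xn / dn)
  v <- 13 * L * (9 * Y / den - 9 * Yn / dn)
  c(L = L, u = u, v = v)
}

# Windowed median with replicated borders, by explicit window sort.
oracle_median_filter <- function(m, w) {
  h <- w %/% 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- pmin(pmax((i - h):(i + h), 1), nrow(m))
    jj <- pmin(pmax((j - h):(j + h), 1), ncol(m))
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# Pixel-center-aligned bilinear resize by the direct interpolation formula.
oracle_bilinear <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    si <- min(max((i - 0.5) * nrow(m) / nr + 0.5, 1), nrow(m))
    sj <- min(max((j - 0.5) * ncol(m) / nc + 0.5, 1), ncol(m))
    i0 <- min(floor(si), nrow(m) - 1); j0 <- min(floor(sj), ncol(m) - 1)
    wi <- si - i0; wj <- sj - j0
    out[i, j] <- m[i0, j0] * (1 - wi) * (1 - wj) + m[i0 + 1, j0] * wi * (1 - wj) +
      m[i0, j0 + 1] * (1 - wi) * wj + m[i0 + 1, j0 + 1] * wi * wj
  }
  out
}

# Exhaustive box scan: best (top, left) of a side x side box fully inside
# `domain`, maximizing `objective` of the box mean of L; row-major ties.
oracle_box_best <- function(L, domain, side, objective = identity) {
  best <- -Inf; best_pos <- NULL
  for (i in seq_len(nrow(L) - side + 1)) for (j in seq_len(ncol(L) - side + 1)) {
    rows <- i:(i + side - 1); cols <- j:(j + side - 1)
    if (!all(domain[rows, cols])) next
    crit <- objective(mean(L[rows, cols]))
    if (crit > best) { best <- crit; best_pos <- c(top = i, left = j) }
  }
  best_pos
}

# Brute-force binary morphology: min/max over the in-image disk footprint.
oracle_morph <- function(m, radius, op) {
  foot <- which(outer(-radius:radius, -radius:radius,
                      function(a, b) a^2 + b^2 <= radius^2), arr.ind = TRUE)
  foot <- foot - radius - 1L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- i + foot[, 1]; jj <- j + foot[, 2]
    ok <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    vals <- m[cbind(ii[ok], jj[ok])]
    out[i, j] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

# All-pairs Hausdorff distance in px.
oracle_hausdorff_px <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# Exact 1-D k-clustering by enumeration of ordered partitions (small n only).
oracle_kmeans1d <- function(x, k) {
  xs <- sort(x); n <- length(xs)
  wcss <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_cuts <- NULL
  cuts <- utils::combn(n - 1, k - 1)
  for (c in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c], n)
    tot <- sum(vapply(seq_len(k), function(m) wcss(xs[(b[m] + 1):b[m + 1]]), 0))
    if (tot < best) { best <- tot; best_cuts <- b }
  }
  list(wcss = best,
       centers = vapply(seq_len(k), function(m)
         mean(xs[(best_cuts[m] + 1):best_cuts[m + 1]]), 0))
}

# Construct a bare L*u*v* container around given channel matrices.
make_luv <- function(L, u = NULL, v = NULL, mask = NULL) {
  if (is.null(u)) u <- matrix(0, nrow(L), ncol(L))
  if (is.null(v)) v <- matrix(0, nrow(L), ncol(L))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(L), ncol(L))
  structure(list(L = L, u = u, v = v, field_mask = mask), class = "luv_image")
}

# Construct a Gaussian classifier object directly from parameters.
make_gauss <- function(means, cov = diag(3), mode = "lda",
                       priors = c(skin = 0.5, lesion = 0.5)) {
  out <- list(mode = mode, means = means, priors = priors,
              n = c(100L, 100L), ridge = c(pooled = 0))
  if (mode == "lda") out$cov <- cov else out$covs <- cov
  structure(out, class = "ics_gauss")
}

make_posterior <- function(p_lesion, lambda = 0) {
  structure(list(p_skin = 1 - p_lesion, p_lesion = p_lesion,
                 lambda_used = lambda), class = "posterior_map")
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A small geometry whose full field spans the image.
test_geometry <- function(side, field_mm = 17.4, d1 = 5)
  build_geometry(field_mm, side, c(side, side), d1_radius_mm = d1)
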