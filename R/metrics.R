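#' Pixelwise confusion counts, sensitivity and specificity
#'
#' Compares a candidate lesion mask against a reference inside the circular
#' field: sensitivity is the fraction of reference lesion pixels recovered,
#' specificity the fraction of reference skin pixels kept. A rate whose
#' denominator is zero is reported as `NA`, not 0.
#'
#' @param candidate,reference Logical/0-1 matrices of the same shape.
#' @param field_mask Logical matrix restricting the evaluation; default all.
#' @return List with `counts` (`tp`, `fp`, `tn`, `fn`), `sensitivity`,
#'   `specificity`.
#' @export
confusion_and_rates <- function(candidate, reference, field_mask = NULL) {
  if (!identical(dim(candidate), dim(reference)))
    stop("mask shapes differ", call. = FALSE)
  if (is.null(field_mask)) field_mask <- matrix(TRUE, nrow(candidate), ncol(candidate))
  if (!identical(dim(candidate), dim(field_mask)))
    stop("field mask shape differs", call. = FALSE)
  cand <- candidate[field_mask] > 0
  ref  <- reference[field_mask] > 0
  tp <- sum(cand & ref);  fn <- sum(!cand & ref)
  fp <- sum(cand & !ref); tn <- sum(!cand & !ref)
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

contour_points <- function(x) {
  m <- if (inherits(x, "ics_contour")) unclass(x)[, c("row", "col")] else as.matrix(x)
  if (nrow(m) == 0) stop("empty contour", call. = FALSE)
  m
}

# Directed nearest-point distances (px) from each row of a to the set b,
# chunked to bound memory.
nearest_dists <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  for (start in seq(1L, nrow(a), by = chunk)) {
    i <- start:min(start + chunk - 1L, nrow(a))
    d2 <- outer(a[i, 1], b[, 1], `-`)^2 + outer(a[i, 2], b[, 2], `-`)^2
    out[i] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Hausdorff distance between two contours, in millimetres
#'
#' The symmetric Hausdorff distance over the two contour point sets: the
#' larger of the two directed maximum nearest-point distances, converted from
#' pixels to mm.
#'
#' @param A,B `"ics_contour"` objects or plain (row, col) point matrices.
#' @param geom An `"ics_geometry"`; defaults to the geometry attached to `A`.
#' @return Nonnegative scalar in mm.
#' @export
hausdorff_mm <- function(A, B, geom = attr(A, "geom")) {
  a <- contour_points(A); b <- contour_points(B)
  d <- max(max(nearest_dists(a, b)), max(nearest_dists(b, a)))
  d / geom$px_per_mm
}

#' Tolerance-ratio contour agreement e(tau)
#'
#' The fraction of contour points of both curves lying within `tau_mm` of the
#' other curve. Robust to isolated large disagreements, unlike the Hausdorff
#' distance; `e(tau) = 1` whenever `tau` is at least the Hausdorff distance.
#'
#' @inheritParams hausdorff_mm
#' @param tau_mm Tolerance in mm; default 0.5.
#' @return Scalar in `[0, 1]`.
#' @export
contour_agreement <- function(A, B, tau_mm = 0.5, geom = attr(A, "geom")) {
  a <- contour_points(A); b <- contour_points(B)
  da <- nearest_dists(a, b) / geom$px_per_mm
  db <- nearest_dists(b, a) / geom$px_per_mm
  (sum(da <= tau_mm) + sum(db <= tau_mm)) / (length(da) + length(db))
}

#' Pixelwise majority vote of reference masks
#'
#' Consensus reference built from an odd number (at least 3) of independent
#' manual segmentations: a pixel is lesion iff more than half the masks mark
#' it.
#'
#' @param masks List of aligned logical/0-1 matrices, odd count >= 3.
#' @return Logical matrix.
#' @export
majority_vote <- function(masks) {
  n <- length(masks)
  if (n < 3 || n %% 2 == 0)
    stop("an odd number (>= 3) of masks is required", call. = FALSE)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), TRUE)))
    stop("mask shapes differ", call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) (m > 0) * 1L))
  votes > n / 2
}

#' Seed placement accuracy against an agreement region
#'
#' Fraction of a seed box's pixels falling inside the region where at least
#' two of three manual references agree with the seed's class. The combined
#' skin + mole summary is the mean of the skin-seed and lesion-seed
#' accuracies.
#'
#' @param seed A `"seed_region"`.
#' @param agreement_mask Logical matrix of pixels labeled as the seed's class
#'   by the reference consensus.
#' @return Scalar in `[0, 1]`.
#' @export
seed_accuracy <- function(seed, agreement_mask) {
  if (length(seed$pixels) == 0) stop("empty seed region", call. = FALSE)
  mean(agreement_mask[seed$pixels] > 0)
}

#' Exact 1-D clustering of lesion contrasts
#'
#' Groups scalar skin-lesion contrast values (absolute difference of median
#' luminance) into `k` clusters by exactly minimizing the within-cluster sum
#' of squares with dynamic programming over the sorted values, avoiding the
#' local optima of iterative k-means. For `k = 3` the groups are labeled
#' `low`, `intermediate`, `high` in order of their centers.
#'
#' @param contrasts Numeric vector, length >= `k`.
#' @param k Number of groups; default 3.
#' @return List with `labels` (factor, in input order) and `centers` (sorted
#'   increasing). Duplicate degenerate centers are merged, so fewer than `k`
#'   groups may be returned for ties.
#' @export
contrast_groups <- function(contrasts, k = 3L) {
  x <- as.numeric(contrasts)
  n <- length(x)
  k <- as.integer(k)
  if (n < k) stop("need at least k values", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  s1 <- cumsum(xs); s2 <- cumsum(xs^2)
  cost <- function(a, b) {   # WCSS of xs[a..b]
    s  <- s1[b] - if (a > 1) s1[a - 1] else 0
    ss <- s2[b] - if (a > 1) s2[a - 1] else 0
    max(ss - s^2 / (b - a + 1), 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (i in 1:n) D[1, i] <- cost(1, i)
  if (k > 1) for (m in 2:k) for (i in m:n) {
    for (j in m:i) {
      v <- D[m - 1, j - 1] + cost(j, i)
      if (v < D[m, i]) { D[m, i] <- v; B[m, i] <- j }
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  i <- n
  for (m in k:1) { bounds[m] <- B[m, i]; i <- B[m, i] - 1L }
  grp_sorted <- rep(seq_len(k), times = diff(c(bounds[1:k] - 1L, n)))
  centers <- vapply(seq_len(k), function(m) mean(xs[grp_sorted == m]), 0)
  # merge degenerate groups with identical centers
  keep <- !duplicated(centers)
  remap <- cumsum(keep)[match(centers, centers)]
  centers <- unique(centers)
  grp_sorted <- remap[grp_sorted]
  labels <- integer(n)
  labels[ord] <- grp_sorted
  lev <- if (length(centers) == 3) c("low", "intermediate", "high")
         else paste0("group", seq_along(centers))
  list(labels = factor(lev[labels], levels = lev), centers = centers)
}

#' Evaluate a candidate segmentation against a reference mask
#'
#' Convenience wrapper computing the four border-evaluation scores between a
#' candidate and a reference lesion mask: sensitivity, specificity, Hausdorff
#' distance (mm) and the tolerance-ratio contour agreement `e(tau)`. Contours
#' are traced from the largest component of each mask.
#'
#' @param candidate,reference Logical/0-1 lesion masks of the same shape.
#' @param geom An `"ics_geometry"`.
#' @param tau_mm Contour tolerance in mm; default 0.5.
#' @return List with `sensitivity`, `specificity`, `hausdorff_mm`, `e_tau`,
#'   `tau_mm` and `counts`.
#' @export
evaluate_masks <- function(candidate, reference, geom, tau_mm = 0.5) {
  cr <- confusion_and_rates(candidate, reference, field_mask(geom))
  single <- function(m) {
    sc <- score_regions(m, geom)
    finalize_lesion_mask(m, sc)
  }
  h <- e <- NA_real_
  if (any(candidate > 0) && any(reference > 0)) {
    ca <- extract_contour(single(candidate), geom)
    cb <- extract_contour(single(reference), geom)
    h <- hausdorff_mm(ca, cb, geom)
    e <- contour_agreement(ca, cb, tau_mm, geom)
  }
  list(sensitivity = cr$sensitivity, specificity = cr$specificity,
       hausdorff_mm = h, e_tau = e, tau_mm = tau_mm, counts = cr$counts)
}
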