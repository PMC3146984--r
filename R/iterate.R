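# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' High-confidence pixel masks
#'
#' Pixels whose class posterior strictly exceeds the confidence threshold are
#' eligible as new training samples. The two masks are disjoint for any
#' threshold above 0.5.
#'
#' @param post A `"posterior_map"`.
#' @param tau_conf Confidence threshold in (0, 1); default 0.98.
#' @return List of logical matrices `skin` and `lesion`.
#' @export
high_confidence_map <- function(post, tau_conf = 0.98) {
  if (!is.numeric(tau_conf) || tau_conf <= 0 || tau_conf >= 1)
    stop("'tau_conf' must lie in (0, 1)", call. = FALSE)
  list(skin   = !is.na(post$p_skin)   & post$p_skin   > tau_conf,
       lesion = !is.na(post$p_lesion) & post$p_lesion > tau_conf)
}

#' Safeguarded lesion candidate region
#'
#' Before lesion pixels may enter the training set, the binary lesion
#' classification is opened with a 1 mm disk (removing hairs and isolated
#' specks) and, of the resulting 8-connected components, the one best
#' enclosing the initial lesion seed box is kept: largest pixel overlap with
#' the box, falling back to the component whose centroid is nearest the box
#' center when none overlaps. Only high-confidence lesion pixels inside this
#' region are harvested; the segmentation itself is not restricted.
#'
#' @param lesion_class_mask Logical/0-1 matrix of pixels classified as lesion.
#' @param seed_box The initial lesion `"seed_region"`.
#' @param geom An `"ics_geometry"`.
#' @param opening_diameter_mm Structuring-element diameter in mm; default 1.
#' @return Logical matrix of the selected candidate region (empty if the
#'   opened mask is empty).
#' @export
lesion_candidate_region <- function(lesion_class_mask, seed_box, geom,
                                    opening_diameter_mm = 1.0) {
  opened <- morph_disk(lesion_class_mask, opening_diameter_mm, geom, "open")
  if (!any(opened)) return(matrix(FALSE, nrow(opened), ncol(opened)))
  lab <- label_components(opened)
  nlab <- max(lab)
  if (nlab == 1L) return(lab == 1L)
  overlap <- tabulate(lab[seed_box$pixels], nbins = nlab)
  if (any(overlap > 0)) return(lab == which.max(overlap))
  ctr <- c(seed_box$top + (seed_box$side - 1) / 2,
           seed_box$left + (seed_box$side - 1) / 2)
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
  cen <- vapply(seq_len(nlab), function(l) {
    sel <- lab[idx] == l
    (mean(rows[sel]) - ctr[1])^2 + (mean(cols[sel]) - ctr[2])^2
  }, 0)
  lab == which.min(cen)
}

#' Refresh the training split with high-confidence samples
#'
#' Per class, up to `origin_counts` pixels are drawn uniformly without
#' replacement from the eligible high-confidence pixels, so at most half of
#' each class's training set is refreshed while the original seed samples are
#' always retained. Draws alternate between the LDA and QDA halves to keep
#' them balanced; the draw is reproducible from `rng_seed`.
#'
#' @param split An `"ics_training"` split (its `$origin` is reused verbatim).
#' @param eligible_skin,eligible_lesion Integer vectors of linear pixel
#'   indices eligible per class.
#' @param luv The `"luv_image"` to read features from.
#' @param rng_seed Integer seed for the draw.
#' @return A new `"ics_training"` split.
#' @export
refresh_training_set <- function(split, eligible_skin, eligible_lesion, luv,
                                 rng_seed = 0L) {
  draw <- with_seed(rng_seed, list(
    skin   = sample_capped(eligible_skin,   split$origin_counts["skin"]),
    lesion = sample_capped(eligible_lesion, split$origin_counts["lesion"])))
  out <- split
  for (cls in c("skin", "lesion")) {
    idx <- draw[[cls]]
    odd <- seq_along(idx) %% 2L == 1L
    out$lda[[cls]] <- rbind(split$origin$lda[[cls]], seed_samples(luv, idx[odd]))
    out$qda[[cls]] <- rbind(split$origin$qda[[cls]], seed_samples(luv, idx[!odd]))
  }
  out
}

# Uniform draw of min(length(x), cap) elements without replacement.
sample_capped <- function(x, cap) {
  if (length(x) <= cap) return(x)
  x[sample.int(length(x), cap)]
}

#' Convergence test for the iterative update
#'
#' The loop stops when the count of high-confidence lesion pixels has
#' stabilized: `|1 - m_next / m_prev| < tol`. A zero previous count never
#' counts as convergence (the loop's zero-harvest fallback handles it).
#'
#' @param m_prev,m_next High-confidence lesion pixel counts of consecutive
#'   iterations.
#' @param tol Relative tolerance; default 0.01.
#' @return Logical.
#' @export
check_convergence <- function(m_prev, m_next, tol = 0.01) {
  m_prev > 0 && abs(1 - m_next / m_prev) < tol
}
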