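# Integral image with a zero first row/col; box sums in O(1).
integral_image <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- matrix(apply(x, 2, cumsum), nr, nc)
  rcs <- apply(cs, 1, cumsum)
  cs <- if (is.matrix(rcs)) t(rcs) else matrix(rcs, nr, nc)
  out <- matrix(0, nr + 1, nc + 1)
  out[-1, -1] <- cs
  out
}

# Sum of x over the side x side box at every placement (top, left); returns a
# (nr-side+1) x (nc-side+1) matrix.
box_sums <- function(ii, side) {
  nr <- nrow(ii) - 1; nc <- ncol(ii) - 1
  rt <- seq_len(nr - side + 1); ct <- seq_len(nc - side + 1)
  ii[rt + side, ct + side, drop = FALSE] - ii[rt, ct + side, drop = FALSE] -
    ii[rt + side, ct, drop = FALSE] + ii[rt, ct, drop = FALSE]
}

# First row-major (smallest row, then col) position of the matrix maximum.
# Values within a relative 1e-9 of the maximum count as tied, so exact ties
# survive the rounding noise of integral-image differencing.
argmax_row_major <- function(m, tol = 1e-9) {
  best <- max(m, na.rm = TRUE)
  thr <- best - tol * max(1, abs(best))
  hits <- which(!is.na(m) & m >= thr, arr.ind = TRUE)
  hits[order(hits[, 1], hits[, 2])[1], ]
}

new_seed_region <- function(label, top, left, side, luv) {
  nr <- nrow(luv$L)
  rows <- top + seq_len(side) - 1L
  cols <- left + seq_len(side) - 1L
  idx <- as.integer(outer(rows, (cols - 1L) * nr, `+`))
  structure(list(label = label, top = as.integer(top), left = as.integer(left),
                 side = as.integer(side), pixels = idx,
                 mean_L = mean(luv$L[idx])),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("%s seed: %dpx box at (%d, %d), mean L* = %.2f\n",
              x$label, x$side, x$top, x$left, x$mean_L))
  invisible(x)
}

seed_samples <- function(luv, idx) {
  cbind(L = luv$L[idx], u = luv$u[idx], v = luv$v[idx])
}

# Exhaustive scan for the box maximizing `objective(mean L)` over placements
# fully contained in `domain`. Stride > 1 coarsens the scan for speed.
scan_box <- function(luv, domain, side, objective = identity, stride = 1L) {
  nr <- nrow(domain); nc <- ncol(domain)
  if (side > nr || side > nc) return(NULL)
  n_in <- box_sums(integral_image(domain * 1), side)
  valid <- n_in == side * side
  if (stride > 1L) {
    keep_r <- seq(1L, nrow(valid), by = stride)
    keep_c <- seq(1L, ncol(valid), by = stride)
    sub <- matrix(FALSE, nrow(valid), ncol(valid))
    sub[keep_r, keep_c] <- TRUE
    valid <- valid & sub
  }
  if (!any(valid)) return(NULL)
  means <- box_sums(integral_image(luv$L), side) / (side * side)
  crit <- objective(means)
  crit[!valid] <- NA
  pos <- argmax_row_major(crit)
  list(top = pos[1], left = pos[2])
}

#' Automatic skin seed selection
#'
#' Splits the peripheral annulus `d2` into four axis-aligned quadrants about
#' the field center and, in each, exhaustively scans for the square box of
#' side `w_skin_mm` (fully contained in that quadrant's part of the annulus)
#' with maximal mean luminance L*. Under the acquisition assumptions the
#' lightest peripheral patches are background skin. Ties are broken by the
#' first position in row-major order.
#'
#' @param luv A `"luv_image"`.
#' @param geom An `"ics_geometry"`.
#' @param w_skin_mm Seed box side in mm; default 1.
#' @param stride Scan stride in px (1 = exhaustive).
#' @return List of four `"seed_region"` objects, one per quadrant
#'   (top-left, top-right, bottom-left, bottom-right).
#' @export
select_skin_seeds <- function(luv, geom, w_skin_mm = 1.0, stride = 1L) {
  side <- max(1L, as.integer(round(mm_to_px(geom, w_skin_mm))))
  d2 <- d2_mask(geom)
  lapply(1:4, function(q) {
    dom <- d2 & quadrant_mask(geom, q)
    hit <- scan_box(luv, dom, side, stride = stride)
    if (is.null(hit))
      stop(sprintf("no valid %dpx skin seed placement in quadrant %d", side, q),
           call. = FALSE)
    new_seed_region("skin", hit$top, hit$left, side, luv)
  })
}

#' Prune the four skin seeds to the three most consistent
#'
#' For each leave-one-out split of the four quadrant seeds, the absolute
#' difference between the held-out seed's mean L* and the mean L* of the
#' merged other three is computed; the seed with the largest difference is
#' dropped (ties drop the highest quadrant index). Excluding the most deviant
#' seed guards against boxes contaminated by artifacts.
#'
#' @param seeds List of exactly four `"seed_region"` objects in quadrant order.
#' @return List of the three retained `"seed_region"` objects, quadrant order
#'   preserved.
#' @export
prune_to_three <- function(seeds) {
  if (length(seeds) != 4)
    stop("exactly four skin seeds are required", call. = FALSE)
  sums <- vapply(seeds, function(s) s$mean_L * length(s$pixels), 0)
  ns   <- vapply(seeds, function(s) length(s$pixels), 0)
  dev <- vapply(1:4, function(q) {
    abs(seeds[[q]]$mean_L - sum(sums[-q]) / sum(ns[-q]))
  }, 0)
  drop <- max(which(dev == max(dev)))   # ties: highest quadrant index
  seeds[-drop]
}

#' Automatic lesion seed selection
#'
#' Exhaustively scans the central disk `d1` for the square box of side
#' `w_mole_mm` whose mean luminance is farthest (in absolute value) from the
#' skin seeds' mean luminance. The absolute distance makes the rule work for
#' the occasional lesion lighter than the surrounding skin.
#'
#' @param luv A `"luv_image"`.
#' @param skin_mean_L Mean L* of the merged skin seed pixels.
#' @param geom An `"ics_geometry"`.
#' @param w_mole_mm Box side in mm; default 1.5.
#' @param stride Scan stride in px.
#' @return A `"seed_region"` labeled `"lesion"`.
#' @export
select_lesion_seed <- function(luv, skin_mean_L, geom, w_mole_mm = 1.5,
                               stride = 1L) {
  side <- max(1L, as.integer(round(mm_to_px(geom, w_mole_mm))))
  hit <- scan_box(luv, d1_mask(geom), side,
                  objective = function(m) abs(m - skin_mean_L),
                  stride = stride)
  if (is.null(hit))
    stop(sprintf("no valid %dpx lesion seed placement inside d1", side),
         call. = FALSE)
  new_seed_region("lesion", hit$top, hit$left, side, luv)
}

# Linear indices of the left (first floor(side/2) columns) and right halves of
# a seed box.
split_box_halves <- function(seed, nr) {
  rows <- seed$top + seq_len(seed$side) - 1L
  cols <- seed$left + seq_len(seed$side) - 1L
  half <- seed$side %/% 2L
  left  <- cols[seq_len(half)]
  right <- cols[setdiff(seq_along(cols), seq_len(half))]
  list(left  = as.integer(outer(rows, (left - 1L) * nr, `+`)),
       right = as.integer(outer(rows, (right - 1L) * nr, `+`)))
}

#' Split seed pixels into disjoint LDA and QDA training halves
#'
#' The linear and quadratic classifiers are trained on spatially disjoint
#' subsets of the seed pixels so that each classifier can be scored on samples
#' it has not seen. Of the three skin seeds (quadrant order A, B, C): A plus
#' the left half of B trains LDA; C plus the right half of B trains QDA. The
#' lesion box is split into left (LDA) and right (QDA) halves.
#'
#' @param skin_seeds List of three `"seed_region"` objects.
#' @param lesion_seed The lesion `"seed_region"`.
#' @param luv The `"luv_image"` the seeds index into.
#' @return An object of class `"ics_training"`: per-classifier per-class
#'   sample matrices (`lda$skin`, `lda$lesion`, `qda$skin`, `qda$lesion`),
#'   the immutable original halves in `$origin`, and `$origin_counts`.
#' @export
split_seed_samples <- function(skin_seeds, lesion_seed, luv) {
  if (length(skin_seeds) != 3)
    stop("exactly three skin seeds are required", call. = FALSE)
  if (any(vapply(skin_seeds, function(s) length(s$pixels), 0) == 0) ||
      length(lesion_seed$pixels) == 0)
    stop("empty seed region", call. = FALSE)
  nr <- nrow(luv$L)
  bh <- split_box_halves(skin_seeds[[2]], nr)
  mh <- split_box_halves(lesion_seed, nr)
  lda_skin_idx <- c(skin_seeds[[1]]$pixels, bh$left)
  qda_skin_idx <- c(skin_seeds[[3]]$pixels, bh$right)
  origin <- list(
    lda = list(skin = seed_samples(luv, lda_skin_idx),
               lesion = seed_samples(luv, mh$left)),
    qda = list(skin = seed_samples(luv, qda_skin_idx),
               lesion = seed_samples(luv, mh$right)))
  structure(list(
    lda = origin$lda, qda = origin$qda, origin = origin,
    origin_counts = c(
      skin   = length(lda_skin_idx) + length(qda_skin_idx),
      lesion = length(mh$left) + length(mh$right))
  ), class = "ics_training")
}

#' @export
print.ics_training <- function(x, ...) {
  n <- function(s) sprintf("%d skin / %d lesion", nrow(s$skin), nrow(s$lesion))
  cat("ICS training split: LDA", n(x$lda), "| QDA", n(x$qda),
      "| original", x$origin_counts["skin"], "skin /",
      x$origin_counts["lesion"], "lesion\n")
  invisible(x)
}

# Seed boxes as a plain table for CSV export / overlays.
seed_table <- function(seeds) {
  do.call(rbind, lapply(seeds, function(s)
    data.frame(label = s$label, top = s$top, left = s$left, side_px = s$side,
               mean_L = s$mean_L)))
}
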