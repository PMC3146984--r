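# Stage 1: automatic seed placement and the training split.

test_that("skin seed boxes land on the brightest patch of each quadrant", {
  g <- test_geometry(128)
  set.seed(3)
  L <- matrix(50 + rnorm(128 * 128, 0, 0.5), 128, 128)
  side <- round(g$px_per_mm)           # 1 mm box
  # plant one uniquely bright patch per quadrant, fully inside d2
  spots <- list(c(30, 30), c(25, 95), c(100, 22), c(98, 98))
  for (s in spots) {
    rows <- s[1]:(s[1] + side - 1); cols <- s[2]:(s[2] + side - 1)
    L[rows, cols] <- L[rows, cols] + 30
  }
  luv <- make_luv(L)
  seeds <- select_skin_seeds(luv, g)
  d2 <- d2_mask(g)
  for (q in 1:4) {
    s <- seeds[[q]]
    ora <- oracle_box_best(L, d2 & icseg:::quadrant_mask(g, q), side)
    expect_equal(c(s$top, s$left), unname(ora))
    expect_equal(c(s$top, s$left), spots[[q]])
    # full containment in the annulus
    expect_true(all(d2[s$top:(s$top + side - 1), s$left:(s$left + side - 1)]))
  }
})

test_that("uniform luminance breaks ties at the first row-major position", {
  g <- test_geometry(96)
  luv <- make_luv(matrix(60, 96, 96))
  seeds <- select_skin_seeds(luv, g)
  side <- seeds[[1]]$side
  for (q in 1:4) {
    ora <- oracle_box_best(luv$L, d2_mask(g) & icseg:::quadrant_mask(g, q), side)
    expect_equal(c(seeds[[q]]$top, seeds[[q]]$left), unname(ora))
  }
})

test_that("a bright patch straddling the domain boundary is not selected", {
  g <- test_geometry(128)
  L <- matrix(50, 128, 128)
  # bright band exactly on the d1 boundary in quadrant 1 (partially inside d1)
  d1 <- d1_mask(g)
  edge <- which(d1 & !d1_mask(build_geometry(17.4, 128, c(128, 128),
                                             d1_radius_mm = 4.5)))
  L[edge] <- 95
  seeds <- select_skin_seeds(make_luv(L), g)
  d2 <- d2_mask(g)
  for (s in seeds) {
    box <- d2[s$top:(s$top + s$side - 1), s$left:(s$left + s$side - 1)]
    expect_true(all(box))
  }
})

test_that("pruning drops the statistically most deviant seed", {
  fake <- function(mean_L, q)
    structure(list(label = "skin", top = 1L + q, left = 1L, side = 7L,
                   pixels = seq_len(49), mean_L = mean_L),
              class = "seed_region")
  mk <- function(means) lapply(1:4, function(q) fake(means[q], q))
  # enumeration oracle over the four leave-one-out splits
  oracle_drop <- function(means) {
    dev <- vapply(1:4, function(q) abs(means[q] - mean(means[-q])), 0)
    max(which(dev == max(dev)))
  }
  for (means in list(c(80, 81, 79, 50), c(80, 80.001, 80, 80),
                     c(10, 40, 41, 42))) {
    kept <- prune_to_three(mk(means))
    expect_equal(vapply(kept, `[[`, 0, "mean_L"), means[-oracle_drop(means)])
  }
  # all equal: quadrant 4 dropped by the tie rule
  kept <- prune_to_three(mk(c(70, 70, 70, 70)))
  expect_equal(vapply(kept, `[[`, 0L, "top"), c(2L, 3L, 4L))
  expect_error(prune_to_three(mk(c(1, 2, 3, 4))[1:3]), "four")
})

test_that("lesion seed maximizes absolute luminance distance from skin", {
  g <- test_geometry(128)
  set.seed(5)
  L <- matrix(70 + rnorm(128 * 128, 0, 0.3), 128, 128)
  ctr <- g$center
  dark <- outer(seq_len(128), seq_len(128),
                function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2 <= 12^2)
  L[dark] <- 30
  luv <- make_luv(L)
  side <- round(1.5 * g$px_per_mm)
  seed <- select_lesion_seed(luv, 70, g)
  ora <- oracle_box_best(L, d1_mask(g), side, function(m) abs(m - 70))
  expect_equal(c(seed$top, seed$left), unname(ora))
  # box pixels inside the dark disk
  expect_gt(mean(dark[seed$pixels]), 0.95)

  # a lesion brighter than skin is still found (absolute distance)
  L2 <- matrix(70 + rnorm(128 * 128, 0, 0.3), 128, 128)
  L2[dark] <- 95
  seed2 <- select_lesion_seed(make_luv(L2), 70, g)
  expect_gt(mean(dark[seed2$pixels]), 0.95)

  # luminance identically at the skin mean: first row-major placement
  L3 <- matrix(70, 128, 128)
  seed3 <- select_lesion_seed(make_luv(L3), 70, g)
  ora3 <- oracle_box_best(L3, d1_mask(g), side, function(m) abs(m - 70))
  expect_equal(c(seed3$top, seed3$left), unname(ora3))
})

test_that("seed samples split into disjoint LDA/QDA halves covering all pixels", {
  g <- test_geometry(128)
  set.seed(11)
  L <- matrix(runif(128 * 128, 40, 90), 128, 128)
  luv <- make_luv(L, matrix(rnorm(128^2), 128), matrix(rnorm(128^2), 128))
  mk <- function(top, left, side, label)
    icseg:::new_seed_region(label, top, left, side, luv)
  skin <- list(mk(10, 10, 6, "skin"), mk(10, 100, 6, "skin"),
               mk(100, 10, 6, "skin"))
  lesion <- mk(60, 60, 10, "lesion")
  split <- split_seed_samples(skin, lesion, luv)
  # whole seed A + half of B on one side, C + other half on the other
  expect_equal(nrow(split$lda$skin), 36 + 18)
  expect_equal(nrow(split$qda$skin), 36 + 18)
  expect_equal(nrow(split$lda$lesion), 50)
  expect_equal(nrow(split$qda$lesion), 50)
  expect_equal(unname(split$origin_counts), c(108L, 100L))
  # partition: union of halves equals all seed pixels, no overlap
  all_skin <- sort(luv$L[c(skin[[1]]$pixels, skin[[2]]$pixels, skin[[3]]$pixels)])
  expect_equal(sort(c(split$lda$skin[, "L"], split$qda$skin[, "L"])), all_skin)
  all_lesion <- sort(luv$L[lesion$pixels])
  expect_equal(sort(c(split$lda$lesion[, "L"], split$qda$lesion[, "L"])),
               all_lesion)

  # odd-width box: halves differ by one column of pixels
  lesion_odd <- mk(60, 60, 7, "lesion")
  sp2 <- split_seed_samples(skin, lesion_odd, luv)
  expect_equal(abs(nrow(sp2$lda$lesion) - nrow(sp2$qda$lesion)), 7)
})

test_that("stage 1 places the lesion seed inside the true lesion on generated frames", {
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    fr <- synth_image(synth_spec(image_side_px = 192, contrast_L = 35,
                                 rng_seed = 100 + s))
    luv <- rgb_to_luv(fr$image, fr$geom)
    skin <- prune_to_three(select_skin_seeds(luv, fr$geom))
    skin_mean <- mean(luv$L[unlist(lapply(skin, `[[`, "pixels"))])
    seed <- select_lesion_seed(luv, skin_mean, fr$geom)
    if (mean(fr$mask[seed$pixels]) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
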