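# Postprocessing: morphology, region scoring, final mask, contour tracing.

test_that("disk morphology matches the brute-force min/max oracle", {
  g <- test_geometry(32, field_mm = 32)   # 1 px per mm
  set.seed(13)
  m <- matrix(rbinom(32 * 32, 1, 0.4), 32, 32)
  for (d in c(3, 5)) {                    # diameters in mm = px
    r <- round(d / 2)
    expect_equal(morph_disk(m, d, g, "erode") * 1, oracle_morph(m, r, "erode"))
    expect_equal(morph_disk(m, d, g, "dilate") * 1, oracle_morph(m, r, "dilate"))
  }
  # containment and annihilation
  blob <- matrix(0, 32, 32); blob[15:17, 15:17] <- 1
  expect_false(any(morph_disk(blob, 9, g, "erode")))   # element bigger than blob
  expect_true(all(morph_disk(m, 3, g, "dilate") >= (m > 0)))
  expect_true(all((m > 0) >= morph_disk(m, 3, g, "erode")))
  # opening is idempotent
  op1 <- morph_disk(m, 3, g, "open")
  expect_equal(morph_disk(op1, 3, g, "open"), op1)
})

test_that("clean-and-connect removes specks, bridges gaps, stays near the input", {
  g <- test_geometry(192)
  m <- matrix(FALSE, 192, 192)
  disk <- outer(1:192, 1:192,
                function(i, j) (i - 96)^2 + (j - 96)^2 <= (2 * g$px_per_mm)^2)
  m[disk] <- TRUE
  m[20, 20] <- TRUE                                   # isolated 1-px speck
  out <- clean_and_connect(m, g)
  expect_false(out[20, 20])
  # changes confined to a band around the disk boundary
  inner <- outer(1:192, 1:192,
                 function(i, j) (i - 96)^2 + (j - 96)^2 <= (1.6 * g$px_per_mm)^2)
  expect_true(all(out[inner]))
  expect_false(any(out & !morph_disk(m, 1.2, g, "dilate")))

  # two blobs separated by a small gap become one component
  m2 <- matrix(FALSE, 192, 192)
  m2[90:102, 60:90] <- TRUE
  m2[90:102, 93:123] <- TRUE                          # 2-px gap
  out2 <- clean_and_connect(m2, g)
  expect_equal(max(icseg:::label_components(out2)), 1L)
})

test_that("region scores follow the central Gaussian weight", {
  g <- build_geometry(17.4, 129, c(129, 129))         # integer center (65, 65)
  s2px <- mm_to_px(g, 2.5)
  m <- matrix(FALSE, 129, 129)
  m[65, 65] <- TRUE
  sc <- score_regions(m, g)
  expect_equal(sc$score, 1)                            # exp(0) at the center
  m2 <- matrix(FALSE, 129, 129)
  off <- round(s2px)
  m2[65, 65 + off] <- TRUE                             # one sigma off-axis
  expect_equal(score_regions(m2, g)$score, exp(-off^2 / (2 * s2px^2)))
  expect_equal(score_regions(m2, g)$score, exp(-0.5), tolerance = 0.06)

  # identical shapes: the centered copy outscores the peripheral one, and
  # total score equals the brute-force sum of the Gaussian over all pixels
  m3 <- matrix(FALSE, 129, 129)
  m3[61:69, 61:69] <- TRUE
  m3[10:18, 61:69] <- TRUE
  sc3 <- score_regions(m3, g)
  expect_equal(nrow(sc3), 2)
  expect_gt(max(sc3$score), 10 * min(sc3$score))
  idx <- which(m3)
  rows <- (idx - 1) %% 129 + 1; cols <- (idx - 1) %/% 129 + 1
  brute <- sum(exp(-((rows - 65)^2 + (cols - 65)^2) / (2 * s2px^2)))
  expect_equal(sum(sc3$score), brute, tolerance = 1e-12)
  expect_equal(sum(sc3$pixel_count), length(idx))
  # empty mask: empty table
  expect_equal(nrow(score_regions(matrix(FALSE, 129, 129), g)), 0)
})

test_that("final mask keeps the best region and fills holes", {
  g <- build_geometry(17.4, 129, c(129, 129))
  m <- matrix(FALSE, 129, 129)
  m[60:70, 60:70] <- TRUE                              # central winner
  m[5:7, 5:7] <- TRUE                                  # peripheral loser
  sc <- score_regions(m, g)
  out <- finalize_lesion_mask(m, sc)
  expect_true(attr(out, "found"))
  expect_false(any(out[1:20, 1:20]))
  expect_true(all(out[60:70, 60:70]))

  ring <- matrix(FALSE, 129, 129)
  for (i in 1:129) for (j in 1:129) {
    d <- sqrt((i - 65)^2 + (j - 65)^2)
    if (d >= 8 && d <= 14) ring[i, j] <- TRUE
  }
  filled <- finalize_lesion_mask(ring, score_regions(ring, g))
  expect_true(filled[65, 65])
  # simply connected: one component, refilling changes nothing
  lab <- icseg:::label_components(filled)
  expect_equal(max(lab), 1L)
  expect_equal(finalize_lesion_mask(filled, score_regions(filled, g)) * 1,
               filled * 1, ignore_attr = TRUE)

  empty <- finalize_lesion_mask(matrix(FALSE, 129, 129),
                                score_regions(matrix(FALSE, 129, 129), g))
  expect_false(attr(empty, "found"))
  expect_false(any(empty))
})

test_that("contours are closed, boundary-accurate and length-faithful", {
  g <- test_geometry(200)
  m <- outer(1:200, 1:200, function(i, j) (i - 100)^2 + (j - 100)^2 <= 50^2)
  ct <- extract_contour(m, g)
  expect_equal(ct[1, ], ct[nrow(ct), ])
  len <- sum(sqrt(diff(ct[, "row"])^2 + diff(ct[, "col"])^2))
  expect_lt(abs(len - 2 * pi * 50) / (2 * pi * 50), 0.05)
  # every contour point sits within one pixel of both phases
  for (i in seq(1, nrow(ct) - 1, by = 7)) {
    r <- ct[i, "row"]; c <- ct[i, "col"]
    rr <- pmin(pmax(c(floor(r), ceiling(r)), 1), 200)
    cc <- pmin(pmax(c(floor(c), ceiling(c)), 1), 200)
    vals <- m[as.matrix(expand.grid(rr, cc))]
    expect_true(any(vals) && any(!vals))
  }
  # unit-square boundary of a single pixel
  m1 <- matrix(FALSE, 9, 9); m1[5, 5] <- TRUE
  c1 <- extract_contour(m1, g)
  expect_equal(nrow(c1), 5)                          # 4 points + closure
  expect_true(all(abs(c1[, "row"] - 5) <= 0.5 & abs(c1[, "col"] - 5) <= 0.5))
  # mm conversion scales with the pixel pitch
  mm <- contour_to_mm(ct)
  expect_equal(max(mm[, "x"]), 50 / g$px_per_mm, tolerance = 0.05)

  expect_error(extract_contour(matrix(FALSE, 9, 9), g), "empty")
  m2 <- matrix(FALSE, 20, 20); m2[2, 2] <- TRUE; m2[18, 18] <- TRUE
  expect_error(extract_contour(m2, g), "more than one")
})

test_that("repeated postprocessing drifts by at most a thin boundary band", {
  # the Gaussian connect step thresholded at 0.1 expands smooth blobs by a
  # sub-structuring-element ring, so exact idempotence cannot hold; the
  # second application must stay within that ring of the first result
  g <- test_geometry(192)
  fr <- synth_image(synth_spec(image_side_px = 192, rng_seed = 41))
  fit <- ics(fr$image, fr$geom)
  once <- fit$mask
  twice <- finalize_lesion_mask(
    clean_and_connect(once, fit$geometry),
    score_regions(clean_and_connect(once, fit$geometry), fit$geometry))
  expect_true(all(once[!twice] == FALSE | !any(once & !twice)))
  expect_false(any(twice & !morph_disk(once, 0.5, fit$geometry, "dilate")))
  expect_gt(dice_coef(once, twice), 0.97)
})
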