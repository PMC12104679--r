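test_that("colour correction: identity, scalar, and affine recovery", {
  ref <- chart_reference_colors()
  ## identity case
  ct <- fit_color_correction(ref, ref)
  expect_equal(ct$matrix, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ct$offset, rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(ct$rms), rep(0, 3), tolerance = 1e-8)
  ## observed at half intensity: fitted matrix ~ 2 * identity
  ct <- fit_color_correction(ref / 2, ref)
  expect_equal(ct$matrix, 2 * diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  ## construct-and-invert: known well-conditioned affine map
  set.seed(3)
  A <- diag(c(0.9, 1.1, 1.05)) + matrix(rnorm(9, 0, 0.05), 3, 3)
  b <- c(4, -3, 7)
  observed <- ref %*% A + matrix(b, 24, 3, byrow = TRUE)
  ct <- fit_color_correction(observed, ref)
  recovered <- observed %*% ct$matrix +
    matrix(ct$offset, 24, 3, byrow = TRUE)
  expect_equal(recovered, ref, tolerance = 1e-6, ignore_attr = TRUE)
  ## residual never worse than identity (fit includes identity in its span)
  expect_true(all(ct$rms <= ct$rms_identity + 1e-9))
  ## rank-deficient patch set refused
  grey <- matrix(rep(seq(10, 100, length.out = 8), 3), ncol = 3)
  expect_error(fit_color_correction(grey, grey + 1), "rank")
  expect_error(fit_color_correction(ref[1:3, ], ref[1:3, ]), "4 patch")
})

test_that("apply_color_transform is the fitted map, clipped", {
  ref <- chart_reference_colors()
  ct <- fit_color_correction(ref / 2, ref)
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- ref[1, ] / 2
  img[2, 2, ] <- c(200, 200, 200)       # would map to ~400: clipped
  out <- apply_color_transform(img, ct)
  expect_equal(out[1, 1, ], unname(ref[1, ]), tolerance = 1e-6)
  expect_true(all(out <= 255 & out >= 0))
})

test_that("auto threshold separates green plant from black background", {
  img <- array(0, c(20, 20, 3))
  plant <- matrix(FALSE, 20, 20)
  plant[5:15, 8:12] <- TRUE
  img[, , 2][plant] <- 255
  m <- threshold_mask(img, "auto")
  expect_identical(m, plant)
  ## manual bounds excluding everything: empty mask with a warning
  expect_warning(
    m0 <- threshold_mask(img, list(lower = c(1, 1, 1), upper = c(2, 2, 2))),
    "empty")
  expect_false(any(m0))
  ## HSV bounds select the green hue
  mh <- threshold_mask(img, list(lower = c(0.2, 0.5, 0.5),
                                 upper = c(0.5, 1, 1)), color_space = "hsv")
  expect_identical(mh, plant)
})

test_that("clean_mask size filter and hole filling", {
  m <- matrix(FALSE, 30, 30)
  m[5:14, 5:14] <- TRUE                       # 100-px blob
  m[20, 20] <- TRUE; m[25, 3:4] <- TRUE; m[2, 28] <- TRUE  # specks
  cleaned <- clean_mask(m, min_component_px = 50, fill_holes = FALSE)
  expect_equal(sum(cleaned), 100)
  expect_true(all(which(cleaned) %in% which(m)))
  ## ring: filled with the flag, unchanged without
  ring <- matrix(FALSE, 15, 15)
  ring[4:11, 4:11] <- TRUE
  ring[6:9, 6:9] <- FALSE
  expect_equal(sum(clean_mask(ring, 0, fill_holes = TRUE)), 64)
  expect_identical(clean_mask(ring, 0, fill_holes = FALSE), ring)
  ## speckle field below the size threshold vanishes
  set.seed(9)
  sp <- matrix(runif(400) < 0.05, 20, 20)
  expect_false(any(clean_mask(sp, min_component_px = 50)))
})

test_that("label_components uses 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal touch: one component
  m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  ## 4-connectivity splits the diagonal pair
  lab4 <- label_components(m, connectivity = 4)
  expect_equal(max(lab4), 3)
})

test_that("split_plants assigns whole components by maximal ROI overlap", {
  rois <- data.frame(row1 = c(1, 1), row2 = c(20, 20),
                     col1 = c(1, 11), col2 = c(10, 20))
  ## one-to-one
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE
  m[3:6, 14:17] <- TRUE
  out <- split_plants(m, rois)
  expect_equal(sum(out[[1]]), 16); expect_equal(sum(out[[2]]), 16)
  expect_false(any(out[[1]] & out[[2]]))
  ## 60/40 straddling blob goes wholly to the majority ROI
  m2 <- matrix(FALSE, 20, 20)
  m2[5, 5:14] <- TRUE     # 6 px in ROI-1 cols 5:10, 4 px in ROI-2
  out2 <- split_plants(m2, rois)
  expect_equal(sum(out2[[1]]), 10)
  expect_equal(sum(out2[[2]]), 0)
  ## a component escaping above its ROI is kept whole
  rois3 <- data.frame(row1 = 10, row2 = 20, col1 = 1, col2 = 20)
  m3 <- matrix(FALSE, 20, 20)
  m3[2:20, 10] <- TRUE     # tall seedling extending above the rectangle
  out3 <- split_plants(m3, rois3)
  expect_equal(sum(out3[[1]]), 19)
  ## no-ROI component dropped with a log message
  m4 <- m3; m4[1:2, 1] <- TRUE
  rois4 <- data.frame(row1 = 10, row2 = 20, col1 = 5, col2 = 20)
  expect_message(out4 <- split_plants(m4, rois4), "dropped")
  expect_equal(sum(out4[[1]]), 19)
  expect_error(split_plants(m3, rois3[0, ]), "ROI")
  ## union of outputs contained in the input mask, outputs disjoint
  set.seed(4)
  mr <- clean_mask(random_test_mask(20, 20, 0.2), 3, FALSE)
  outs <- suppressMessages(split_plants(mr, rois))
  expect_false(any(outs[[1]] & outs[[2]]))
  expect_true(all(which(outs[[1]] | outs[[2]]) %in% which(mr)))
})

test_that("otsu threshold splits a clean bimodal signal", {
  set.seed(8)
  x <- c(rnorm(400, 10, 2), rnorm(200, 60, 4))
  t <- otsu_threshold(x)
  ## the cut separates the two modes perfectly
  expect_true(all(x[401:600] > t))
  expect_true(all(x[1:400] <= t))
  expect_equal(otsu_threshold(rep(3, 10)), 3)
})

test_that("front end achieves high overlap on a noisy synthetic scene", {
  ## scene with known plant pixels plus ~1% salt noise: Jaccard >= 0.95
  set.seed(21)
  img <- array(rnorm(60 * 60 * 3, 5, 2), c(60, 60, 3))
  plant <- matrix(FALSE, 60, 60)
  plant[10:50, 25:35] <- TRUE
  img[, , 1][plant] <- rnorm(sum(plant), 45, 6)
  img[, , 2][plant] <- rnorm(sum(plant), 140, 6)
  img[, , 3][plant] <- rnorm(sum(plant), 48, 6)
  salt <- matrix(runif(3600) < 0.01, 60, 60) & !plant
  img[, , 2][salt] <- 255
  m <- clean_mask(threshold_mask(img, "auto"), min_component_px = 25,
                  fill_holes = TRUE)
  jac <- sum(m & plant) / sum(m | plant)
  expect_gte(jac, 0.95)
})
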