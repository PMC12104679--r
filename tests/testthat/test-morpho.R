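test_that("features match hand values on canonical shapes", {
  sq <- matrix(FALSE, 20, 20)
  sq[6:15, 4:13] <- TRUE
  expect_identical(mask_area(sq), 100L)
  expect_equal(unname(bounding_extents(sq)), c(10, 10))
  h <- mask_convex_hull(sq)
  expect_equal(h$area, 100)
  expect_equal(h$n_vertices, 4)
  expect_equal(mask_solidity(mask_area(sq), h$area), 1.0)
  expect_equal(mask_perimeter(sq), 40)
  expect_equal(unname(center_of_mass(sq)), c(3 + 4.5, 5 + 4.5))
  expect_equal(longest_path(sq)$length, 10 * sqrt(2), tolerance = 1e-12)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_identical(mask_area(one), 1L)
  expect_equal(unname(bounding_extents(one)), c(1, 1))
  expect_equal(mask_perimeter(one), 4)

  diag10 <- matrix(FALSE, 12, 12)
  for (i in 1:10) diag10[i, i] <- TRUE
  expect_equal(unname(bounding_extents(diag10)), c(10, 10))

  two <- matrix(FALSE, 5, 9); two[2, 2] <- TRUE; two[4, 8] <- TRUE
  expect_equal(mask_perimeter(two), 8)   # additive over components

  pts <- matrix(FALSE, 3, 12)
  pts[1, c(1, 11)] <- TRUE               # pixels at (col,row) (0,0), (10,0)
  expect_equal(unname(center_of_mass(pts)), c(5, 0))
})

test_that("plus-shape hull area is 7 and solidity 5/7", {
  plus <- mask_from_string("
    .#.
    ###
    .#.")
  expect_identical(mask_area(plus), 5L)
  h <- mask_convex_hull(plus)
  expect_equal(h$area, 7)               # octagon of pixel corners
  expect_equal(h$n_vertices, 8)
  expect_equal(mask_solidity(5, h$area), 5 / 7)
  ## sparse L-shape is non-convex
  ell <- mask_from_string("
    #..
    #..
    ###")
  expect_lt(mask_solidity(mask_area(ell), mask_convex_hull(ell)$area), 1)
})

test_that("longest path: degenerate line and fallback behave as defined", {
  line <- matrix(FALSE, 3, 12)
  line[2, 2:11] <- TRUE                 # horizontal 1-px line of 10
  lp <- longest_path(line)
  ## chords qualifying within eps of the centroid include the box diagonal
  ## (0,0)-(10,1), which is sqrt(101); the horizontal edge gives 10.0
  expect_equal(lp$length, sqrt(101), tolerance = 1e-12)
  expect_false(lp$fallback)
  ## eps = 0 keeps only chords through the exact centroid: the diagonals
  expect_equal(longest_path(line, eps = 0)$length, sqrt(101),
               tolerance = 1e-12)
})

test_that("ellipse centre: exact fit, symmetry, and degeneracy flag", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  pts <- cbind(30 + 12 * cos(th), 40 + 7 * sin(th))
  ctr <- needledyn:::fit_ellipse_center(pts)
  expect_equal(unname(ctr), c(30, 40), tolerance = 1e-6)

  sq <- matrix(FALSE, 30, 30); sq[10:21, 8:19] <- TRUE
  ec <- ellipse_center(sq)
  com <- center_of_mass(sq)
  expect_lt(max(abs(ec - com)), 0.5)

  expect_true(isTRUE(attr(needledyn:::fit_ellipse_center(pts[1:5, ]),
                          "undefined")))
  ## collinear contour is degenerate
  col_pts <- cbind(1:10, 2 * (1:10))
  expect_true(isTRUE(attr(needledyn:::fit_ellipse_center(col_pts),
                          "undefined")))
})

test_that("extract_morphometrics composes features and flags empty masks", {
  sq <- matrix(FALSE, 12, 12)
  sq[2:11, 2:11] <- TRUE
  rec <- extract_morphometrics(sq, seedling = "s1", day = 1, session = "D1M")
  expect_equal(rec$area_px, 100)
  expect_equal(rec$solidity, 1)
  expect_equal(rec$hull_vertices, 4)
  expect_equal(rec$perimeter_px, 40)
  expect_equal(c(rec$com_x, rec$com_y), c(5.5, 5.5))
  expect_false(rec$undefined)

  empty <- extract_morphometrics(matrix(FALSE, 4, 4))
  expect_true(empty$undefined)
  expect_true(is.na(empty$area_px))
})

test_that("randomised masks agree with brute-force oracles", {
  set.seed(42)
  for (i in 1:25) {
    m <- clean_mask(random_test_mask(12, 12, p = runif(1, 0.2, 0.6)),
                    min_component_px = 0, fill_holes = FALSE)
    expect_identical(mask_area(m), oracle_area(m))
    expect_equal(bounding_extents(m), oracle_extents(m))
    expect_equal(center_of_mass(m), oracle_com(m))
    expect_equal(mask_perimeter(m), oracle_perimeter(m))
    h <- mask_convex_hull(m)
    expect_equal(h$area, oracle_hull_area(m), tolerance = 1e-9)
    expect_equal(h$n_vertices, oracle_hull_vertices(m))
    expect_gte(h$area, mask_area(m))     # containment
    lp <- longest_path(m)
    olp <- oracle_longest_path(m)
    expect_equal(lp$length, olp$length, tolerance = 1e-9)
    expect_identical(lp$fallback, olp$fallback)
  }
})

test_that("translation and 90-degree rotation behave as expected", {
  set.seed(7)
  base <- clean_mask(random_test_mask(10, 10, 0.4), 0, FALSE)
  shifted <- matrix(FALSE, 25, 25)
  shifted[6:15, 9:18] <- base            # translate by (+8, +5) in (x, y)
  padded <- matrix(FALSE, 25, 25)
  padded[1:10, 1:10] <- base
  for (f in list(mask_area, mask_perimeter,
                 function(m) mask_convex_hull(m)$area,
                 function(m) mask_convex_hull(m)$n_vertices,
                 function(m) unname(bounding_extents(m)),
                 function(m) longest_path(m)$length)) {
    expect_equal(f(padded), f(shifted))
  }
  expect_equal(center_of_mass(shifted) - center_of_mass(padded),
               c(x = 8, y = 5))
  ## 90-degree rotation swaps width and height
  rot <- t(padded)[, rev(seq_len(25))]
  e1 <- bounding_extents(padded); e2 <- bounding_extents(rot)
  expect_equal(unname(e1["width"]), unname(e2["height"]))
  expect_equal(unname(e1["height"]), unname(e2["width"]))
  expect_equal(mask_area(rot), mask_area(padded))
  ## rot[r, c] = padded[26 - c, r], so (x, y) maps to (24 - y, x)
  c1 <- center_of_mass(padded); c2 <- center_of_mass(rot)
  expect_equal(unname(c2), c(24 - c1[["y"]], c1[["x"]]))
})
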