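## Conventions (documented once, used everywhere):
##  * a mask is a logical matrix; matrix row r / column c hold the pixel at
##    0-based image coordinates x = c - 1 (column), y = r - 1 (row), with y
##    increasing downward;
##  * pixel-centre coordinates: the centre of pixel (r, c) is (x, y);
##  * corner-lattice coordinates: pixel (r, c) occupies the unit square with
##    corners (x, y) .. (x + 1, y + 1). Hull area and perimeter use the
##    corner lattice so a filled convex digital shape has solidity exactly 1
##    and area / hull area share units.

mask_check <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  mask
}

mask_coords <- function(mask) {
  idx <- which(mask)
  r <- ((idx - 1L) %% nrow(mask)) + 1L
  c <- ((idx - 1L) %/% nrow(mask)) + 1L
  cbind(x = c - 1, y = r - 1)
}

#' Mask area
#'
#' Number of foreground pixels.
#'
#' @param mask Logical matrix.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask_check(mask))

#' Bounding-box extents of a mask
#'
#' Maximum horizontal and vertical extents as inclusive pixel counts
#' (`max_col - min_col + 1`, `max_row - min_row + 1`).
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Named numeric vector `c(width, height)`.
#' @export
bounding_extents <- function(mask) {
  xy <- mask_coords(mask_check(mask))
  if (!nrow(xy)) stop("empty mask: extents undefined", call. = FALSE)
  c(width = diff(range(xy[, "x"])) + 1, height = diff(range(xy[, "y"])) + 1)
}

## all corner-lattice corners of the given pixels (deduplicated)
pixel_corners <- function(xy) {
  if (!nrow(xy)) return(xy)
  corners <- rbind(xy, sweep(xy, 2, c(1, 0), "+"),
                   sweep(xy, 2, c(0, 1), "+"), xy + 1)
  unique(corners)
}

## drop collinear points from an ordered polygon (closed implicitly)
drop_collinear <- function(v) {
  n <- nrow(v)
  if (n < 3) return(v)
  keep <- vapply(seq_len(n), function(i) {
    p <- v[if (i == 1) n else i - 1, ]
    q <- v[i, ]
    r <- v[if (i == n) 1 else i + 1, ]
    cr <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    abs(cr) > 1e-9
  }, logical(1))
  v[keep, , drop = FALSE]
}

shoelace_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Convex hull of a mask on the pixel-corner lattice
#'
#' The hull of the union of the unit squares occupied by the foreground
#' pixels: hull of all pixel corners, with area by the shoelace formula and
#' the vertex count taken after removing collinear points.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return List with `vertices` (two-column matrix of corner coordinates in
#'   hull order), `area`, and `n_vertices`.
#' @export
mask_convex_hull <- function(mask) {
  xy <- mask_coords(mask_check(mask))
  if (!nrow(xy)) stop("empty mask: hull undefined", call. = FALSE)
  corners <- pixel_corners(xy)
  h <- grDevices::chull(corners[, 1], corners[, 2])
  v <- drop_collinear(corners[h, , drop = FALSE])
  list(vertices = v, area = shoelace_area(v), n_vertices = nrow(v))
}

#' Solidity of a mask
#'
#' Area divided by convex hull area; exactly 1 for convex digital shapes
#' under the shared corner-lattice convention.
#'
#' @param area Foreground pixel count.
#' @param hull_area Convex hull area (corner lattice units), must be > 0.
#' @return Ratio in `(0, 1]`.
#' @export
mask_solidity <- function(area, hull_area) {
  if (!is.finite(hull_area) || hull_area <= 0) {
    stop("hull area must be positive", call. = FALSE)
  }
  area / hull_area
}

#' Crack-boundary perimeter of a mask
#'
#' Total length of the pixel-corner ("crack") boundary: the number of unit
#' edges between a foreground pixel and a background pixel or the image
#' border. Additive over disjoint components; includes hole boundaries
#' unless holes were filled upstream.
#'
#' @param mask Logical matrix.
#' @return Perimeter length (lattice units).
#' @export
mask_perimeter <- function(mask) {
  m <- mask_check(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up <- pad[1:nr, 2:(nc + 1)]
  down <- pad[3:(nr + 2), 2:(nc + 1)]
  left <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  sum(core & !up) + sum(core & !down) + sum(core & !left) + sum(core & !right)
}

#' Centre of mass of a mask
#'
#' Unweighted mean of the foreground pixel-centre coordinates.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Named numeric vector `c(x, y)` in pixel-centre coordinates.
#' @export
center_of_mass <- function(mask) {
  xy <- mask_coords(mask_check(mask))
  if (!nrow(xy)) stop("empty mask: centre of mass undefined", call. = FALSE)
  c(x = mean(xy[, "x"]), y = mean(xy[, "y"]))
}

## corner points of foreground pixels that touch background or the border
## (the candidate endpoints for the longest chord)
boundary_corner_points <- function(mask) {
  m <- mask_check(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + !pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  boundary <- m & nb > 0L
  pixel_corners(mask_coords(boundary))
}

## min distance from point cnt to segments p-q (vectorised over rows)
segment_point_distance <- function(p, q, cnt) {
  vx <- q[, 1] - p[, 1]; vy <- q[, 2] - p[, 2]
  wx <- cnt[1] - p[, 1]; wy <- cnt[2] - p[, 2]
  len2 <- vx * vx + vy * vy
  t <- ifelse(len2 > 0, clamp((wx * vx + wy * vy) / len2, 0, 1), 0)
  dx <- wx - t * vx; dy <- wy - t * vy
  sqrt(dx * dx + dy * dy)
}

#' Longest path through the centre of a mask
#'
#' The longest distance "passing through the centre": the maximum Euclidean
#' distance between two boundary corner points whose connecting segment
#' passes within `eps` of the mask centroid (the centre of mass expressed
#' on the corner lattice, i.e. shifted by +0.5 in x and y). If no chord
#' qualifies, falls back to twice the maximum distance from the centroid to
#' a boundary point, and flags the record.
#'
#' For masks with more than `max_exact` boundary corners the candidate set
#' is reduced to the convex hull vertices (a subset of the boundary
#' corners); exact enumeration is used below that size.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @param eps Chord-to-centroid tolerance in pixels (default 0.75).
#' @param max_exact Boundary-corner count above which only hull vertices
#'   are considered (default 1200).
#' @return List with `length`, `fallback` (logical), and `endpoints`
#'   (2 x 2 matrix, corner coordinates).
#' @export
longest_path <- function(mask, eps = 0.75, max_exact = 1200) {
  com <- center_of_mass(mask)
  cnt <- com + 0.5   # centroid on the corner lattice
  pts <- boundary_corner_points(mask)
  if (nrow(pts) > max_exact) pts <- mask_convex_hull(mask)$vertices
  n <- nrow(pts)
  if (n >= 2) {
    pair <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    p <- pts[pair[, 1], , drop = FALSE]
    q <- pts[pair[, 2], , drop = FALSE]
    ok <- segment_point_distance(p, q, cnt) <= eps
    if (any(ok)) {
      d <- sqrt(rowSums((p[ok, , drop = FALSE] - q[ok, , drop = FALSE])^2))
      best <- which.max(d)
      ep <- rbind(p[ok, , drop = FALSE][best, ], q[ok, , drop = FALSE][best, ])
      return(list(length = max(d), fallback = FALSE, endpoints = ep))
    }
  }
  d <- sqrt(rowSums(sweep(pts, 2, cnt)^2))
  best <- which.max(d)
  list(length = 2 * max(d), fallback = TRUE,
       endpoints = rbind(pts[best, ], 2 * cnt - pts[best, ]))
}

#' Centre of the ellipse fitted to a mask outline
#'
#' Fits an algebraic conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to
#' the outer-contour pixel centres by total least squares (smallest
#' singular vector of the design matrix) and returns the conic centre.
#' Requires at least 6 non-collinear contour points.
#'
#' @param mask Logical matrix.
#' @return Named numeric vector `c(x, y)`, or `c(NA, NA)` with attribute
#'   `undefined = TRUE` when the contour is too small or degenerate.
#' @export
ellipse_center <- function(mask) {
  m <- mask_check(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  contour <- m & !interior
  pts <- mask_coords(contour)
  fit_ellipse_center(pts)
}

## conic fit on explicit contour points; shared by ellipse_center and tests
fit_ellipse_center <- function(pts) {
  undefined <- function() {
    out <- c(x = NA_real_, y = NA_real_)
    attr(out, "undefined") <- TRUE
    out
  }
  if (nrow(pts) < 6) return(undefined())
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my          # centre for conditioning
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  sv <- svd(D)
  if (sv$d[5] < 1e-9 * max(sv$d[1], 1)) return(undefined())  # degenerate
  a <- sv$v[, 6]
  A <- a[1]; B <- a[2]; C <- a[3]; Dc <- a[4]; E <- a[5]
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  if (abs(det(M)) < 1e-12 * max(abs(a))^2) return(undefined())
  ctr <- solve(M, -c(Dc, E))
  c(x = ctr[1] + mx, y = ctr[2] + my)
}

#' Extract all seedling-level morphometric parameters
#'
#' Computes the full parameter set from a cleaned per-plant mask: area,
#' longest path, width, height, convex hull area, solidity, perimeter,
#' centre of mass (x, y), convex hull vertex count, and fitted-ellipse
#' centre (x, y). An empty mask yields a flagged record with all features
#' `NA` so a pipeline can continue past fully wilted seedlings.
#'
#' @param mask Logical matrix.
#' @param seedling,day,session Identifiers copied into the record.
#' @param eps Chord tolerance passed to [longest_path()].
#' @return One-row data frame (a `MorphometricRecord`); column `undefined`
#'   flags empty masks, `lp_fallback` flags the longest-path fallback.
#' @export
extract_morphometrics <- function(mask, seedling = NA, day = NA,
                                  session = NA, eps = 0.75) {
  empty <- data.frame(
    seedling = seedling, day = day, session = session,
    area_px = NA_real_, longest_path_px = NA_real_, width_px = NA_real_,
    height_px = NA_real_, hull_area_px2 = NA_real_, solidity = NA_real_,
    perimeter_px = NA_real_, com_x = NA_real_, com_y = NA_real_,
    hull_vertices = NA_real_, ellipse_x = NA_real_, ellipse_y = NA_real_,
    undefined = TRUE, lp_fallback = FALSE, stringsAsFactors = FALSE
  )
  if (!sum(mask_check(mask))) return(empty)
  a <- mask_area(mask)
  ext <- bounding_extents(mask)
  hull <- mask_convex_hull(mask)
  com <- center_of_mass(mask)
  lp <- longest_path(mask, eps = eps)
  ec <- ellipse_center(mask)
  data.frame(
    seedling = seedling, day = day, session = session,
    area_px = a,
    longest_path_px = lp$length,
    width_px = unname(ext["width"]),
    height_px = unname(ext["height"]),
    hull_area_px2 = hull$area,
    solidity = mask_solidity(a, hull$area),
    perimeter_px = mask_perimeter(mask),
    com_x = unname(com["x"]),
    com_y = unname(com["y"]),
    hull_vertices = hull$n_vertices,
    ellipse_x = unname(ec["x"]),
    ellipse_y = unname(ec["y"]),
    undefined = FALSE,
    lp_fallback = lp$fallback,
    stringsAsFactors = FALSE
  )
}
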