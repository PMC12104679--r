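#' Fit a chart-based colour correction
#'
#' Least-squares affine map from observed patch colours to reference patch
#' colours: `ref ~ obs %*% M + b`. Standardising colours against a chart of
#' known patches removes frame-to-frame lighting drift before
#' segmentation. The per-channel RMS residual is reported, together with
#' the RMS the identity map would leave, so improvement can be verified.
#'
#' @param observed Numeric matrix (n x 3) of mean RGB per chart patch as
#'   captured.
#' @param reference Numeric matrix (n x 3) of the known patch colours.
#' @return Object of class `color_transform`: `matrix` (3 x 3), `offset`
#'   (length 3), `rms` (per channel), `rms_identity`.
#' @export
fit_color_correction <- function(observed, reference) {
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  if (!all(dim(observed) == dim(reference)) || ncol(observed) != 3) {
    stop("observed and reference must be matching n x 3 matrices",
         call. = FALSE)
  }
  if (nrow(observed) < 4) {
    stop("need at least 4 patch pairs to fit an affine colour map",
         call. = FALSE)
  }
  X <- cbind(observed, 1)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    stop("rank-deficient patch set (rank ", qrX$rank,
         " < 4): patches do not span colour space", call. = FALSE)
  }
  coefs <- qr.coef(qrX, reference)
  fitted <- X %*% coefs
  out <- list(
    matrix = coefs[1:3, , drop = FALSE],
    offset = as.numeric(coefs[4, ]),
    rms = sqrt(colMeans((reference - fitted)^2)),
    rms_identity = sqrt(colMeans((reference - observed)^2))
  )
  class(out) <- "color_transform"
  out
}

#' @export
print.color_transform <- function(x, ...) {
  cat("<color_transform> affine RGB map\n")
  cat("  RMS residual:", sprintf("%.3f", x$rms), "\n")
  cat("  RMS identity:", sprintf("%.3f", x$rms_identity), "\n")
  invisible(x)
}

#' Apply a colour transform to an image
#'
#' @param image Numeric array `rows x cols x 3` (0--255).
#' @param transform A [fit_color_correction()] result.
#' @return Corrected image array, clipped to `[0, 255]`.
#' @export
apply_color_transform <- function(image, transform) {
  stopifnot(inherits(transform, "color_transform"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be rows x cols x 3",
                                        call. = FALSE)
  flat <- matrix(image, ncol = 3)
  out <- flat %*% transform$matrix +
    matrix(transform$offset, nrow(flat), 3, byrow = TRUE)
  array(clamp(out, 0, 255), dim = d)
}

#' Otsu threshold of a numeric channel
#'
#' Maximises between-class variance over a 256-bin histogram of the
#' channel's range. Used by the automatic plant/background cut.
#'
#' @param x Numeric vector or matrix.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold on the scale of `x` (values `> threshold` are
#'   foreground).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Threshold an image into a plant mask
#'
#' Automatic mode computes the excess-green index `2G - R - B` and splits
#' it with an Otsu cut, which is parameter-free and robust for green
#' vegetation on a dark background. Manual mode applies inclusive
#' per-channel bounds in RGB or HSV space (HSV channels on the usual
#' `h, s, v` in `[0, 1]` scale of [grDevices::rgb2hsv()]).
#'
#' @param image Numeric array `rows x cols x 3` (0--255), ideally colour
#'   corrected.
#' @param bounds `"auto"` (default) or a list with numeric length-3
#'   `lower` and `upper` vectors.
#' @param color_space `"rgb"` or `"hsv"` for manual bounds.
#' @return Logical matrix (the binary mask). An empty foreground triggers
#'   a warning, not an error.
#' @export
threshold_mask <- function(image, bounds = "auto", color_space = c("rgb", "hsv")) {
  color_space <- match.arg(color_space)
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be rows x cols x 3",
                                        call. = FALSE)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  if (identical(bounds, "auto")) {
    exg <- 2 * g - r - b
    mask <- exg > otsu_threshold(exg)
  } else {
    if (!is.list(bounds) || !all(c("lower", "upper") %in% names(bounds))) {
      stop("bounds must be \"auto\" or list(lower=, upper=)", call. = FALSE)
    }
    ch <- if (color_space == "rgb") {
      list(r, g, b)
    } else {
      hsv <- grDevices::rgb2hsv(rbind(as.numeric(r), as.numeric(g),
                                      as.numeric(b)), maxColorValue = 255)
      lapply(1:3, function(i) matrix(hsv[i, ], d[1], d[2]))
    }
    mask <- ch[[1]] >= bounds$lower[1] & ch[[1]] <= bounds$upper[1] &
      ch[[2]] >= bounds$lower[2] & ch[[2]] <= bounds$upper[2] &
      ch[[3]] >= bounds$lower[3] & ch[[3]] <= bounds$upper[3]
  }
  if (!any(mask)) warning("threshold produced an empty mask")
  mask
}

#' Label connected components of a mask
#'
#' 8-connectivity for the foreground by default (the background is
#' implicitly 4-connected, the usual complementary pairing in binary
#' imaging).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix: 0 for background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask_check(mask)
  stopifnot(connectivity %in% c(4, 8))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  lookup <- integer(length(mask)); lookup[idx] <- seq_along(idx)
  edges <- integer(0)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  for (d in shifts) {
    rr <- r + d[1]; cc <- c + d[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    nidx <- (cc[ok] - 1L) * nr + rr[ok]
    both <- mask[nidx]
    from <- lookup[idx[ok][both]]
    to <- lookup[nidx[both]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components in raster order of first occurrence
  lab_first <- comp[!duplicated(comp)]
  renum <- integer(max(comp)); renum[lab_first] <- seq_along(lab_first)
  lab[idx] <- renum[comp]
  lab
}

fill_mask_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2, nc + 2)          # border ring joins outside air
  pad[2:(nr + 1), 2:(nc + 1)] <- !mask         # TRUE where background
  bg <- label_components(pad, connectivity = 4)
  outside <- bg[1, 1]                          # ring is one 4-connected piece
  holes <- pad & bg != outside
  mask | holes[2:(nr + 1), 2:(nc + 1)]
}

#' Clean a binary mask
#'
#' Removes connected components (8-connectivity) smaller than
#' `min_component_px` and optionally fills interior holes (background
#' regions, 4-connected, that do not touch the image border).
#'
#' @param mask Logical matrix.
#' @param min_component_px Minimum component size kept (default 0).
#' @param fill_holes Fill interior holes (default `TRUE`).
#' @return Cleaned logical matrix.
#' @export
clean_mask <- function(mask, min_component_px = 0, fill_holes = TRUE) {
  if (min_component_px < 0) stop("min_component_px must be >= 0",
                                 call. = FALSE)
  out <- mask_check(mask)
  if (min_component_px > 0 && any(out)) {
    lab <- label_components(out)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_px)
    out <- matrix(lab %in% keep, nrow(out), ncol(out))
  }
  if (fill_holes && any(out)) out <- fill_mask_holes(out)
  out
}

#' Split a cleaned mask into per-plant masks
#'
#' Each connected component is assigned wholly (including pixels outside
#' the rectangle) to the ROI it overlaps; components overlapping several
#' ROIs go to the ROI of maximal pixel overlap (ties to the lowest ROI
#' index, logged via `message()`), and components touching no ROI are
#' dropped with a log entry.
#'
#' @param mask Cleaned logical matrix.
#' @param plant_rois Data frame (or list of vectors) with columns/elements
#'   `row1`, `row2`, `col1`, `col2` (inclusive, 1-based matrix indices).
#' @return List of logical masks, one per ROI, pairwise disjoint with
#'   union contained in `mask`.
#' @export
split_plants <- function(mask, plant_rois) {
  if (is.list(plant_rois) && !is.data.frame(plant_rois)) {
    plant_rois <- as.data.frame(do.call(rbind, plant_rois))
  }
  if (is.null(plant_rois) || nrow(plant_rois) == 0) {
    stop("split_plants needs at least one ROI", call. = FALSE)
  }
  need <- c("row1", "row2", "col1", "col2")
  if (!all(need %in% names(plant_rois))) {
    stop("ROIs must provide row1, row2, col1, col2", call. = FALSE)
  }
  if (any(plant_rois$row1 < 1) || any(plant_rois$col1 < 1) ||
      any(plant_rois$row2 > nrow(mask)) || any(plant_rois$col2 > ncol(mask))) {
    stop("ROIs must lie within the mask bounds", call. = FALSE)
  }
  lab <- label_components(mask_check(mask))
  n_comp <- max(lab)
  n_roi <- nrow(plant_rois)
  out <- lapply(seq_len(n_roi), function(i) matrix(FALSE, nrow(mask), ncol(mask)))
  if (n_comp == 0) return(out)
  overlap <- matrix(0L, n_comp, n_roi)
  for (j in seq_len(n_roi)) {
    sub <- lab[plant_rois$row1[j]:plant_rois$row2[j],
               plant_rois$col1[j]:plant_rois$col2[j]]
    t <- tabulate(sub[sub > 0], n_comp)
    overlap[, j] <- t
  }
  for (k in seq_len(n_comp)) {
    hits <- which(overlap[k, ] > 0)
    if (!length(hits)) {
      message("split_plants: component ", k, " touches no ROI; dropped")
      next
    }
    best <- hits[which.max(overlap[k, hits])]
    if (length(hits) > 1 &&
        sum(overlap[k, hits] == max(overlap[k, hits])) > 1) {
      message("split_plants: component ", k,
              " ties between ROIs; assigned to lowest index ", best)
    }
    out[[best]] <- out[[best]] | (lab == k)
  }
  out
}
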