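## Brute-force oracles, written as plain loops independent of the package
## internals. Coordinates follow the package conventions: pixel (r, c) has
## centre (x = c - 1, y = r - 1) and corners (x, y)..(x + 1, y + 1).

mask_from_string <- function(s) {
  rows <- strsplit(trimws(strsplit(s, "\n")[[1]]), "")
  rows <- rows[lengths(rows) > 0]
  t(vapply(rows, function(r) r == "#", logical(length(rows[[1]]))))
}

random_test_mask <- function(nr, nc, p = 0.3) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr * nc, 1)] <- TRUE
  m
}

oracle_area <- function(mask) {
  n <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) n <- n + 1L
  }
  n
}

oracle_extents <- function(mask) {
  rs <- c(); cs <- c()
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) { rs <- c(rs, r); cs <- c(cs, c) }
  }
  c(width = max(cs) - min(cs) + 1, height = max(rs) - min(rs) + 1)
}

oracle_com <- function(mask) {
  xs <- c(); ys <- c()
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) { xs <- c(xs, c - 1); ys <- c(ys, r - 1) }
  }
  c(x = mean(xs), y = mean(ys))
}

oracle_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  p <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      if (!at(r + d[1], c + d[2])) p <- p + 1L
    }
  }
  p
}

## all pixel corners of the mask (for hull) — loops, deduplicated
oracle_corners <- function(mask) {
  pts <- NULL
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    x <- c - 1; y <- r - 1
    pts <- rbind(pts, c(x, y), c(x + 1, y), c(x, y + 1), c(x + 1, y + 1))
  }
  unique(pts)
}

## Jarvis gift-wrapping convex hull (candidate scan vectorised, but the
## algorithm is independent of grDevices::chull); vertices in march order
oracle_hull <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 1] * 1e6 + pts[, 2])
  hull <- start
  current <- start
  repeat {
    cx <- pts[current, 1]; cy <- pts[current, 2]
    cand <- setdiff(seq_len(n), current)
    nxt <- cand[1]
    repeat {
      cr <- (pts[nxt, 1] - cx) * (pts[cand, 2] - cy) -
        (pts[nxt, 2] - cy) * (pts[cand, 1] - cx)
      d_nxt <- (pts[nxt, 1] - cx)^2 + (pts[nxt, 2] - cy)^2
      d_cand <- (pts[cand, 1] - cx)^2 + (pts[cand, 2] - cy)^2
      better <- cr < -1e-12 | (abs(cr) <= 1e-12 & d_cand > d_nxt)
      if (!any(better)) break
      nxt <- cand[which(better)[which.max(d_cand[better])]]
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    current <- nxt
    if (length(hull) > n) stop("hull loop failure")
  }
  pts[hull, , drop = FALSE]
}

oracle_shoelace <- function(v) {
  n <- nrow(v); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

oracle_hull_area <- function(mask) {
  oracle_shoelace(oracle_hull(oracle_corners(mask)))
}

oracle_hull_vertices <- function(mask) {
  v <- oracle_hull(oracle_corners(mask))
  ## drop collinear points
  n <- nrow(v)
  if (n < 3) return(n)
  keep <- 0L
  for (i in seq_len(n)) {
    p <- v[if (i == 1) n else i - 1, ]
    q <- v[i, ]
    r <- v[if (i == n) 1 else i + 1, ]
    cr <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(cr) > 1e-9) keep <- keep + 1L
  }
  keep
}

## boundary corner points (corners of pixels with a background 8-neighbour
## or at the border), by loops
oracle_boundary_corners <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  pts <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    isb <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (!at(r + dr, c + dc)) isb <- TRUE
    }
    if (isb) {
      x <- c - 1; y <- r - 1
      pts <- rbind(pts, c(x, y), c(x + 1, y), c(x, y + 1), c(x + 1, y + 1))
    }
  }
  unique(pts)
}

oracle_seg_dist <- function(p, q, z) {
  v <- q - p; w <- z - p
  len2 <- sum(v * v)
  t <- if (len2 > 0) max(0, min(1, sum(w * v) / len2)) else 0
  sqrt(sum((w - t * v)^2))
}

oracle_longest_path <- function(mask, eps = 0.75) {
  com <- oracle_com(mask)
  cnt <- com + 0.5
  pts <- oracle_boundary_corners(mask)
  best <- -1
  n <- nrow(pts)
  ## pairwise scan, inner loop vectorised over j for speed; the chord
  ## distance formula is written out independently of the implementation
  for (i in seq_len(max(0, n - 1))) {
    j <- (i + 1):n
    vx <- pts[j, 1] - pts[i, 1]; vy <- pts[j, 2] - pts[i, 2]
    wx <- cnt[1] - pts[i, 1]; wy <- cnt[2] - pts[i, 2]
    len2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ifelse(len2 > 0, (wx * vx + wy * vy) / len2, 0)))
    dist_c <- sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
    ok <- dist_c <= eps
    if (any(ok)) best <- max(best, sqrt(max(len2[ok])))
  }
  if (best >= 0) return(list(length = best, fallback = FALSE))
  dmax <- sqrt(max((pts[, 1] - cnt[1])^2 + (pts[, 2] - cnt[2])^2))
  list(length = 2 * dmax, fallback = TRUE)
}

## small, fast experiment configuration for pipeline-level tests
tiny_config <- function(seed = 1, ...) {
  experiment_config(n_seedlings_per_treatment = 4,
                    n_imaged_per_treatment = 4, n_days = 4,
                    rng_seed = seed, ...)
}
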