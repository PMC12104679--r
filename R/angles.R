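#' Needle angle from base and tip image coordinates
#'
#' The needle angle theta is the signed interior angle (within +/- 90
#' degrees) between the horizontal line through the needle base and the
#' base-to-tip vector. Image coordinates have the origin at the top-left
#' with y (row) increasing downward, so a tip on a *smaller* row than its
#' base points up and yields a positive angle; a drooping needle yields a
#' negative angle. Vertical needles return +/- 90.
#'
#' @param base,tip Numeric length-2 vectors `c(col, row)`, or two-column
#'   matrices of coordinates (vectorised over rows).
#' @return Angle(s) in degrees within `[-90, 90]`.
#' @export
#' @examples
#' needle_angle(c(50, 100), c(60, 90))  # +45
needle_angle <- function(base, tip) {
  base <- matrix(as.numeric(base), ncol = 2)
  tip <- matrix(as.numeric(tip), ncol = 2)
  if (nrow(base) == 1 && nrow(tip) > 1) base <- base[rep(1, nrow(tip)), , drop = FALSE]
  if (nrow(tip) == 1 && nrow(base) > 1) tip <- tip[rep(1, nrow(base)), , drop = FALSE]
  rise <- base[, 2] - tip[, 2]           # positive when tip is above base
  run <- abs(tip[, 1] - base[, 1])       # unsigned horizontal distance
  if (any(rise == 0 & run == 0)) {
    stop("needle base and tip coincide; angle undefined", call. = FALSE)
  }
  clamp(atan2(rise, run) * 180 / pi, -90, 90)
}

#' Quadrant-averaged apical needle angle
#'
#' Individual needles are hard to track over time, so the apical image is
#' split into four quadrants, needle angles are averaged within each
#' quadrant (unweighted), and the seedling's session angle `theta` is the
#' unweighted mean of the non-empty quadrant means.
#'
#' @param angles Numeric vector of per-needle angles in degrees.
#' @param quadrant Vector (coercible to factor with levels 1--4) assigning
#'   each needle to a quadrant.
#' @return A list of class `needle_angle_observation` with elements
#'   `quadrant_angles` (length 4, `NA` for empty quadrants), `theta`,
#'   `n_needles_measured`, and `measurable`.
#' @export
quadrant_mean <- function(angles, quadrant) {
  keep <- !is.na(angles)
  angles <- angles[keep]
  quadrant <- as.integer(quadrant)[keep]
  if (length(angles) && (any(is.na(quadrant)) || any(quadrant < 1 | quadrant > 4))) {
    stop("quadrant assignments must be integers in 1..4", call. = FALSE)
  }
  qa <- rep(NA_real_, 4)
  for (q in unique(quadrant)) qa[q] <- mean(angles[quadrant == q])
  obs <- list(
    quadrant_angles = qa,
    theta = if (length(angles)) mean(qa, na.rm = TRUE) else NA_real_,
    n_needles_measured = length(angles),
    measurable = length(angles) > 0
  )
  class(obs) <- "needle_angle_observation"
  obs
}

#' @export
print.needle_angle_observation <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf("theta = %.2f deg from %d needles (quadrants: %s)\n",
                x$theta, x$n_needles_measured,
                paste(sprintf("%.1f", x$quadrant_angles), collapse = ", ")))
  } else {
    cat("unmeasurable apical part (no needles)\n")
  }
  invisible(x)
}

#' STx bin of a needle angle
#'
#' Partitions `[-90, +90]` into six 30-degree intervals: ST1 `[-90, -60)`,
#' ST2 `[-60, -30)`, ST3 `[-30, 0)`, ST4 `[0, 30)`, ST5 `[30, 60)`, and
#' ST6 `[60, 90]` (only the last interval is right-closed).
#'
#' @param theta Numeric vector of angles in degrees, `|theta| <= 90`.
#' @return Factor with levels `ST1`..`ST6` (`NA` input maps to `NA`).
#' @export
stx_bin <- function(theta) {
  bad <- !is.na(theta) & (theta < -90 | theta > 90)
  if (any(bad)) {
    stop("theta outside [-90, 90]: ", paste(theta[bad], collapse = ", "),
         call. = FALSE)
  }
  idx <- pmin(floor((theta + 90) / 30) + 1, 6)
  factor(paste0("ST", idx), levels = paste0("ST", 1:6))
}

#' Numeric STx level of a needle angle
#'
#' Convenience scoring of [stx_bin()] as the integers 1--6, the form used
#' when STx serves as a regression response.
#'
#' @inheritParams stx_bin
#' @return Integer vector in 1..6.
#' @export
stx_level <- function(theta) as.integer(stx_bin(theta))

#' Difference parameters of a needle-angle series
#'
#' For each session of a per-seedling series of quadrant-averaged angles,
#' derives the three difference parameters:
#' \describe{
#'   \item{bd_m}{baseline (pre-drought, `BD`) angle minus current angle;}
#'   \item{pm_m}{angle at the immediately preceding session minus current;}
#'   \item{pm_m_st}{angle at the previous session of the same time of day
#'     (previous morning for a morning, previous evening for an evening)
#'     minus current.}
#' }
#' Positive values mean the needles dropped relative to the reference
#' (wilting); negative values mean they rose (recovery). A parameter is
#' `NA` when either operand session is missing or unmeasurable.
#'
#' @param sessions Character vector of session labels.
#' @param theta Numeric vector of angles (degrees), `NA` when unmeasurable.
#' @return Data frame with columns `session`, `theta`, `stx`, `bd_m`,
#'   `pm_m`, `pm_m_st`, sorted chronologically.
#' @export
derive_angle_parameters <- function(sessions, theta) {
  info <- session_info(sessions)
  ord <- order(info$index)
  info <- info[ord, ]
  theta <- theta[ord]
  n <- nrow(info)
  look <- function(idx) {
    m <- match(idx, info$index)
    ifelse(is.na(m), NA_real_, theta[m])
  }
  theta_bd <- look(rep(0L, n))
  theta_prev <- look(info$index - 1L)
  ## same time of day, previous day; BD counts as the day-0 morning
  st_index <- ifelse(info$day >= 2L, 2L * (info$day - 1L) - 1L +
                       (info$time == "E"),
                     ifelse(info$day == 1L & info$time == "M", 0L,
                            NA_integer_))
  theta_prev_st <- look(st_index)
  data.frame(
    session = info$session,
    theta = theta,
    stx = stx_bin(theta),
    bd_m = theta_bd - theta,
    pm_m = theta_prev - theta,
    pm_m_st = theta_prev_st - theta,
    stringsAsFactors = FALSE
  )
}

#' Classify apical vitality over a session series
#'
#' Applies the three-state apical bookkeeping used for the vitality tally:
#' `O` (survival), `R` (recovery: the morning session immediately after a
#' first wilt at which the angle has returned within the wilt threshold),
#' and `X` (dead: apical discoloration at or above `dead_frac`; absorbing).
#' A session counts as wilted when the drop from the baseline angle is at
#' least `wilt_drop_min` degrees. Seedlings whose apical part is
#' unmeasurable at a session (angle `NA` while not yet discoloured-dead)
#' are excluded from that session's tally.
#'
#' @param sessions Character session labels (one seedling's series).
#' @param theta Numeric angles, `NA` when unmeasurable.
#' @param discoloration Numeric fraction (0--1) of apical discoloration per
#'   session (default all 0).
#' @param wilt_drop_min Wilt threshold in degrees (default 15).
#' @param dead_frac Discoloration fraction at which the apical part counts
#'   as dead (default 0.8).
#' @return Data frame with columns `session`, `state` (`"O"`, `"R"`, `"X"`,
#'   or `NA` when unmeasurable but not dead), `wilted` (logical),
#'   `first_wilt_session`, `death_session`.
#' @export
classify_vitality <- function(sessions, theta,
                              discoloration = rep(0, length(sessions)),
                              wilt_drop_min = 15, dead_frac = 0.8) {
  info <- session_info(sessions)
  ord <- order(info$index)
  info <- info[ord, ]
  theta <- theta[ord]
  discoloration <- discoloration[ord]
  if (info$index[1] != 0L) {
    stop("series must include the baseline session BD", call. = FALSE)
  }
  theta_bd <- theta[1]
  n <- nrow(info)
  wilted <- !is.na(theta) & (theta_bd - theta >= wilt_drop_min)
  dead_at <- which(discoloration >= dead_frac)
  death_i <- if (length(dead_at)) min(dead_at) else NA_integer_
  first_wilt_i <- if (any(wilted)) min(which(wilted)) else NA_integer_
  state <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(death_i) && i >= death_i) {
      state[i] <- "X"
    } else if (is.na(theta[i])) {
      state[i] <- NA_character_   # unmeasurable, excluded from tally
    } else if (!is.na(first_wilt_i) &&
               info$index[i] == info$index[first_wilt_i] + 1L &&
               info$time[i] == "M" && !wilted[i]) {
      state[i] <- "R"
    } else {
      state[i] <- "O"
    }
  }
  data.frame(
    session = info$session,
    state = state,
    wilted = wilted,
    first_wilt_session = if (is.na(first_wilt_i)) NA_character_ else
      info$session[first_wilt_i],
    death_session = if (is.na(death_i)) NA_character_ else
      info$session[death_i],
    stringsAsFactors = FALSE
  )
}

#' Vitality tally across a cohort
#'
#' Percentage of seedlings in each vitality state per session, in the style
#' of an apical-vigour table. Unmeasurable (NA-state) seedlings are
#' excluded from a session's denominator.
#'
#' @param states Data frame with columns `seedling`, `session`, `state`
#'   (rows as produced by [classify_vitality()], one set per seedling).
#' @return Data frame with columns `session`, `O`, `R`, `X` (percentages).
#' @export
vitality_tally <- function(states) {
  stopifnot(all(c("seedling", "session", "state") %in% names(states)))
  info <- session_info(unique(states$session))
  out <- lapply(info$session[order(info$index)], function(s) {
    st <- states$state[states$session == s]
    st <- st[!is.na(st)]
    n <- length(st)
    data.frame(session = s,
               O = if (n) 100 * mean(st == "O") else NA_real_,
               R = if (n) 100 * mean(st == "R") else NA_real_,
               X = if (n) 100 * mean(st == "X") else NA_real_,
               n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
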