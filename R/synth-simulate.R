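## Scene geometry constants (pixels). Frames hold a 24-patch colour chart
## strip along the top and four plant ROIs (control, drought, control,
## drought) above a black background.
CHART_PATCH <- 8L
CHART_GAP <- 2L
PLANT_GREEN <- c(45, 140, 48)
DEAD_BROWN <- c(150, 95, 40)

#' Reference colours of the synthetic 24-patch chart
#'
#' A fixed palette spanning colour space (dark/light skin-tone stand-ins,
#' primaries, greys) so the affine colour fit is well conditioned.
#'
#' @return 24 x 3 numeric matrix of RGB values in 0--255.
#' @export
chart_reference_colors <- function() {
  m <- matrix(c(
    115,  82,  68,  194, 150, 130,   98, 122, 157,   87, 108,  67,
    133, 128, 177,  103, 189, 170,  214, 126,  44,   80,  91, 166,
    193,  90,  99,   94,  60, 108,  157, 188,  64,  224, 163,  46,
     56,  61, 150,   70, 148,  73,  175,  54,  60,  231, 199,  31,
    187,  86, 149,    8, 133, 161,  243, 243, 242,  200, 200, 200,
    160, 160, 160,  122, 122, 121,   85,  85,  85,   52,  52,  52
  ), ncol = 3, byrow = TRUE)
  colnames(m) <- c("R", "G", "B")
  m
}

## chart patch rectangles for a given frame width; 12 x 2 grid
chart_patch_rects <- function() {
  rects <- expand.grid(col_i = 0:11, row_i = 0:1)
  step <- CHART_PATCH + CHART_GAP
  data.frame(
    patch = seq_len(24),
    row1 = 4L + rects$row_i * step,
    row2 = 4L + rects$row_i * step + CHART_PATCH - 1L,
    col1 = 8L + rects$col_i * step,
    col2 = 8L + rects$col_i * step + CHART_PATCH - 1L
  )
}

plant_roi_rects <- function(frame_height, frame_width) {
  w <- (frame_width - 20L) %/% 4L
  col1 <- 10L + (0:3) * w
  data.frame(
    roi = 1:4,
    row1 = 32L, row2 = frame_height - 4L,
    col1 = col1, col2 = col1 + w - 5L
  )
}

## sample integer pixels along a segment given float endpoints (col,row)
segment_pixels <- function(p, q, nr, nc) {
  len <- sqrt(sum((q - p)^2))
  t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
  cc <- round(p[1] + t * (q[1] - p[1]))
  rr <- round(p[2] + t * (q[2] - p[2]))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[ok] - 1L) * nr + rr[ok])   # linear indices (column-major)
}

## fixed per-seedling plant geometry, drawn from the seedling's substream
draw_seedling_geometry <- function(config, roi) {
  stem_h <- round(clamp(stats::rnorm(1, 92, 7), 70,
                        roi$row2 - roi$row1 - 8))
  base_col <- (roi$col1 + roi$col2) %/% 2L
  base_row <- roi$row2 - 3L
  lower_h <- seq(8, floor(0.8 * stem_h), by = 7)
  lower <- data.frame(
    h = rep(lower_h, each = 2),
    side = rep(c(-1, 1), length(lower_h)),
    len = clamp(stats::rnorm(2 * length(lower_h), 13, 2), 9, 17),
    angle = clamp(stats::rnorm(2 * length(lower_h), 25, 10), -10, 60)
  )
  apical_h <- floor(0.8 * stem_h) +
    sort(stats::runif(6, 0, 0.2 * stem_h - 1))
  apical <- data.frame(
    h = rep(apical_h, each = 2),
    side = rep(c(-1, 1), 6),
    len = clamp(stats::rnorm(12, 13, 2), 9, 17)
  )
  list(stem_h = stem_h, base_col = base_col, base_row = base_row,
       lower = lower, apical = apical)
}

## render one seedling into the truth canvas; returns pixel indices, colour
## mix factors and the apical needle annotation endpoints
render_seedling <- function(geom, theta, droop, discolor, vitality, config) {
  nr <- config$frame_height; nc <- config$frame_width
  droop <- if (vitality %in% c("wilted", "dead")) droop else 0
  eff_h <- max(10, geom$stem_h - round(droop))
  apex_row <- geom$base_row - eff_h
  stem_px <- segment_pixels(c(geom$base_col, geom$base_row),
                            c(geom$base_col, apex_row), nr, nc)
  stem_px <- c(stem_px, segment_pixels(
    c(geom$base_col + 1, geom$base_row),
    c(geom$base_col + 1, apex_row), nr, nc))
  apical_cut <- geom$base_row - 0.8 * eff_h   # rows above this are apical
  lower_px <- integer(0)
  for (i in seq_len(nrow(geom$lower))) {
    nd <- geom$lower[i, ]
    if (nd$h > eff_h) next
    b <- c(geom$base_col, geom$base_row - nd$h)
    ang <- nd$angle * pi / 180
    tip <- b + c(nd$side * nd$len * cos(ang), -nd$len * sin(ang))
    lower_px <- c(lower_px, segment_pixels(b, tip, nr, nc))
  }
  apical_px <- integer(0)
  ann <- NULL
  if (vitality != "dead" || discolor < 1) {
    apical_scale <- eff_h / geom$stem_h
    heights <- geom$apical$h * apical_scale
    mid_h <- (min(heights) + max(heights)) / 2
    for (i in seq_len(nrow(geom$apical))) {
      nd <- geom$apical[i, ]
      h_i <- heights[i]
      th_i <- theta + stats::rnorm(1, 0, config$needle_angle_sd)
      th_i <- clamp(th_i, -90, 90)
      b <- c(geom$base_col, geom$base_row - h_i)
      ang <- th_i * pi / 180
      tip <- b + c(nd$side * nd$len * cos(ang), -nd$len * sin(ang))
      apical_px <- c(apical_px, segment_pixels(b, tip, nr, nc))
      if (vitality != "dead") {
        quadrant <- (if (h_i >= mid_h) 0L else 2L) +
          (if (nd$side < 0) 1L else 2L)
        ann <- rbind(ann, data.frame(
          quadrant = quadrant, theta_needle = th_i,
          base_col = round(b[1]), base_row = round(b[2]),
          tip_col = round(tip[1]), tip_row = round(tip[2])
        ))
      }
    }
  }
  list(stem_px = unique(stem_px), lower_px = unique(lower_px),
       apical_px = unique(apical_px), annotations = ann)
}

## assemble + distort one frame; returns scene list and thermal map
render_frame <- function(config, session, frame_id, members, geoms, gt_rows,
                         ta, ah) {
  nr <- config$frame_height; nc <- config$frame_width
  img <- array(0, dim = c(nr, nc, 3))
  rois <- plant_roi_rects(nr, nc)
  refc <- chart_reference_colors()
  patches <- chart_patch_rects()
  for (p in seq_len(24)) {
    img[patches$row1[p]:patches$row2[p],
        patches$col1[p]:patches$col2[p], 1] <- refc[p, 1]
    img[patches$row1[p]:patches$row2[p],
        patches$col1[p]:patches$col2[p], 2] <- refc[p, 2]
    img[patches$row1[p]:patches$row2[p],
        patches$col1[p]:patches$col2[p], 3] <- refc[p, 3]
  }
  thermal <- matrix(ta + stats::rnorm(nr * nc, 0, config$thermal_pixel_sd),
                    nr, nc)
  truth_pixels <- vector("list", 4)
  annotations <- NULL
  extents <- NULL
  plane <- nr * nc
  for (k in seq_len(nrow(members))) {
    sid <- members$seedling[k]
    gt <- gt_rows[gt_rows$seedling == sid, ]
    geom <- geoms[[sid]]
    theta <- if (is.na(gt$theta_true)) gt$last_theta else gt$theta_true
    rs <- render_seedling(geom, theta, gt$droop_px, gt$discoloration,
                          gt$vitality, config)
    green_px <- c(rs$stem_px, rs$lower_px)
    ap <- rs$apical_px
    f <- if (gt$vitality == "dead") gt$discoloration else 0
    col_green <- PLANT_GREEN
    col_ap <- (1 - f) * PLANT_GREEN + f * DEAD_BROWN
    for (ch in 1:3) {
      img[green_px + (ch - 1L) * plane] <- col_green[ch] +
        stats::rnorm(length(green_px), 0, 6)
      img[ap + (ch - 1L) * plane] <- col_ap[ch] +
        stats::rnorm(length(ap), 0, 6)
    }
    ## the stated truth is the filled plant silhouette: enclosed pockets
    ## between crossing needles belong to the plant region
    all_px <- unique(c(green_px, ap))
    rr <- ((all_px - 1L) %% nr) + 1L
    cc <- ((all_px - 1L) %/% nr) + 1L
    r0 <- min(rr); c0 <- min(cc)
    sub <- matrix(FALSE, max(rr) - r0 + 1L, max(cc) - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
    sub <- fill_mask_holes(sub)
    fidx <- which(sub)
    fr_ <- ((fidx - 1L) %% nrow(sub)) + r0
    fc_ <- ((fidx - 1L) %/% nrow(sub)) + c0
    all_px <- (fc_ - 1L) * nr + fr_
    truth_pixels[[members$roi[k]]] <- all_px
    thermal[all_px] <- gt$tl_true +
      stats::rnorm(length(all_px), 0, config$thermal_pixel_sd)
    if (!is.null(rs$annotations)) {
      annotations <- rbind(annotations, data.frame(
        seedling = sid, treatment = members$treatment[k],
        session = session, rendered = TRUE, rs$annotations
      ))
    }
    extents <- rbind(extents, data.frame(
      seedling = sid, session = session,
      canopy_height_px = max(fr_) - min(fr_) + 1L,
      canopy_width_px = max(fc_) - min(fc_) + 1L,
      n_truth_px = length(all_px), stringsAsFactors = FALSE
    ))
  }
  # capture distortion: per-channel affine drift + sensor noise
  gains <- stats::rnorm(3, 1, 0.04)
  cross <- 0.02
  A <- diag(gains) + matrix(stats::rnorm(9, 0, cross), 3, 3) * (1 - diag(3))
  b <- stats::rnorm(3, 0, 4)
  flat <- matrix(img, ncol = 3) %*% t(A) +
    matrix(b, plane, 3, byrow = TRUE)
  flat <- flat + stats::rnorm(length(flat), 0, 3)
  img <- array(as.integer(round(clamp(flat, 0, 255))), dim = c(nr, nc, 3))
  scene <- list(
    image = img, session = session, frame = frame_id,
    rois = cbind(members, rois[members$roi, c("row1", "row2", "col1", "col2")]),
    chart = list(patches = patches, reference = refc),
    truth_pixels = truth_pixels
  )
  list(scene = scene, thermal = thermal, annotations = annotations,
       extents = extents)
}

#' Simulate a complete drought-stress imaging experiment
#'
#' Generates the full synthetic world of one experiment under a seeded
#' configuration: per-session RGB frames (four plants plus a colour chart,
#' with affine capture distortion and sensor noise), matching thermal
#' maps, the greenhouse environment series, a physiology table, apical
#' needle annotations (base/tip coordinates standing in for manual
#' digitisation), and the generating ground truth for every seedling and
#' session. Identical configuration and seed give bitwise identical
#' output.
#'
#' @param config An [experiment_config()].
#' @param render Render frames and thermal maps (default `TRUE`); with
#'   `FALSE` only the tabular outputs are produced (fast path for
#'   statistical property checks).
#' @return Object of class `needle_experiment`: list with `config`,
#'   `sessions`, `env`, `physio`, `ground_truth`, `annotations`,
#'   `seedlings`, `scenes`, `thermal_maps`.
#' @export
simulate_experiment <- function(config = experiment_config(), render = TRUE) {
  validate_experiment_config(config)
  set.seed(config$rng_seed)
  n <- config$n_seedlings_per_treatment
  sessions <- session_info(session_labels(config$n_days))
  n_sessions <- nrow(sessions)
  seed_pool <- substream_seeds(config$rng_seed, 2L * n + n_sessions + 2L)

  ## ---- environment series (diurnal structure + noise) ----
  set.seed(seed_pool[1])
  amp <- c(AH = 5, AT = 2, SR = 80, SM = 0, ST = 2)
  diurnal_sign <- ifelse(sessions$time == "M", 1, -1)
  env <- sessions
  for (v in c("AH", "AT", "SR", "ST")) {
    s <- if (v == "AT") -diurnal_sign else diurnal_sign  # AT peaks evenings
    resid_sd <- sqrt(max(0, config$env_sds[[v]]^2 - amp[[v]]^2))
    env[[v]] <- config$env_means[[v]] + s * amp[[v]] +
      stats::rnorm(n_sessions, 0, resid_sd)
  }
  env$AH <- clamp(env$AH, 2, 100)
  env$SR <- pmax(env$SR, 0)
  env$SM_control <- stats::rnorm(n_sessions, config$env_means[["SM"]],
                                 config$env_sds[["SM"]])
  sm_slope <- seq(config$env_means[["SM"]], config$sm_drought_final,
                  length.out = n_sessions)
  env$SM_drought <- stats::rnorm(n_sessions, sm_slope, 1)

  ## ---- per-seedling trajectories and ground truth ----
  effect_from_day <- if (is.na(config$physio_effect_day)) Inf else
    as.integer(sub("^D", "", config$physio_effect_day))
  seedlings <- data.frame(
    seedling = c(sprintf("C%02d", seq_len(n)), sprintf("D%02d", seq_len(n))),
    treatment = rep(c("control", "drought"), each = n),
    stringsAsFactors = FALSE
  )
  seedlings$imaged <- c(seq_len(n) <= config$n_imaged_per_treatment,
                        seq_len(n) <= config$n_imaged_per_treatment)
  rois <- plant_roi_rects(config$frame_height, config$frame_width)
  geoms <- list()
  gt <- NULL
  ann_all <- NULL
  for (i in seq_len(nrow(seedlings))) {
    sid <- seedlings$seedling[i]
    trt <- seedlings$treatment[i]
    set.seed(seed_pool[1L + i])
    baseline <- clamp(stats::rnorm(1, config$baseline_angle_mean,
                                   config$baseline_angle_sd), -85, 85)
    frame_pos <- ((match(sid, seedlings$seedling[seedlings$treatment == trt &
                                                   seedlings$imaged]) - 1L) %% 2L)
    roi_id <- if (trt == "control") 1L + 2L * frame_pos else 2L + 2L * frame_pos
    geoms[[sid]] <- draw_seedling_geometry(config, rois[if (is.na(roi_id)) 1 else roi_id, ])
    tl_shift <- stats::rnorm(1, config$tl_shift_mean, config$tl_shift_sd)
    st <- seedling_state(baseline)
    for (s in seq_len(n_sessions)) {
      step <- angle_trajectory(trt, sessions$session[s], st, config)
      st <- step$state
      eff_on <- trt == "drought" && sessions$day[s] >= effect_from_day
      tl_true <- env$AT[s] - config$tl_offset +
        (if (eff_on) tl_shift else 0) +
        stats::rnorm(1, 0, config$tl_noise_sd)
      gt <- rbind(gt, data.frame(
        seedling = sid, treatment = trt,
        session = sessions$session[s], day = sessions$day[s],
        time = sessions$time[s],
        theta_true = step$theta, vitality = st$vitality,
        discoloration = st$discoloration,
        droop_px = if (st$vitality %in% c("wilted", "dead")) st$droop else 0,
        last_theta = st$last_theta,
        stem_height_px = geoms[[sid]]$stem_h,
        baseline_theta = baseline,
        tl_true = tl_true,
        stringsAsFactors = FALSE
      ))
      ## analytic annotations for non-imaged seedlings (digitised by hand
      ## in the real protocol); rendered seedlings get pixel endpoints later
      if ((!seedlings$imaged[i] || !render) && st$vitality != "dead") {
        th_needle <- clamp(step$theta +
                             stats::rnorm(12, 0, config$needle_angle_sd),
                           -90, 90)
        side <- rep(c(-1, 1), 6)
        len <- 20
        bx <- 60; by <- 60
        ann_all <- rbind(ann_all, data.frame(
          seedling = sid, treatment = trt, session = sessions$session[s],
          rendered = FALSE,
          quadrant = rep(1:4, 3),
          theta_needle = th_needle,
          base_col = bx, base_row = by,
          tip_col = bx + side * len * cos(th_needle * pi / 180),
          tip_row = by - len * sin(th_needle * pi / 180)
        ))
      }
    }
  }
  rownames(gt) <- NULL

  ## ---- physiology table (daily; instrument values, never computed) ----
  set.seed(seed_pool[2L * n + 2L])
  physio_base <- list(
    Fm = c(3900, 1100), Fo = c(1000, 260), FvFm = c(0.74, 0.03),
    PhiII = c(0.69, 0.03), PhiNO = c(0.18, 0.02), PhiNPQ = c(0.13, 0.04),
    PSIact = c(2.0, 1.5), PSIopen = c(0.6, 0.7), qL = c(0.77, 0.07),
    SPAD = c(18, 9), EC = c(0.12, 0.01)
  )
  physio_shift <- list(   # drought response from the effect day on
    PhiNPQ = c(0.24, 0.04), FvFm = c(0.66, 0.05), PhiII = c(0.60, 0.06),
    PhiNO = c(0.16, 0.02)
  )
  days <- seq_len(config$n_days - 1L)
  physio <- expand.grid(seedling = seedlings$seedling, day = days,
                        stringsAsFactors = FALSE)
  physio$treatment <- seedlings$treatment[match(physio$seedling,
                                                seedlings$seedling)]
  for (v in names(physio_base)) {
    mu <- rep(physio_base[[v]][1], nrow(physio))
    sd <- rep(physio_base[[v]][2], nrow(physio))
    hit <- physio$treatment == "drought" & physio$day >= effect_from_day &
      v %in% names(physio_shift)
    if (any(hit)) {
      mu[hit] <- physio_shift[[v]][1]
      sd[hit] <- physio_shift[[v]][2]
    }
    physio[[v]] <- stats::rnorm(nrow(physio), mu, sd)
  }
  physio$SPAD <- pmax(physio$SPAD, 0.5)
  physio$EC <- pmax(physio$EC, 0.001)

  ## ---- frames + thermal maps ----
  scenes <- list()
  thermal_maps <- list()
  extents_all <- NULL
  if (render) {
    imaged <- seedlings[seedlings$imaged, ]
    n_frames <- config$n_imaged_per_treatment %/% 2L
    fi <- 0L
    for (s in seq_len(n_sessions)) {
      set.seed(seed_pool[2L * n + 2L + s])
      for (k in seq_len(n_frames)) {
        ctrl <- imaged$seedling[imaged$treatment == "control"][(2 * k - 1):(2 * k)]
        drou <- imaged$seedling[imaged$treatment == "drought"][(2 * k - 1):(2 * k)]
        members <- data.frame(
          roi = 1:4,
          seedling = c(ctrl[1], drou[1], ctrl[2], drou[2]),
          treatment = c("control", "drought", "control", "drought"),
          stringsAsFactors = FALSE
        )
        gt_rows <- gt[gt$session == sessions$session[s] &
                        gt$seedling %in% members$seedling, ]
        fr <- render_frame(config, sessions$session[s], k, members, geoms,
                           gt_rows, env$AT[s], env$AH[s])
        fi <- fi + 1L
        scenes[[fi]] <- fr$scene
        thermal_maps[[fi]] <- fr$thermal
        ann_all <- rbind(ann_all, fr$annotations)
        extents_all <- rbind(extents_all, fr$extents)
      }
    }
  }
  rownames(ann_all) <- NULL
  gt$canopy_height_px <- NA_real_
  gt$canopy_width_px <- NA_real_
  gt$n_truth_px <- NA_real_
  if (!is.null(extents_all)) {
    hit <- match(paste(gt$seedling, gt$session),
                 paste(extents_all$seedling, extents_all$session))
    gt$canopy_height_px <- extents_all$canopy_height_px[hit]
    gt$canopy_width_px <- extents_all$canopy_width_px[hit]
    gt$n_truth_px <- extents_all$n_truth_px[hit]
  }

  out <- list(config = config, sessions = sessions, env = env,
              physio = physio, ground_truth = gt, annotations = ann_all,
              seedlings = seedlings, scenes = scenes,
              thermal_maps = thermal_maps)
  class(out) <- "needle_experiment"
  out
}

#' @export
print.needle_experiment <- function(x, ...) {
  cat("<needle_experiment>\n")
  cat(sprintf("  %d seedlings/treatment over %d sessions; %d frames rendered\n",
              x$config$n_seedlings_per_treatment, nrow(x$sessions),
              length(x$scenes)))
  invisible(x)
}
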