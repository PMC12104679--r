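#' Earliest significant session of an adjusted p-value series
#'
#' @param p_adj Numeric vector of adjusted p values named by session label,
#'   in any order (sorted chronologically internally).
#' @param alpha Significance level; strict inequality (`p < alpha`), so a
#'   p value exactly at `alpha` does not count.
#' @return The earliest significant session label, or `NA_character_`.
#' @export
earliest_session <- function(p_adj, alpha = 0.05) {
  if (!length(p_adj)) return(NA_character_)
  info <- session_info(names(p_adj))
  ord <- order(info$index)
  hit <- which(!is.na(p_adj[ord]) & p_adj[ord] < alpha)
  if (!length(hit)) return(NA_character_) else names(p_adj)[ord][hit[1]]
}

## segment + measure one scene: colour-correct, mask, split, morphometrics
analyze_scene <- function(scene, thermal_map = NULL, min_component_px = 25) {
  img <- scene$image
  patches <- scene$chart$patches
  observed <- t(vapply(seq_len(nrow(patches)), function(p) {
    c(mean(img[patches$row1[p]:patches$row2[p],
               patches$col1[p]:patches$col2[p], 1]),
      mean(img[patches$row1[p]:patches$row2[p],
               patches$col1[p]:patches$col2[p], 2]),
      mean(img[patches$row1[p]:patches$row2[p],
               patches$col1[p]:patches$col2[p], 3]))
  }, numeric(3)))
  ct <- fit_color_correction(observed, scene$chart$reference)
  corrected <- apply_color_transform(img, ct)
  mask <- suppressWarnings(threshold_mask(corrected, "auto"))
  ## the chart strip contains green patches; drop it from the plant mask
  mask[1:min(nrow(mask), max(patches$row2) + 2L), ] <- FALSE
  mask <- clean_mask(mask, min_component_px = min_component_px,
                     fill_holes = TRUE)
  plant_masks <- suppressMessages(split_plants(mask, scene$rois))
  sinfo <- session_info(scene$session)
  rows <- lapply(seq_len(nrow(scene$rois)), function(k) {
    rec <- extract_morphometrics(plant_masks[[k]],
                                 seedling = scene$rois$seedling[k],
                                 day = sinfo$day, session = scene$session)
    rec$treatment <- scene$rois$treatment[k]
    rec$mask_px <- sum(plant_masks[[k]])
    rec$tl_img <- if (!is.null(thermal_map)) {
      tl_from_thermal(thermal_map, plant_masks[[k]])
    } else NA_real_
    rec
  })
  list(records = do.call(rbind, rows), masks = plant_masks,
       transform = ct, mask_all = mask)
}

## per-seedling, per-session theta from annotation endpoints
measure_angles <- function(annotations) {
  if (is.null(annotations) || !nrow(annotations)) return(NULL)
  key <- interaction(annotations$seedling, annotations$session, drop = TRUE)
  rows <- lapply(split(annotations, key), function(a) {
    th <- needle_angle(cbind(a$base_col, a$base_row),
                       cbind(a$tip_col, a$tip_row))
    obs <- quadrant_mean(th, a$quadrant)
    data.frame(seedling = a$seedling[1], treatment = a$treatment[1],
               session = a$session[1], theta = obs$theta,
               n_needles = obs$n_needles_measured,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## one two-group comparison following the sample-size rule:
## n <= 10 in either group -> Mann-Whitney, otherwise a pooled t test
detect_test <- function(ctrl, drou) {
  ctrl <- ctrl[!is.na(ctrl)]; drou <- drou[!is.na(drou)]
  if (length(ctrl) < 2 || length(drou) < 2) return(NULL)
  if (stats::var(ctrl) == 0 && stats::var(drou) == 0 &&
      ctrl[1] == drou[1]) {
    return(data.frame(test = "none", statistic = NA_real_, p_raw = 1,
                      n_control = length(ctrl), n_drought = length(drou),
                      direction = 0, stringsAsFactors = FALSE))
  }
  if (min(length(ctrl), length(drou)) <= 10) {
    ties <- anyDuplicated(c(ctrl, drou)) > 0
    exact <- !ties && (length(ctrl) + length(drou)) <= 100
    wt <- suppressWarnings(stats::wilcox.test(ctrl, drou, exact = exact,
                                              correct = !exact))
    data.frame(test = "mann-whitney", statistic = unname(wt$statistic),
               p_raw = wt$p.value, n_control = length(ctrl),
               n_drought = length(drou),
               direction = sign(mean(drou) - mean(ctrl)),
               stringsAsFactors = FALSE)
  } else {
    tt <- stats::t.test(ctrl, drou, var.equal = TRUE)
    data.frame(test = "t", statistic = unname(tt$statistic),
               p_raw = tt$p.value, n_control = length(ctrl),
               n_drought = length(drou),
               direction = sign(mean(drou) - mean(ctrl)),
               stringsAsFactors = FALSE)
  }
}

MORPHO_FEATURES <- c("area_px", "longest_path_px", "width_px", "height_px",
                     "hull_area_px2", "solidity", "perimeter_px", "com_x",
                     "com_y", "hull_vertices", "ellipse_x", "ellipse_y")
PHYSIO_VARS <- c("Fm", "Fo", "FvFm", "PhiII", "PhiNO", "PhiNPQ", "PSIact",
                 "PSIopen", "qL", "SPAD", "EC")
THERMAL_VARS <- c("tl", "vpd", "cwsi_tl", "cwsi_tlta", "ltd")

#' Run the full analysis pipeline and detection report
#'
#' Orchestrates segmentation, morphometrics, needle-angle measurement,
#' thermal indices and the per-session statistical battery over a
#' (synthetic or pre-simulated) experiment, then reports for every
#' parameter the earliest session at which the drought and control groups
#' diverge.
#'
#' Parameter families and units of comparison:
#' \describe{
#'   \item{angle}{BD-M, PM-M, PM-M(ST) per seedling from quadrant-averaged
#'     theta; a session enters the battery only while at least
#'     `min_angle_values` individual drought needle measurements remain.}
#'   \item{morpho}{baseline-minus-current differences of the 11
#'     seedling-level features measured from the rendered frames.}
#'   \item{physio}{instrument covariates per day.}
#'   \item{thermal}{leaf temperature, VPD, both CWSI variants and LTD per
#'     session.}
#' }
#' Tests follow the sample-size rule (groups of n <= 10 use Mann-Whitney,
#' larger groups a pooled t test) and a Bonferroni correction whose family
#' is every test in the report, so the report-wide type-I error is
#' controlled at `alpha` under a null scenario.
#'
#' @param x An [experiment_config()] or a ready [simulate_experiment()]
#'   result.
#' @param alpha Significance level (default 0.05).
#' @param min_angle_values Minimum drought needle-value count for a
#'   session to enter the angle battery (default 30).
#' @param min_component_px Mask cleanup threshold (default 25).
#' @return Object of class `detection_report`: `tests` (one row per
#'   parameter x session), `earliest` (per parameter), `ranking`, `m`,
#'   `alpha`, plus the intermediate tables (`morpho`, `angles`, `thermal`,
#'   `physio`, `anova`).
#' @export
run_pipeline <- function(x, alpha = 0.05, min_angle_values = 30,
                         min_component_px = 25) {
  exp <- if (inherits(x, "experiment_config")) simulate_experiment(x) else x
  stopifnot(inherits(exp, "needle_experiment"))
  sessions <- exp$sessions
  after_bd <- sessions$session[sessions$index > 0]

  ## ---- image route: morphometrics + image-based leaf temperature ----
  morpho_tab <- NULL
  for (i in seq_along(exp$scenes)) {
    an <- analyze_scene(exp$scenes[[i]],
                        thermal_map = if (length(exp$thermal_maps) >= i)
                          exp$thermal_maps[[i]] else NULL,
                        min_component_px = min_component_px)
    morpho_tab <- rbind(morpho_tab, an$records)
  }

  ## ---- angle route ----
  angles_tab <- measure_angles(exp$annotations)
  angle_params <- NULL
  if (!is.null(angles_tab)) {
    full <- expand.grid(seedling = unique(exp$seedlings$seedling),
                        session = sessions$session,
                        stringsAsFactors = FALSE)
    full$theta <- angles_tab$theta[match(paste(full$seedling, full$session),
                                         paste(angles_tab$seedling,
                                               angles_tab$session))]
    angle_params <- do.call(rbind, lapply(split(full, full$seedling),
                                          function(d) {
      out <- derive_angle_parameters(d$session, d$theta)
      out$seedling <- d$seedling[1]
      out
    }))
    angle_params$treatment <- exp$seedlings$treatment[
      match(angle_params$seedling, exp$seedlings$seedling)]
    rownames(angle_params) <- NULL
  }

  ## ---- thermal route: image Tl where available, instrument Tl else ----
  gt <- exp$ground_truth
  thermal_tab <- NULL
  for (s in sessions$session) {
    g <- gt[gt$session == s, ]
    tl <- g$tl_true
    if (!is.null(morpho_tab)) {
      mt <- morpho_tab[morpho_tab$session == s, ]
      hit <- match(g$seedling, mt$seedling)
      use <- !is.na(hit) & !is.na(mt$tl_img[hit])
      tl[use] <- mt$tl_img[hit[use]]
    }
    env_row <- exp$env[exp$env$session == s, ]
    thermal_tab <- rbind(thermal_tab, thermal_observations(
      g$seedling, g$treatment, tl, env_row$AT, env_row$AH, s))
  }

  ## ---- assemble the battery ----
  tests <- NULL
  add_test <- function(family, parameter, session, ctrl, drou) {
    tt <- detect_test(ctrl, drou)
    if (is.null(tt)) return(NULL)
    cbind(data.frame(family = family, parameter = parameter,
                     session = session, stringsAsFactors = FALSE), tt)
  }
  if (!is.null(angle_params)) {
    ang_d <- angles_tab[angles_tab$treatment == "drought", ]
    needle_counts <- tapply(ang_d$n_needles, ang_d$session, sum)
    for (p in c("bd_m", "pm_m", "pm_m_st")) {
      for (s in after_bd) {
        nv <- needle_counts[s]
        if (is.na(nv) || nv < min_angle_values) next
        d <- angle_params[angle_params$session == s, ]
        tests <- rbind(tests, add_test(
          "angle", p, s,
          d[[p]][d$treatment == "control"],
          d[[p]][d$treatment == "drought"]))
      }
    }
  }
  if (!is.null(morpho_tab)) {
    bd <- morpho_tab[morpho_tab$session == "BD", ]
    for (p in MORPHO_FEATURES) {
      for (s in after_bd) {
        cur <- morpho_tab[morpho_tab$session == s & !morpho_tab$undefined, ]
        if (!nrow(cur)) next
        ref <- bd[match(cur$seedling, bd$seedling), ]
        diffv <- ref[[p]] - cur[[p]]     # before minus current
        tests <- rbind(tests, add_test(
          "morpho", p, s,
          diffv[cur$treatment == "control"],
          diffv[cur$treatment == "drought"]))
      }
    }
  }
  for (p in PHYSIO_VARS) {
    for (d in sort(unique(exp$physio$day))) {
      cur <- exp$physio[exp$physio$day == d, ]
      tests <- rbind(tests, add_test(
        "physio", p, sprintf("D%dM", d),
        cur[[p]][cur$treatment == "control"],
        cur[[p]][cur$treatment == "drought"]))
    }
  }
  for (p in THERMAL_VARS) {
    for (s in after_bd) {
      cur <- thermal_tab[thermal_tab$session == s, ]
      tests <- rbind(tests, add_test(
        "thermal", p, s,
        cur[[p]][cur$treatment == "control"],
        cur[[p]][cur$treatment == "drought"]))
    }
  }

  m <- nrow(tests)
  tests$p_adj <- pmin(1, m * tests$p_raw)
  tests$significant <- tests$p_adj < alpha

  earliest <- do.call(rbind, lapply(
    split(tests, paste(tests$family, tests$parameter)), function(d) {
      es <- earliest_session(stats::setNames(d$p_adj, d$session), alpha)
      data.frame(family = d$family[1], parameter = d$parameter[1],
                 earliest_session = es,
                 direction = if (!is.na(es))
                   d$direction[d$session == es] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(earliest) <- NULL
  idx <- session_info(sessions$session)
  earliest$earliest_index <- idx$index[match(earliest$earliest_session,
                                             idx$session)]
  ranking <- earliest[order(earliest$earliest_index), ]
  ranking <- ranking[!is.na(ranking$earliest_session), ]

  ## ---- supporting repeated-measures ANOVAs on complete windows ----
  anova_out <- list()
  if (!is.null(angle_params) && !is.na(exp$config$wilt_onset_session)) {
    win <- angle_params[angle_params$session %in%
                          c("D1M", "D1E", "D2M", "D2E") &
                          !is.na(angle_params$bd_m), ]
    si <- session_info(win$session)
    win$day <- paste0("D", si$day)
    win$time <- si$time
    complete <- names(which(table(win$seedling) == 4))
    win <- win[win$seedling %in% complete, ]
    anova_out$bd_m_3way <- tryCatch(
      rm_anova(win, "bd_m", between = "treatment",
               within = c("day", "time"), subject = "seedling"),
      error = function(e) e$message)
  }
  ph <- exp$physio
  ph$day_f <- paste0("D", ph$day)
  anova_out$phinpq_2way <- tryCatch(
    rm_anova(ph, "PhiNPQ", between = "treatment", within = "day_f",
             subject = "seedling"),
    error = function(e) e$message)

  out <- list(tests = tests, earliest = earliest, ranking = ranking,
              m = m, alpha = alpha, morpho = morpho_tab,
              angles = angle_params, thermal = thermal_tab,
              physio = exp$physio, anova = anova_out,
              config = exp$config)
  class(out) <- "detection_report"
  out
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  cat(sprintf("  %d tests, Bonferroni family m = %d, alpha = %.3f\n",
              nrow(x$tests), x$m, x$alpha))
  flagged <- x$ranking
  if (nrow(flagged)) {
    cat("  earliest significant sessions:\n")
    for (i in seq_len(min(nrow(flagged), 20))) {
      cat(sprintf("    %-8s %-16s %s (direction %+d)\n",
                  flagged$family[i], flagged$parameter[i],
                  flagged$earliest_session[i], flagged$direction[i]))
    }
  } else {
    cat("  no parameter significant at alpha\n")
  }
  invisible(x)
}
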