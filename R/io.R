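## Plain-text netpbm (PPM/PGM) is used for image artifacts because it
## round-trips losslessly, needs no external image libraries, and stays
## human-inspectable. Thermal maps travel as CSV matrices.

#' Write an RGB image as ASCII PPM (P3)
#'
#' @param image Numeric/integer array `rows x cols x 3`, values 0--255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be rows x cols x 3",
                                        call. = FALSE)
  px <- matrix(as.integer(round(clamp(image, 0, 255))), d[1] * d[2], 3)
  ## raster order: row by row, R G B per pixel
  ord <- order(rep(seq_len(d[1]), d[2]))
  lines <- c("P3", paste(d[2], d[1]), "255",
             apply(px[ord, , drop = FALSE], 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII PPM/PGM image
#'
#' PPM (P3) yields a `rows x cols x 3` integer array; PGM (P2) a
#' `rows x cols` matrix. Images with a maxval above 255 are rescaled to
#' 8 bit with a warning.
#'
#' @param path File path.
#' @return Integer array or matrix.
#' @export
read_pnm <- function(path) {
  raw <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- raw[1]
  if (!magic %in% c("P2", "P3")) {
    stop("unsupported image format '", magic, "' (expect ASCII P2/P3)",
         call. = FALSE)
  }
  nums <- as.numeric(raw[-1])
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  px <- nums[-(1:3)]
  if (maxval > 255) {
    warning("maxval ", maxval, " > 255; rescaling to 8 bit")
    px <- px / maxval * 255
  }
  if (magic == "P3") {
    if (length(px) != w * h * 3) stop("truncated PPM payload", call. = FALSE)
    arr <- array(0L, dim = c(h, w, 3))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(as.integer(round(px[seq(ch, length(px), by = 3)])),
                            h, w, byrow = TRUE)
    }
    arr
  } else {
    if (length(px) != w * h) stop("truncated PGM payload", call. = FALSE)
    matrix(as.integer(round(px)), h, w, byrow = TRUE)
  }
}

#' Write a binary mask as ASCII PGM (P2, 0/255)
#'
#' @param mask Logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  mask_check(mask)
  vals <- ifelse(t(mask), 255L, 0L)
  lines <- c("P2", paste(ncol(mask), nrow(mask)), "255",
             apply(vals, 2, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 0/255 PGM mask
#'
#' @param path File path.
#' @return Logical matrix (any value > 127 is foreground).
#' @export
read_mask_pgm <- function(path) {
  m <- read_pnm(path)
  if (!is.matrix(m)) stop("expected a single-channel PGM mask", call. = FALSE)
  m > 127
}

#' Read a scene image with ROI specification
#'
#' @param path ASCII PPM path.
#' @param plant_rois Data frame with `row1`, `row2`, `col1`, `col2`
#'   (validated against the image bounds).
#' @param chart_region Optional single-row data frame for the chart strip;
#'   checked for overlap with the plant ROIs.
#' @return List with `image`, `plant_rois`, `chart_region`.
#' @export
read_scene <- function(path, plant_rois, chart_region = NULL) {
  img <- read_pnm(path)
  if (!(length(dim(img)) == 3 && dim(img)[3] == 3)) {
    stop("scene must be an RGB (P3) image, got single channel",
         call. = FALSE)
  }
  if (dim(img)[1] != dim(img)[2]) {
    warning("scene is not 1:1 aspect ratio (", dim(img)[1], " x ",
            dim(img)[2], ")")
  }
  check_roi <- function(r) {
    all(r$row1 >= 1, r$col1 >= 1, r$row2 <= dim(img)[1],
        r$col2 <= dim(img)[2], r$row1 <= r$row2, r$col1 <= r$col2)
  }
  if (!all(vapply(seq_len(nrow(plant_rois)),
                  function(i) check_roi(plant_rois[i, ]), logical(1)))) {
    stop("plant ROIs must lie within image bounds", call. = FALSE)
  }
  if (!is.null(chart_region)) {
    if (!check_roi(chart_region)) stop("chart region out of bounds",
                                       call. = FALSE)
    for (i in seq_len(nrow(plant_rois))) {
      r <- plant_rois[i, ]
      if (r$row1 <= chart_region$row2 && r$row2 >= chart_region$row1 &&
          r$col1 <= chart_region$col2 && r$col2 >= chart_region$col1) {
        stop("chart region overlaps plant ROI ", i, call. = FALSE)
      }
    }
  }
  list(image = img, plant_rois = plant_rois, chart_region = chart_region)
}

#' Write a thermal map as a CSV matrix
#'
#' @param thermal Numeric matrix (degC); `NA`/`NaN` cells written as `NA`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(thermal, path) {
  utils::write.table(thermal, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a thermal map CSV matrix
#'
#' @param path File path; comma-separated numeric rows, `NA`/`NaN`
#'   supported for dead pixels.
#' @return Numeric matrix (degC).
#' @export
read_thermal_csv <- function(path) {
  rows <- strsplit(readLines(path), ",")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop("ragged thermal CSV: row lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  suppress <- function(v, i) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !(trimws(v) %in% c("NA", "NaN", "nan", ""))
    if (any(bad)) {
      stop("non-numeric thermal cell at row ", i, ", column ",
           which(bad)[1], ": '", v[which(bad)[1]], "'", call. = FALSE)
    }
    out
  }
  do.call(rbind, lapply(seq_along(rows), function(i) suppress(rows[[i]], i)))
}

#' Validate environment and physiology tables
#'
#' Checks the schema (required columns), numeric types, and unit ranges
#' (air humidity within 0--100 %). All violations are collected and
#' reported together.
#'
#' @param env Environment series data frame (needs `session`, `AH`, `AT`,
#'   `SR`).
#' @param physio Physiology data frame (needs `seedling`, `treatment`,
#'   `day`); `require_vars` lists covariates that must be present.
#' @param require_vars Character vector of required physiology columns
#'   (default `"PhiNPQ"`).
#' @return Invisibly `list(env, physio)`; stops with the full violation
#'   list otherwise.
#' @export
validate_tables <- function(env, physio, require_vars = "PhiNPQ") {
  problems <- character(0)
  need_env <- c("session", "AH", "AT", "SR")
  miss <- setdiff(need_env, names(env))
  if (length(miss)) {
    problems <- c(problems, paste("env: missing column(s)",
                                  paste(miss, collapse = ", ")))
  }
  if ("AH" %in% names(env)) {
    bad <- which(!is.na(env$AH) & (env$AH < 0 | env$AH > 100))
    if (length(bad)) {
      problems <- c(problems, paste0("env: AH outside [0,100] at row(s) ",
                                     paste(utils::head(bad, 5),
                                           collapse = ", ")))
    }
  }
  for (v in intersect(c("AT", "SR"), names(env))) {
    if (!is.numeric(env[[v]])) {
      problems <- c(problems, paste0("env: ", v, " is not numeric"))
    }
  }
  need_phy <- c("seedling", "treatment", "day", require_vars)
  miss <- setdiff(need_phy, names(physio))
  if (length(miss)) {
    problems <- c(problems, paste("physio: missing column(s)",
                                  paste(miss, collapse = ", ")))
  }
  for (v in intersect(require_vars, names(physio))) {
    if (!is.numeric(physio[[v]])) {
      problems <- c(problems, paste0("physio: ", v, " is not numeric"))
    }
  }
  if (length(problems)) {
    stop("table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(list(env = env, physio = physio))
}

#' Write the tabular artifacts of an experiment and a run manifest
#'
#' Writes the environment, physiology, ground-truth and annotation tables
#' as CSV (UTF-8, comma separator, header row, `NA` token), the config
#' snapshot as a structured text file, and a JSON manifest with MD5
#' checksums, the seed, package version, and per-table row counts.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param out_dir Output directory (created if needed).
#' @param write_frames Also write every frame as PPM and thermal map as
#'   CSV (default `FALSE`; the image artifacts are bulky).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_experiment <- function(experiment, out_dir, write_frames = FALSE) {
  stopifnot(inherits(experiment, "needle_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(env = experiment$env, physio = experiment$physio,
               ground_truth = experiment$ground_truth,
               annotations = experiment$annotations,
               seedlings = experiment$seedlings)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, na = "NA")
    paths[nm] <- p
  }
  cfg <- experiment$config
  cfg_lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(format(cfg[[k]], digits = 12), collapse = ", "))
  }, character(1))
  p <- file.path(out_dir, "config.txt")
  writeLines(cfg_lines, p)
  paths["config"] <- p
  if (write_frames) {
    for (i in seq_along(experiment$scenes)) {
      sc <- experiment$scenes[[i]]
      p1 <- file.path(out_dir, sprintf("frame_%s_%d.ppm", sc$session,
                                       sc$frame))
      write_ppm(sc$image, p1)
      p2 <- file.path(out_dir, sprintf("thermal_%s_%d.csv", sc$session,
                                       sc$frame))
      write_thermal_csv(experiment$thermal_maps[[i]], p2)
      paths[paste0("frame_", i)] <- p1
      paths[paste0("thermal_", i)] <- p2
    }
  }
  manifest <- list(
    seed = cfg$rng_seed,
    version = as.character(utils::packageVersion("needledyn")),
    files = lapply(stats::setNames(names(paths), names(paths)), function(k) {
      list(path = basename(paths[[k]]),
           md5 = unname(tools::md5sum(paths[[k]])))
    }),
    rows = lapply(tabs, nrow)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
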