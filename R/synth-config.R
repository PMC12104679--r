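#' Configuration for a synthetic drought-stress experiment
#'
#' Collects every scenario constant used by [simulate_experiment()]. The
#' defaults encode the stated world the package is tested against: two
#' treatments (control irrigated daily, drought unirrigated from day 1),
#' a 7-day course with two capture sessions per day, evening apical wilting
#' of every drought seedling starting at `wilt_onset_session`, next-morning
#' recovery of a `recovery_fraction` of them, apical death 1--2 days after
#' first wilting, and a late (day-6) rise in regulated heat dissipation
#' (PhiNPQ) together with warmer-than-control needles.
#'
#' Greenhouse environment means/SDs default to the reference growing
#' conditions (air humidity 79.13 +/- 13.88 %, air temperature 30.46 +/-
#' 4.72 degC, solar radiation 194.32 +/- 233.92 W/m2, control soil moisture
#' 29.48 +/- 1.22 %, soil temperature 29.55 +/- 4.06 degC).
#'
#' @param n_seedlings_per_treatment Seedlings per treatment (default 30).
#' @param n_imaged_per_treatment Seedlings per treatment that appear in the
#'   rendered frames (default 10; frames hold 2 control + 2 drought plants).
#' @param n_days Experiment length in days including the baseline day
#'   (default 7: `BD` plus days 1--6).
#' @param baseline_angle_mean,baseline_angle_sd Per-seedling mean apical
#'   needle angle at baseline, degrees.
#' @param session_angle_sd Session-to-session fluctuation of a seedling's
#'   mean apical angle, degrees.
#' @param needle_angle_sd Needle-to-needle spread around the seedling's
#'   session mean, degrees.
#' @param wilt_onset_session Session at which drought seedlings first wilt
#'   (default `"D2E"`). `NA` disables wilting entirely (null scenario).
#' @param wilt_drop_mean,wilt_drop_sd Downward apical angle shift (degrees,
#'   positive = drop) drawn per seedling at wilting.
#' @param recovery_fraction Probability a wilted seedling recovers the next
#'   morning (default 0.7).
#' @param days_to_death_after_first_wilt Integer range (length 2) of days
#'   from first wilt to apical death.
#' @param discoloration_start Discoloration fraction of the apical region at
#'   the session apical death begins.
#' @param discoloration_rate Additional discoloration fraction per day after
#'   death begins.
#' @param apical_droop_px_mean,apical_droop_px_sd Pixels by which the apical
#'   stem tip sags while wilted (drives the centre-of-mass(y) and height
#'   signals).
#' @param env_means,env_sds Named numeric vectors (`AH`, `AT`, `SR`, `SM`,
#'   `ST`) of greenhouse environment means and SDs. `SM` is the control
#'   value; drought soil moisture declines linearly to `sm_drought_final`.
#' @param sm_drought_final Final drought soil-moisture mean, percent.
#' @param physio_effect_day Day label (e.g. `"D6"`) from which drought
#'   physiology (PhiNPQ up, Fv'/Fm' and PhiII down) and needle temperature
#'   depart from control. `NA` disables the effect.
#' @param tl_offset Baseline transpirational cooling: needle temperature is
#'   air temperature minus this many degC.
#' @param tl_shift_mean,tl_shift_sd Per-seedling needle-temperature rise
#'   (degC) in drought from `physio_effect_day` on.
#' @param tl_noise_sd Per-seedling, per-session noise on true needle
#'   temperature, degC.
#' @param thermal_pixel_sd Per-pixel noise of the rendered thermal map, degC.
#' @param frame_height,frame_width Rendered frame size in pixels.
#' @param rng_seed Integer seed; identical seed and config give bitwise
#'   identical outputs.
#' @return An object of class `experiment_config` (a validated list).
#' @seealso [simulate_experiment()], [angle_trajectory()]
#' @export
experiment_config <- function(n_seedlings_per_treatment = 30L,
                              n_imaged_per_treatment = 10L,
                              n_days = 7L,
                              baseline_angle_mean = 30,
                              baseline_angle_sd = 10,
                              session_angle_sd = 3,
                              needle_angle_sd = 2.5,
                              wilt_onset_session = "D2E",
                              wilt_drop_mean = 17,
                              wilt_drop_sd = 5,
                              recovery_fraction = 0.7,
                              days_to_death_after_first_wilt = c(1L, 2L),
                              discoloration_start = 0.7,
                              discoloration_rate = 0.3,
                              apical_droop_px_mean = 18,
                              apical_droop_px_sd = 4,
                              env_means = c(AH = 79.13, AT = 30.46,
                                            SR = 194.32, SM = 29.48,
                                            ST = 29.55),
                              env_sds = c(AH = 13.88, AT = 4.72,
                                          SR = 233.92, SM = 1.22,
                                          ST = 4.06),
                              sm_drought_final = 13.97,
                              physio_effect_day = "D6",
                              tl_offset = 2,
                              tl_shift_mean = 1.6,
                              tl_shift_sd = 0.5,
                              tl_noise_sd = 0.5,
                              thermal_pixel_sd = 0.2,
                              frame_height = 150L,
                              frame_width = 260L,
                              rng_seed = 1L) {
  cfg <- list(
    n_seedlings_per_treatment = as.integer(n_seedlings_per_treatment),
    n_imaged_per_treatment = as.integer(n_imaged_per_treatment),
    n_days = as.integer(n_days),
    baseline_angle_mean = baseline_angle_mean,
    baseline_angle_sd = baseline_angle_sd,
    session_angle_sd = session_angle_sd,
    needle_angle_sd = needle_angle_sd,
    wilt_onset_session = wilt_onset_session,
    wilt_drop_mean = wilt_drop_mean,
    wilt_drop_sd = wilt_drop_sd,
    recovery_fraction = recovery_fraction,
    days_to_death_after_first_wilt =
      as.integer(days_to_death_after_first_wilt),
    discoloration_start = discoloration_start,
    discoloration_rate = discoloration_rate,
    apical_droop_px_mean = apical_droop_px_mean,
    apical_droop_px_sd = apical_droop_px_sd,
    env_means = env_means,
    env_sds = env_sds,
    sm_drought_final = sm_drought_final,
    physio_effect_day = physio_effect_day,
    tl_offset = tl_offset,
    tl_shift_mean = tl_shift_mean,
    tl_shift_sd = tl_shift_sd,
    tl_noise_sd = tl_noise_sd,
    thermal_pixel_sd = thermal_pixel_sd,
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  err <- function(...) stop("invalid experiment config: ", ..., call. = FALSE)
  counts <- c(cfg$n_seedlings_per_treatment, cfg$n_imaged_per_treatment,
              cfg$n_days)
  if (any(is.na(counts)) || any(counts < 1)) err("counts must be positive")
  if (cfg$n_imaged_per_treatment > cfg$n_seedlings_per_treatment) {
    err("n_imaged_per_treatment exceeds n_seedlings_per_treatment")
  }
  sds <- c(cfg$baseline_angle_sd, cfg$session_angle_sd, cfg$needle_angle_sd,
           cfg$wilt_drop_sd, cfg$apical_droop_px_sd, cfg$tl_shift_sd,
           cfg$tl_noise_sd, cfg$thermal_pixel_sd, cfg$env_sds)
  if (any(is.na(sds)) || any(sds < 0)) err("all SDs must be >= 0")
  if (is.na(cfg$recovery_fraction) || cfg$recovery_fraction < 0 ||
      cfg$recovery_fraction > 1) {
    err("recovery_fraction must lie in [0, 1]")
  }
  labels <- session_labels(cfg$n_days)
  if (!is.na(cfg$wilt_onset_session)) {
    if (!cfg$wilt_onset_session %in% labels) {
      err("wilt_onset_session '", cfg$wilt_onset_session,
          "' is not a session of a ", cfg$n_days, "-day experiment")
    }
    if (session_info(cfg$wilt_onset_session)$time != "E") {
      err("wilt_onset_session must be an evening session")
    }
  }
  if (!is.na(cfg$physio_effect_day) &&
      !grepl("^D[0-9]+$", cfg$physio_effect_day)) {
    err("physio_effect_day must look like 'D6' (or NA)")
  }
  dd <- cfg$days_to_death_after_first_wilt
  if (length(dd) != 2L || any(is.na(dd)) || any(dd < 1) || dd[1] > dd[2]) {
    err("days_to_death_after_first_wilt must be an increasing pair >= 1")
  }
  need <- c("AH", "AT", "SR", "SM", "ST")
  if (!all(need %in% names(cfg$env_means)) ||
      !all(need %in% names(cfg$env_sds))) {
    err("env_means/env_sds must name AH, AT, SR, SM, ST")
  }
  if (is.na(cfg$rng_seed)) err("rng_seed must be an integer")
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  %d seedlings/treatment (%d imaged), %d days, seed %d\n",
              x$n_seedlings_per_treatment, x$n_imaged_per_treatment,
              x$n_days, x$rng_seed))
  cat(sprintf("  wilt onset %s, drop %.1f +/- %.1f deg, recovery %.0f%%\n",
              as.character(x$wilt_onset_session), x$wilt_drop_mean,
              x$wilt_drop_sd, 100 * x$recovery_fraction))
  cat(sprintf("  physiology/thermal effect from %s\n",
              as.character(x$physio_effect_day)))
  invisible(x)
}
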