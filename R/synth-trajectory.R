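#' Initial apical state of a seedling
#'
#' @param baseline_theta Seedling mean apical angle at baseline, degrees.
#' @return List of class `seedling_state` holding the vitality machine:
#'   `vitality` (`"alive"`, `"wilted"`, `"recovered"`, `"dead"`),
#'   `baseline`, latent wilt variables (drawn at first wilt), droop,
#'   discoloration fraction, and the last defined angle.
#' @export
seedling_state <- function(baseline_theta) {
  st <- list(vitality = "alive", baseline = baseline_theta,
             wilt_drop = NA_real_, recovers = NA, droop = 0,
             first_wilt_index = NA_integer_, death_index = NA_integer_,
             discoloration = 0, last_theta = baseline_theta)
  class(st) <- "seedling_state"
  st
}

#' One session step of the apical angle / vitality trajectory
#'
#' Advances a seedling's vitality state machine by one capture session and
#' samples its mean apical needle angle. Drought seedlings wilt at the
#' configured onset evening (angle shifted down by a per-seedling wilt
#' drop and the apical tip sagging); with probability `recovery_fraction`
#' they recover the following morning, resuming the evening-wilt /
#' morning-recovery cycle, and the apical part dies 1--2 days after the
#' first wilt (absorbing state, angle undefined, discoloration
#' accumulating). Control seedlings fluctuate around their baseline with
#' session noise only. Uses the current R random stream.
#'
#' @param treatment `"control"` or `"drought"`.
#' @param session Session label (e.g. `"D2E"`).
#' @param state A [seedling_state()] (carried between calls).
#' @param config An [experiment_config()].
#' @return List with `theta` (`NA` once dead) and the updated `state`.
#' @export
angle_trajectory <- function(treatment, session, state, config) {
  stopifnot(inherits(state, "seedling_state"),
            inherits(config, "experiment_config"))
  info <- session_info(session)
  onset_index <- if (is.na(config$wilt_onset_session)) NA_integer_ else
    session_info(config$wilt_onset_session)$index
  noise <- function() stats::rnorm(1, 0, config$session_angle_sd)

  if (state$vitality == "dead") {
    state$discoloration <- min(1, state$discoloration +
                                 config$discoloration_rate / 2)
    return(list(theta = NA_real_, state = state))
  }
  if (!is.na(state$death_index) && info$index >= state$death_index) {
    state$vitality <- "dead"
    state$discoloration <- config$discoloration_start
    return(list(theta = NA_real_, state = state))
  }

  theta <- state$baseline + noise()
  if (treatment == "drought" && !is.na(onset_index) &&
      info$index >= onset_index) {
    if (info$time == "E") {
      if (is.na(state$first_wilt_index)) {   # first wilt: draw latents
        state$first_wilt_index <- info$index
        state$wilt_drop <- stats::rnorm(1, config$wilt_drop_mean,
                                        config$wilt_drop_sd)
        state$recovers <- stats::runif(1) < config$recovery_fraction
        delay <- sample(seq(config$days_to_death_after_first_wilt[1],
                            config$days_to_death_after_first_wilt[2]), 1)
        state$death_index <- 2L * (info$day + delay)   # evening session
        state$droop <- max(0, stats::rnorm(1, config$apical_droop_px_mean,
                                           config$apical_droop_px_sd))
      }
      state$vitality <- "wilted"
      theta <- theta - state$wilt_drop
    } else {                                  # morning after a wilt
      if (state$vitality == "wilted" && isTRUE(state$recovers)) {
        state$vitality <- "recovered"
      } else if (state$vitality == "wilted") {
        theta <- theta - state$wilt_drop      # no recovery: stays down
      }
    }
  }
  theta <- clamp(theta, -90, 90)
  state$last_theta <- theta
  list(theta = theta, state = state)
}
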