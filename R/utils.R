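#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Session labels for an experiment
#'
#' Sessions run from the pre-drought baseline session `BD` through morning
#' (`M`) and evening (`E`) captures on each treatment day: `BD, D1M, D1E,
#' ..., D6M, D6E` for the default 7-day design. `BD` is treated as the
#' morning session of day 0.
#'
#' @param n_days Total number of experiment days including the baseline day
#'   (default 7, i.e. `BD` plus days 1--6).
#' @return Character vector of session labels in chronological order.
#' @export
#' @examples
#' session_labels(3) # "BD" "D1M" "D1E" "D2M" "D2E"
session_labels <- function(n_days = 7) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (n_days == 1) return("BD")
  days <- seq_len(n_days - 1)
  c("BD", as.vector(rbind(paste0("D", days, "M"), paste0("D", days, "E"))))
}

#' Decompose session labels into day and time-of-day
#'
#' @param sessions Character vector of session labels (`"BD"` or `"D<k>M"` /
#'   `"D<k>E"`).
#' @return Data frame with columns `session`, `day` (integer, 0 for `BD`),
#'   `time` (`"M"` or `"E"`; `BD` counts as `"M"`), and `index` (chronological
#'   rank: `2*day - 1 + (time == "E")`, with `BD` at 0).
#' @export
session_info <- function(sessions) {
  ok <- grepl("^(BD|D[0-9]+[ME])$", sessions)
  if (!all(ok)) {
    stop("invalid session label(s): ", paste(sessions[!ok], collapse = ", "),
         call. = FALSE)
  }
  day <- integer(length(sessions))
  bd <- sessions == "BD"
  day[!bd] <- as.integer(sub("^D([0-9]+)[ME]$", "\\1", sessions[!bd]))
  time <- ifelse(sessions == "BD", "M", substring(sessions, nchar(sessions)))
  index <- ifelse(sessions == "BD", 0L, 2L * day - 1L + (time == "E"))
  data.frame(session = sessions, day = day, time = time, index = index,
             stringsAsFactors = FALSE)
}

## seeded sub-stream helper: derive a reproducible integer seed per unit so
## per-seedling draws do not depend on rendering order
substream_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(base_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
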