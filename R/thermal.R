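#' Saturation (leaf) vapour pressure, Tetens form
#'
#' `lvp(Tl) = 0.61078 * exp(17.27 * Tl / (Tl + 237.3))` in kPa, with leaf
#' temperature `Tl` in degrees Celsius. Strictly increasing in `Tl`;
#' `lvp(0) = 0.61078` exactly.
#'
#' @param tl Leaf temperature, degC (must exceed -237.3).
#' @return Leaf vapour pressure, kPa.
#' @export
#' @examples
#' lvp(0)   # 0.61078
#' lvp(25)  # about 3.168
lvp <- function(tl) {
  if (any(!is.na(tl) & tl <= -237.3)) {
    stop("leaf temperature must exceed -237.3 degC", call. = FALSE)
  }
  0.61078 * exp(17.27 * tl / (tl + 237.3))
}

#' Actual air vapour pressure
#'
#' Saturation vapour pressure at air temperature `Ta` (Tetens form, as in
#' [lvp()]) scaled by relative humidity: `avp = lvp(Ta) * AH / 100`.
#'
#' @param ta Air temperature, degC.
#' @param ah Relative air humidity, percent in `[0, 100]`.
#' @return Air vapour pressure, kPa.
#' @export
avp <- function(ta, ah) {
  if (any(!is.na(ah) & (ah < 0 | ah > 100))) {
    stop("air humidity must lie in [0, 100] percent", call. = FALSE)
  }
  lvp(ta) * ah / 100
}

#' Vapour pressure deficit
#'
#' `VPD = LVP - AVP` (kPa): saturation vapour pressure at leaf temperature
#' minus actual air vapour pressure. May be negative when the leaf is
#' cooler than the dew-adjusted air.
#'
#' @inheritParams lvp
#' @inheritParams avp
#' @return VPD, kPa.
#' @export
vpd <- function(tl, ta, ah) lvp(tl) - avp(ta, ah)

#' Wet/dry reference temperatures for a capture session
#'
#' The crop-water-stress-index anchors are the componentwise minimum and
#' maximum of the leaf and air temperatures pooled over the session (both
#' treatments share the anchors by default; pass pre-filtered vectors for
#' a narrower scope).
#'
#' @param tl_all Leaf temperatures observed in the session, degC (>= 2
#'   values spanning a nonzero range).
#' @param ta_all Air temperatures observed in the session, degC.
#' @param scope Free-text provenance recorded in the result (default
#'   `"session-pooled"`).
#' @return List of class `session_references` with `tlw`, `tld`, `taw`,
#'   `tad`, `scope`.
#' @export
session_references <- function(tl_all, ta_all, scope = "session-pooled") {
  tl_all <- tl_all[!is.na(tl_all)]
  ta_all <- ta_all[!is.na(ta_all)]
  if (length(tl_all) < 2) {
    stop("need >= 2 leaf temperature observations per session", call. = FALSE)
  }
  refs <- list(tlw = min(tl_all), tld = max(tl_all),
               taw = if (length(ta_all)) min(ta_all) else NA_real_,
               tad = if (length(ta_all)) max(ta_all) else NA_real_,
               scope = scope)
  if (refs$tld == refs$tlw) {
    stop("degenerate references: all leaf temperatures equal (", refs$tlw,
         " degC); CWSI undefined", call. = FALSE)
  }
  class(refs) <- "session_references"
  refs
}

#' Crop water stress index, leaf-temperature form
#'
#' `CWSI(Tl) = (Tl - Tlw) / (Tld - Tlw)`, where `Tlw`/`Tld` are the
#' session's minimum and maximum leaf temperatures. 0 at the wet anchor,
#' 1 at the dry anchor, affine in `Tl`.
#'
#' @param tl Leaf temperature, degC.
#' @param refs A [session_references()] object.
#' @return Dimensionless index (within `[0, 1]` for `tl` inside the
#'   reference range).
#' @export
cwsi_tl <- function(tl, refs) {
  stopifnot(inherits(refs, "session_references"))
  denom <- refs$tld - refs$tlw
  if (!is.finite(denom) || denom == 0) {
    warning("CWSI(Tl) undefined: zero leaf-temperature range")
    return(rep(NA_real_, length(tl)))
  }
  (tl - refs$tlw) / denom
}

#' Crop water stress index, leaf-minus-air form
#'
#' `CWSI(Tl - Ta) = ((Tl - Ta) - (Tlw - Taw)) / ((Tld - Tad) - (Tlw - Taw))`.
#'
#' @param tl Leaf temperature, degC.
#' @param ta Air temperature, degC.
#' @inheritParams cwsi_tl
#' @return Dimensionless index.
#' @export
cwsi_tlta <- function(tl, ta, refs) {
  stopifnot(inherits(refs, "session_references"))
  lower <- refs$tlw - refs$taw
  denom <- (refs$tld - refs$tad) - lower
  if (!is.finite(denom) || denom == 0) {
    warning("CWSI(Tl-Ta) undefined: zero reference span")
    return(rep(NA_real_, length(tl)))
  }
  ((tl - ta) - lower) / denom
}

#' Leaf temperature difference
#'
#' `LTD = mean(control Tl) - Tl_i`, computed for every seedling in the
#' session (control seedlings included, so the control-group LTD averages
#' to exactly zero). Negative values indicate foliage warmer than the
#' control mean, i.e. reduced transpirational cooling under stress.
#'
#' @param control_tl Leaf temperatures of the control group in the session.
#' @param tl Leaf temperature(s) for which to compute LTD.
#' @return LTD in degC, same length as `tl`.
#' @export
ltd <- function(control_tl, tl) {
  control_tl <- control_tl[!is.na(control_tl)]
  if (!length(control_tl)) {
    stop("no control leaf-temperature observations in session", call. = FALSE)
  }
  mean(control_tl) - tl
}

#' Mean leaf temperature under a labelled region
#'
#' Per-seedling leaf temperature is the mean of the thermal-map pixels
#' under the seedling's mask; `NaN`/`NA` map pixels (dead sensor cells)
#' are excluded.
#'
#' @param thermal Numeric matrix of temperatures, degC.
#' @param mask Logical matrix of the same dimensions.
#' @return Mean temperature (degC), or `NA` for an empty mask.
#' @export
tl_from_thermal <- function(thermal, mask) {
  if (!all(dim(thermal) == dim(mask))) {
    stop("thermal map and mask dimensions differ", call. = FALSE)
  }
  px <- thermal[mask]
  px <- px[is.finite(px)]
  if (!length(px)) return(NA_real_)
  mean(px)
}

#' Thermal observation table for a session
#'
#' Assembles per-seedling VPD, both CWSI variants, and LTD from leaf
#' temperatures, a session air temperature, and humidity.
#'
#' @param seedling Seedling identifiers.
#' @param treatment Treatment labels (`"control"` / `"drought"`).
#' @param tl Leaf temperatures, degC.
#' @param ta Session air temperature, degC (scalar or per seedling).
#' @param ah Session air humidity, percent (scalar or per seedling).
#' @param session Session label.
#' @return Data frame with per-seedling `lvp`, `avp`, `vpd`, `cwsi_tl`,
#'   `cwsi_tlta`, `ltd` plus the reference scope used.
#' @export
thermal_observations <- function(seedling, treatment, tl, ta, ah, session) {
  n <- length(tl)
  ta <- rep_len(ta, n)
  ah <- rep_len(ah, n)
  refs <- session_references(tl, ta)
  data.frame(
    seedling = seedling,
    treatment = treatment,
    session = session,
    tl = tl, ta = ta, ah = ah,
    lvp = lvp(tl),
    avp = avp(ta, ah),
    vpd = vpd(tl, ta, ah),
    cwsi_tl = cwsi_tl(tl, refs),
    cwsi_tlta = cwsi_tlta(tl, ta, refs),
    ltd = ltd(tl[treatment == "control"], tl),
    ref_scope = refs$scope,
    stringsAsFactors = FALSE
  )
}
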