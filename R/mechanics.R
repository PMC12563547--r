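# Derived respiratory mechanics from static hold-maneuver readings, and the
# hourly expiratory-transpulmonary-pressure (TPP_exp) targeted PEEP titration.

#' Derived respiratory mechanics from hold-maneuver readings
#'
#' Computes the derived quantities used to characterise ventilation from one
#' or more static hold-maneuver measurement sets: driving pressure, end-
#' expiratory and end-inspiratory transpulmonary pressure, transpulmonary
#' driving pressure, mechanical power, and a quasi-static respiratory-system
#' compliance estimate.
#'
#' All pressures are in cmH2O, tidal volume in mL (converted to litres only
#' inside the mechanical-power formula), respiratory rate in breaths/min.
#' The definitions are:
#' \itemize{
#'   \item driving pressure: `delta_p = p_plat - peep`
#'   \item end-expiratory transpulmonary pressure: `tpp_exp = peep - p_es_exp`
#'   \item end-inspiratory transpulmonary pressure: `tpp_insp = p_plat - p_es_insp`
#'   \item transpulmonary driving pressure: `delta_p_l = tpp_insp - tpp_exp`
#'   \item mechanical power (J/min):
#'     `0.098 * resp_rate * (tidal_volume_ml/1000) * (p_peak - 0.5 * (p_plat - peep))`
#'   \item quasi-static compliance (mL/cmH2O): `tidal_volume_ml / delta_p`,
#'     `NA` (undefined) when `delta_p == 0`.
#' }
#' The quasi-static compliance is an analysis-side estimate and is distinct
#' from any ventilator-reported compliance, which should be carried as a
#' pass-through column and never conflated with it.
#'
#' @param p_peak peak inspiratory pressure, cmH2O.
#' @param p_plat plateau pressure, cmH2O.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param p_es_insp inspiratory esophageal pressure, cmH2O.
#' @param p_es_exp expiratory esophageal pressure, cmH2O.
#' @param tidal_volume_ml tidal volume, mL.
#' @param resp_rate respiratory rate, breaths/min.
#' @param fio2 optional inspired oxygen fraction, validated to [0.21, 1].
#' @return A `data.frame` with columns `delta_p`, `tpp_exp`, `tpp_insp`,
#'   `delta_p_l`, `mech_power_j_min`, `crs_quasistatic`.
#' @examples
#' derive_mechanics(p_peak = 30.3, p_plat = 17.5, peep = 5.0,
#'                  p_es_insp = 13.3, p_es_exp = 7.6,
#'                  tidal_volume_ml = 310, resp_rate = 25.3)
#' @export
derive_mechanics <- function(p_peak, p_plat, peep, p_es_insp, p_es_exp,
                             tidal_volume_ml, resp_rate, fio2 = NULL) {
  check_numeric(p_peak, "p_peak")
  check_numeric(p_plat, "p_plat")
  check_numeric(peep, "peep")
  check_numeric(p_es_insp, "p_es_insp")
  check_numeric(p_es_exp, "p_es_exp")
  check_numeric(tidal_volume_ml, "tidal_volume_ml")
  check_numeric(resp_rate, "resp_rate")
  check_that(p_peak >= p_plat, "p_plat", "exceeds p_peak")
  check_that(p_plat >= peep, "peep", "exceeds p_plat")
  check_that(peep >= 0, "peep", "must be non-negative")
  check_that(tidal_volume_ml > 0, "tidal_volume_ml", "must be positive")
  check_that(resp_rate > 0, "resp_rate", "must be positive")
  if (!is.null(fio2)) {
    check_numeric(fio2, "fio2")
    check_that(fio2 >= 0.21 & fio2 <= 1, "fio2", "must lie in [0.21, 1]")
  }

  delta_p  <- p_plat - peep
  tpp_exp  <- peep - p_es_exp
  tpp_insp <- p_plat - p_es_insp
  delta_p_l <- tpp_insp - tpp_exp
  mech_power <- 0.098 * resp_rate * (tidal_volume_ml / 1000) *
    (p_peak - 0.5 * (p_plat - peep))
  crs <- ifelse(delta_p > 0, tidal_volume_ml / delta_p, NA_real_)

  data.frame(delta_p = delta_p, tpp_exp = tpp_exp, tpp_insp = tpp_insp,
             delta_p_l = delta_p_l, mech_power_j_min = mech_power,
             crs_quasistatic = crs)
}

#' Append derived mechanics to a readings table
#'
#' Takes a tidy table with one row per animal and timepoint (columns
#' `p_peak`, `p_plat`, `peep`, `p_es_insp`, `p_es_exp`, `tidal_volume_ml`,
#' `resp_rate`, plus any identifier and pass-through columns) and appends the
#' derived columns computed by [derive_mechanics()].
#'
#' @param readings a `data.frame` of hold-maneuver readings.
#' @return The input with appended columns `delta_p`, `tpp_exp`, `tpp_insp`,
#'   `delta_p_l`, `mech_power_j_min`, `crs_quasistatic`.
#' @export
derive_mechanics_table <- function(readings) {
  req <- c("p_peak", "p_plat", "peep", "p_es_insp", "p_es_exp",
           "tidal_volume_ml", "resp_rate")
  check_columns(readings, req, "derive_mechanics_table")
  fio2 <- if ("fio2" %in% names(readings)) readings$fio2 else NULL
  derived <- derive_mechanics(readings$p_peak, readings$p_plat, readings$peep,
                              readings$p_es_insp, readings$p_es_exp,
                              readings$tidal_volume_ml, readings$resp_rate,
                              fio2 = fio2)
  cbind(readings, derived)
}

#' PEEP titration policy targeting end-expiratory transpulmonary pressure
#'
#' The titration arm of the study adjusted PEEP hourly to keep the
#' end-expiratory transpulmonary pressure (TPP_exp = PEEP minus expiratory
#' esophageal pressure) inside a slightly positive band, by default
#' `[0, 3]` cmH2O.
#'
#' @param target_low,target_high band for TPP_exp, cmH2O.
#' @param peep_min,peep_max admissible PEEP range, cmH2O.
#' @param rounding_step granularity of the ventilator PEEP setting, cmH2O.
#' @return An object of class `titration_policy`.
#' @export
titration_policy <- function(target_low = 0, target_high = 3,
                             peep_min = 4, peep_max = 24,
                             rounding_step = 1) {
  check_numeric(target_low, "target_low"); check_numeric(target_high, "target_high")
  check_numeric(peep_min, "peep_min"); check_numeric(peep_max, "peep_max")
  check_numeric(rounding_step, "rounding_step")
  check_that(target_low < target_high, "target_low", "must be below target_high")
  check_that(peep_min < peep_max, "peep_min", "must be below peep_max")
  check_that(rounding_step > 0, "rounding_step", "must be positive")
  structure(list(target_low = target_low, target_high = target_high,
                 peep_min = peep_min, peep_max = peep_max,
                 rounding_step = rounding_step),
            class = "titration_policy")
}

#' Apply the TPP_exp-targeted PEEP titration rule once
#'
#' If the current TPP_exp (`current_peep - p_es_exp`) already lies inside the
#' policy band, PEEP is left unchanged. Otherwise PEEP is set directly to
#' `p_es_exp` plus the band midpoint, rounded to the nearest ventilator step
#' (ties away from zero) and clamped to the admissible range. The one-shot
#' set rule is the simplest policy consistent with hourly titration to a
#' band.
#'
#' @param current_peep current PEEP, cmH2O.
#' @param p_es_exp current expiratory esophageal pressure, cmH2O.
#' @param policy a [titration_policy()].
#' @return The new PEEP setting, cmH2O.
#' @examples
#' titrate_peep(5, 7.6)    # TPP_exp = -2.6, out of band -> PEEP raised to 9
#' titrate_peep(10.8, 9.6) # TPP_exp = 1.2, in band -> unchanged
#' @export
titrate_peep <- function(current_peep, p_es_exp, policy = titration_policy()) {
  stopifnot(inherits(policy, "titration_policy"))
  check_numeric(current_peep, "current_peep")
  check_numeric(p_es_exp, "p_es_exp")
  check_that(current_peep >= policy$peep_min & current_peep <= policy$peep_max,
             "current_peep", "outside [peep_min, peep_max]")
  tpp <- current_peep - p_es_exp
  in_band <- tpp >= policy$target_low & tpp <= policy$target_high
  mid <- (policy$target_low + policy$target_high) / 2
  proposed <- round_step(p_es_exp + mid, policy$rounding_step)
  proposed <- pmin(pmax(proposed, policy$peep_min), policy$peep_max)
  ifelse(in_band, current_peep, proposed)
}

#' Run the hourly titration rule against an esophageal response model
#'
#' Iterates [titrate_peep()] over a series of steps. At each step the
#' esophageal pressure is observed from the response model at the currently
#' applied PEEP, the resulting TPP_exp is recorded, and the rule proposes the
#' PEEP for the next step. The response contract maps applied PEEP to the
#' next observed expiratory esophageal pressure; it may be a constant or a
#' function such as `linear_es_response()`.
#'
#' @param response either a single numeric (constant `p_es_exp`) or a
#'   function of one argument mapping applied PEEP (cmH2O) to `p_es_exp`.
#' @param start_peep PEEP applied at the first step, cmH2O.
#' @param n_steps number of hourly steps to simulate.
#' @param policy a [titration_policy()].
#' @return A `data.frame` with one row per step: `step`, `peep` (applied),
#'   `p_es_exp` (observed), `tpp_exp`, `peep_next`.
#' @export
run_titration_series <- function(response, start_peep, n_steps = 6,
                                 policy = titration_policy()) {
  stopifnot(n_steps >= 1)
  if (is.numeric(response) && length(response) == 1) {
    const <- response
    response <- function(peep) const
  }
  stopifnot(is.function(response))
  peep <- start_peep
  out <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    pes <- response(peep)
    if (!is.finite(pes)) {
      stop("esophageal response returned a non-finite value", call. = FALSE)
    }
    nxt <- titrate_peep(peep, pes, policy)
    out[[k]] <- data.frame(step = k, peep = peep, p_es_exp = pes,
                           tpp_exp = peep - pes, peep_next = nxt)
    peep <- nxt
  }
  do.call(rbind, out)
}

#' Linear chest-wall response model
#'
#' Returns a function mapping applied PEEP to the expiratory esophageal
#' pressure under a linear chest-wall response
#' `p_es_exp = intercept + slope * peep`. Slopes below 1 guarantee that the
#' titration rule has a stable fixed point.
#'
#' @param intercept,slope response coefficients (cmH2O; dimensionless slope).
#' @return A function of one argument (`peep`).
#' @export
linear_es_response <- function(intercept, slope) {
  force(intercept); force(slope)
  function(peep) intercept + slope * peep
}
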