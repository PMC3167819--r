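#' Exogenous Dkk1 dosing schedule
#'
#' Exogenous Dkk1 is a well-mixed bath concentration applied as a step
#' function of time (no pharmacokinetics). Under the `"continuous"` and
#' `"refreshed"` regimens the concentration is held for the whole `duration`
#' (refreshing the medium keeps the step up); under `"single"` a single
#' addition is assumed to persist for `pulse` hours and is then gone.
#'
#' @param concentration Dose in ng/mL (>= 0).
#' @param start Treatment start time (h).
#' @param duration Treatment duration (h); default 48.
#' @param regimen One of `"continuous"`, `"single"`, `"refreshed"`.
#' @param pulse Effective persistence of a single addition (h); only used by
#'   the `"single"` regimen.
#' @return A list of class `dose_schedule`.
#' @export
dose_schedule <- function(concentration, start = 0, duration = 48,
                          regimen = c("continuous", "single", "refreshed"),
                          pulse = 24) {
  regimen <- match.arg(regimen)
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            concentration >= 0, is.finite(concentration),
            start >= 0, duration > 0, pulse > 0)
  structure(list(concentration = concentration, start = start,
                 duration = duration, regimen = regimen, pulse = pulse),
            class = "dose_schedule")
}

#' Exogenous Dkk1 concentration at a time point
#'
#' Step-function exposure: the scheduled concentration while `t` lies in the
#' half-open treatment window, zero outside it.
#'
#' @param t Time (h, >= 0); vectorized.
#' @param schedule A [dose_schedule()].
#' @return Concentration in ng/mL.
#' @export
exogenous_dkk <- function(t, schedule) {
  stopifnot(inherits(schedule, "dose_schedule"), all(t >= 0))
  window <- if (schedule$regimen == "single") {
    min(schedule$pulse, schedule$duration)
  } else {
    schedule$duration
  }
  on <- t >= schedule$start & t < schedule$start + window
  ifelse(on, schedule$concentration, 0)
}

#' Total Dkk1 in the close environment of a stem cell
#'
#' The Dkk1 input to the Wnt inhibition gate, in ng/mL equivalents: the
#' global exogenous bath concentration at time `t` plus the secreted
#' contribution of the cell itself and of its stem-cell neighbors
#' (differentiated cells do not secrete), converted from model units with
#' `ng_per_model_unit`.
#'
#' @param lattice An [hex_lattice()].
#' @param site_index Index of a site holding a stem cell.
#' @param calib A [unit_calibration()] (or anything with
#'   `ng_per_model_unit`).
#' @param schedule A [dose_schedule()].
#' @param t Time (h).
#' @return Local Dkk1 level in ng/mL equivalents.
#' @export
dkk_environment <- function(lattice, site_index, calib, schedule, t) {
  check_site(lattice, site_index)
  if (lattice$status[site_index] != 1L) stop("site does not hold a stem cell")
  nb <- lattice$nb[site_index, ]
  stem_nb <- nb[lattice$status[nb] == 1L]
  secreted <- lattice$state[site_index, "dkk_produced"] +
    sum(lattice$state[stem_nb, "dkk_produced"])
  unname(exogenous_dkk(t, schedule) + calib$ng_per_model_unit * secreted)
}

#' Oncogenic mutation scenario
#'
#' Multiplicative defects on the three modeled lesions: `mu_notch` increases
#' the Notch receptor synthesis rate, `mu_wnt` increases the ambient Wnt
#' ligand level, and `mu_ecad` increases the amount of bound E-cadherin
#' required to inhibit LEF/TCF activation (the half-saturation of the
#' inhibition gate). Fractions are expected in `[0, 0.2]` (5-20% defects); a
#' warning is raised outside that range.
#'
#' @param mu_notch,mu_wnt,mu_ecad Fractional increases (>= 0).
#' @return A list of class `mutation_scenario`.
#' @export
mutation_scenario <- function(mu_notch = 0, mu_wnt = 0, mu_ecad = 0) {
  mus <- c(mu_notch = mu_notch, mu_wnt = mu_wnt, mu_ecad = mu_ecad)
  stopifnot(all(is.finite(mus)), all(mus >= 0))
  if (any(mus > 0.2)) {
    warning("mutation fractions above 0.2 are outside the modeled 5-20% range")
  }
  structure(as.list(mus), class = "mutation_scenario")
}

#' Apply a mutation scenario to a parameter set
#'
#' Returns a copy of `params` in which exactly one parameter is scaled per
#' nonzero component: Notch synthesis by `1 + mu_notch`, ambient Wnt by
#' `1 + mu_wnt`, and the half-saturation of the bound-E-cadherin inhibition
#' gate by `1 + mu_ecad`. Everything else is untouched.
#'
#' @param params An [sc_params()] set.
#' @param scenario A [mutation_scenario()].
#' @return The mutated `sc_params`.
#' @export
apply_mutation <- function(params, scenario) {
  stopifnot(inherits(scenario, "mutation_scenario"))
  params$notch_synth <- params$notch_synth * (1 + scenario$mu_notch)
  params$wnt_ext <- params$wnt_ext * (1 + scenario$mu_wnt)
  params$lef_ecad_curve$half_sat <-
    params$lef_ecad_curve$half_sat * (1 + scenario$mu_ecad)
  validate_sc_params(params)
}

#' Dkk1 unit calibration constants
#'
#' Holds the conversion between the model's Dkk1 units and laboratory
#' concentrations. The reference is a secretion measurement of 38432 pg/mL
#' accumulated by 1e5 MCF-7 cells in 200 uL of medium, i.e. a representative
#' medium volume of 2e-3 uL per cell.
#'
#' @param ng_per_model_unit ng/mL corresponding to one model Dkk1 unit.
#' @param per_cell_volume Medium volume per cell (uL).
#' @param reference_secretion Reference secreted concentration (pg/mL).
#' @return A list of class `unit_calibration`.
#' @export
unit_calibration <- function(ng_per_model_unit = 2.01,
                             per_cell_volume = 2e-3,
                             reference_secretion = 38432) {
  stopifnot(ng_per_model_unit > 0, per_cell_volume > 0,
            reference_secretion > 0)
  structure(list(ng_per_model_unit = ng_per_model_unit,
                 per_cell_volume = per_cell_volume,
                 reference_secretion = reference_secretion),
            class = "unit_calibration")
}
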