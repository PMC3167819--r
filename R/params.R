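#' Signaling parameter set
#'
#' Bundles every constant of the intracellular model and the tissue rules:
#' the regulatory curves of the Wnt, E-cadherin and Notch branches,
#' first-order degradation rates (per hour), the fate thresholds `c_p`
#' (proliferation factor) and `c_m` (differentiation factor), the cell-cycle
#' refractory period `tau` (h), the differentiated-cell lifespan `phi` (h),
#' the DSL presentation level per living cell, the ambient Wnt level and the
#' Dkk1 model-unit to ng/mL conversion. Defaults are the shipped calibrated
#' set (see `stemfate_default_params()` and the package vignette).
#'
#' The model equations, with every `a_*`/`g_*`/`d_N` a [reg_curve()]:
#' \describe{
#'   \item{Wnt signal}{`W = S_w(wnt_ext) * I_d(dkk_ext)` (dimensionless gate
#'     `I_d`, `vmax = 1`).}
#'   \item{Secreted Dkk1 `K`}{`dK/dt = a_K(L) - dkk_deg * K`}
#'   \item{LEF/TCF `L`}{`dL/dt = W * g_E(B) - lef_deg * L`, `B` = bound
#'     E-cadherin, `g_E` a dimensionless down gate (`vmax = 1`).}
#'   \item{E-cadherin `E`}{`dE/dt = a_E(L) - ecad_deg * E` (`a_E` down).}
#'   \item{Proliferation factor `P`}{`dP/dt = a_P(L) - pf_deg * P`}
#'   \item{Notch `N`}{`dN/dt = notch_synth - d_N(L) * N` (`d_N` a down curve
#'     returning a degradation rate).}
#'   \item{HES `H`}{`dH/dt = a_H(N*) - hes_deg * H`, `N* = min(N, dsl_sum)`.}
#'   \item{Differentiation factor `D`}{`dD/dt = a_D(H) - df_deg * D`
#'     (`a_D` down: HES represses DF).}
#' }
#'
#' @param ... Named components overriding the shipped defaults. Curves must
#'   be [reg_curve()] objects of the documented kind; scalars must be
#'   positive (`kappa` in (0, 1]).
#' @return A list of class `sc_params`.
#' @examples
#' p <- sc_params()                     # shipped calibrated defaults
#' p2 <- sc_params(tau = 18)            # shorter cell cycle
#' @export
sc_params <- function(...) {
  p <- stemfate_default_params()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_sc_params(p)
}

#' Shipped default (calibrated) parameter set
#'
#' The defaults were produced by the package's calibration harness
#' ([calibrate_defaults()]) against three tissue-level targets: survival of a
#' 36-cell seed to a stable confluent tissue, an exogenous-Dkk1 dose-response
#' threshold near 13 ng/mL, and a 2-4 fold stem-cell increase under 20%
#' oncogenic-defect scenarios. See the methods vignette for the procedure.
#'
#' @return An `sc_params` object.
#' @export
stemfate_default_params <- function() {
  p <- list(
    # Wnt branch: ambient Wnt response and the Dkk1 inhibition gate that
    # carries both the exogenous dose and the secreted quorum signal
    wnt_signal_curve   = reg_curve("up",   vmax = 2,     half_sat = 1,    hill = 2),
    dkk_inhibition_curve = reg_curve("down", vmax = 1,   half_sat = 7.45, hill = 2),
    dkk_synth_curve    = reg_curve("up",   vmax = 0.005, half_sat = 0.1,  hill = 2),
    dkk_deg            = 0.0145,  # slow extracellular turnover (~3 d)
    lef_ecad_curve     = reg_curve("down", vmax = 1,     half_sat = 1.7,  hill = 2),
    lef_deg            = 0.5,
    # E-cadherin branch (adhesion rises as Wnt signaling falls)
    ecad_synth_curve   = reg_curve("down", vmax = 0.1,   half_sat = 1.2,  hill = 2),
    ecad_deg           = 0.1,
    ecad_binding_coeff = 0.5,
    # proliferation factor: half-saturation near the crowded LEF/TCF level
    # makes quiescence a graded brake on division
    pf_synth_curve     = reg_curve("up",   vmax = 0.1,   half_sat = 0.4,  hill = 2),
    pf_deg             = 0.1,
    # Notch branch: shallow LEF/TCF control of receptor degradation, steep
    # HES response - Notch perturbations and density contrasts then carry
    # comparable weight into the differentiation decision
    notch_synth        = 0.1,
    notch_deg_curve    = reg_curve("down", vmax = 0.5,   half_sat = 0.28, hill = 1),
    hes_synth_curve    = reg_curve("up",   vmax = 0.2,   half_sat = 0.62, hill = 6),
    hes_deg            = 0.2,
    # differentiation factor: unprotected cells run a ~40 h countdown
    df_synth_curve     = reg_curve("down", vmax = 0.05,  half_sat = 0.45, hill = 4),
    df_deg             = 1 / 30,
    # fate thresholds and tissue constants
    c_p = 0.54, c_m = 1.1,
    tau = 24, phi = 336,
    dsl_level = 0.12,
    wnt_ext = 1,
    ng_per_model_unit = 2.01
  )
  class(p) <- "sc_params"
  p
}

.curve_slots <- c(
  wnt_signal_curve = "up", dkk_inhibition_curve = "down",
  dkk_synth_curve = "up", lef_ecad_curve = "down", ecad_synth_curve = "down",
  pf_synth_curve = "up", notch_deg_curve = "down", hes_synth_curve = "up",
  df_synth_curve = "down"
)

.rate_slots <- c("dkk_deg", "lef_deg", "ecad_deg", "pf_deg", "notch_synth",
                 "hes_deg", "df_deg", "c_p", "c_m", "tau", "phi",
                 "dsl_level", "wnt_ext", "ng_per_model_unit")

validate_sc_params <- function(p) {
  for (nm in names(.curve_slots)) {
    cv <- p[[nm]]
    if (!inherits(cv, "reg_curve")) stop(nm, " must be a reg_curve")
    if (cv$kind != .curve_slots[[nm]]) {
      stop(nm, " must be a ", .curve_slots[[nm]], " curve")
    }
  }
  for (nm in .rate_slots) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a positive scalar")
    }
  }
  k <- p$ecad_binding_coeff
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1) {
    stop("ecad_binding_coeff must lie in (0, 1]")
  }
  class(p) <- "sc_params"
  p
}

#' @export
print.sc_params <- function(x, ...) {
  cat("<sc_params>\n")
  for (nm in names(.curve_slots)) {
    cv <- x[[nm]]
    cat(sprintf("  %-22s %-4s vmax=%-8g K=%-8g n=%g\n",
                nm, cv$kind, cv$vmax, cv$half_sat, cv$hill))
  }
  for (nm in c(.rate_slots, "ecad_binding_coeff")) {
    cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  }
  invisible(x)
}

# Fixed flattening used by the compiled engine; order is part of the
# R <-> C++ contract and must match PAR_* indices in src/engine.cpp.
params_to_vector <- function(p) {
  p <- validate_sc_params(p)
  cv <- function(nm) {
    c(p[[nm]]$vmax, p[[nm]]$half_sat, p[[nm]]$hill)
  }
  c(cv("wnt_signal_curve"), cv("dkk_inhibition_curve"),
    cv("dkk_synth_curve"), p$dkk_deg,
    cv("lef_ecad_curve"), p$lef_deg,
    cv("ecad_synth_curve"), p$ecad_deg, p$ecad_binding_coeff,
    cv("pf_synth_curve"), p$pf_deg,
    p$notch_synth, cv("notch_deg_curve"),
    cv("hes_synth_curve"), p$hes_deg,
    cv("df_synth_curve"), p$df_deg,
    p$c_p, p$c_m, p$tau, p$phi, p$dsl_level, p$wnt_ext, p$ng_per_model_unit)
}

#' Read / write a parameter set as YAML
#'
#' The on-disk schema is one mapping per component: curves are mappings with
#' keys `kind`, `vmax`, `half_sat`, `hill`; scalars are bare numbers. A
#' `schema` field records the layout version. The shipped default set lives
#' at `system.file("extdata", "default_params.yaml", package = "stemfate")`.
#'
#' @param p An `sc_params` object.
#' @param path File path.
#' @return `read_params()` returns an `sc_params`; `write_params()` returns
#'   `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- validate_sc_params(p)
  out <- list(schema = "stemfate-params/1")
  for (nm in names(p)) {
    x <- p[[nm]]
    out[[nm]] <- if (inherits(x, "reg_curve")) unclass(x) else x
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "stemfate-params/1")) {
    stop("not a stemfate parameter file (schema field missing or unknown)")
  }
  raw$schema <- NULL
  for (nm in intersect(names(raw), names(.curve_slots))) {
    x <- raw[[nm]]
    raw[[nm]] <- reg_curve(x$kind, x$vmax, x$half_sat, x$hill)
  }
  validate_sc_params(raw)
}
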