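#' Intracellular state of one stem cell
#'
#' Seven protein levels (arbitrary model units, all non-negative) plus the
#' time of the cell's last division (h): secreted Dkk1 `dkk_produced`,
#' activated LEF/TCF `lef_tcf`, total E-cadherin `ecad_total`, proliferation
#' factor `pf`, Notch receptor `notch`, HES `hes`, differentiation factor
#' `df`.
#'
#' @param dkk_produced,lef_tcf,ecad_total,pf,notch,hes,df Non-negative levels.
#' @param time_of_last_division Time stamp in hours (may be 0 for a freshly
#'   seeded cell).
#' @return A named numeric vector of class `cell_state`.
#' @export
cell_state <- function(dkk_produced = 0, lef_tcf = 0, ecad_total = 0, pf = 0,
                       notch = 0, hes = 0, df = 0, time_of_last_division = 0) {
  x <- c(dkk_produced = dkk_produced, lef_tcf = lef_tcf,
         ecad_total = ecad_total, pf = pf, notch = notch, hes = hes, df = df,
         time_of_last_division = time_of_last_division)
  if (any(!is.finite(x)) || any(x[1:7] < 0)) {
    stop("cell_state levels must be finite and non-negative")
  }
  structure(x, class = "cell_state")
}

#' Micro-environmental inputs of one stem cell
#'
#' Everything the cell senses from its close environment, held constant over
#' one integration step: ambient Wnt, total local Dkk1 (exogenous dose plus
#' own and neighboring stem cells' secretion, in ng/mL equivalents), total
#' bound E-cadherin `B`, and the summed DSL ligand presented by occupied
#' neighbor sites.
#'
#' @param wnt_ext,dkk_ext,bound_ecad,dsl_sum Non-negative levels.
#' @return A named numeric vector of class `cell_inputs`.
#' @export
cell_inputs <- function(wnt_ext = 0, dkk_ext = 0, bound_ecad = 0, dsl_sum = 0) {
  x <- c(wnt_ext = wnt_ext, dkk_ext = dkk_ext, bound_ecad = bound_ecad,
         dsl_sum = dsl_sum)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("cell_inputs must be finite and non-negative")
  }
  structure(x, class = "cell_inputs")
}

#' Wnt signal intensity
#'
#' The Wnt signal a cell receives is the saturating response to ambient Wnt,
#' multiplied by a dimensionless Dkk1 inhibition gate: `W = S_w(wnt_ext) *
#' I_d(dkk_ext)`. It is increasing in `wnt_ext`, decreasing in `dkk_ext`,
#' zero without ligand and bounded by the `S_w` plateau.
#'
#' @param wnt_ext Ambient Wnt level (model units).
#' @param dkk_ext Total local Dkk1 (ng/mL equivalents).
#' @param params An [sc_params()] set.
#' @return Wnt signal intensity (vectorized over the inputs).
#' @export
wnt_signal <- function(wnt_ext, dkk_ext, params) {
  regulatory(wnt_ext, params$wnt_signal_curve) *
    regulatory(dkk_ext, params$dkk_inhibition_curve)
}

#' Time derivatives of the intracellular model
#'
#' Evaluates the right-hand side of the seven coupled ODEs for one stem cell
#' given frozen micro-environmental inputs. Activated Notch is
#' `min(notch, dsl_sum)` (receptor- or ligand-limited juxtacrine
#' activation).
#'
#' @param state A [cell_state()].
#' @param inputs A [cell_inputs()].
#' @param params An [sc_params()] set.
#' @return Named numeric vector of the seven derivatives (per hour), in
#'   state order.
#' @export
cell_derivatives <- function(state, inputs, params) {
  w <- wnt_signal(inputs[["wnt_ext"]], inputs[["dkk_ext"]], params)
  n_act <- min(state[["notch"]], inputs[["dsl_sum"]])
  c(
    dkk_produced = regulatory(state[["lef_tcf"]], params$dkk_synth_curve) -
      params$dkk_deg * state[["dkk_produced"]],
    lef_tcf = w * regulatory(inputs[["bound_ecad"]], params$lef_ecad_curve) -
      params$lef_deg * state[["lef_tcf"]],
    ecad_total = regulatory(state[["lef_tcf"]], params$ecad_synth_curve) -
      params$ecad_deg * state[["ecad_total"]],
    pf = regulatory(state[["lef_tcf"]], params$pf_synth_curve) -
      params$pf_deg * state[["pf"]],
    notch = params$notch_synth -
      regulatory(state[["lef_tcf"]], params$notch_deg_curve) * state[["notch"]],
    hes = regulatory(n_act, params$hes_synth_curve) -
      params$hes_deg * state[["hes"]],
    df = regulatory(state[["hes"]], params$df_synth_curve) -
      params$df_deg * state[["df"]]
  )
}

#' Advance one cell by a fixed time step
#'
#' Classical fixed-step RK4 with the micro-environmental inputs held constant
#' over the step; `dt` is subdivided into substeps of at most `ode_dt`.
#' Levels are clipped at zero after every substep, which together with the
#' saturating (bounded) synthesis terms keeps the state non-negative.
#'
#' @param state A [cell_state()].
#' @param inputs A [cell_inputs()].
#' @param params An [sc_params()] set.
#' @param dt Step length in hours (> 0).
#' @param ode_dt Maximum internal substep (h); default 0.2.
#' @return The advanced `cell_state` (time of last division unchanged).
#' @export
integrate_cell <- function(state, inputs, params, dt, ode_dt = 0.2) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive scalar")
  }
  n_sub <- max(1L, as.integer(ceiling(dt / ode_dt - 1e-9)))
  h <- dt / n_sub
  y <- unclass(state)[1:7]
  for (s in seq_len(n_sub)) {
    y <- rk4_substep(y, inputs, params, h)
  }
  out <- c(y, time_of_last_division = state[["time_of_last_division"]])
  structure(out, class = "cell_state")
}

# One RK4 substep on the 7 levels; mirrors the compiled engine exactly.
rk4_substep <- function(y, inputs, params, h) {
  f <- function(y7) {
    st <- structure(c(y7, time_of_last_division = 0), class = "cell_state")
    cell_derivatives(st, inputs, params)
  }
  k1 <- f(y)
  k2 <- f(pmax(y + 0.5 * h * k1, 0))
  k3 <- f(pmax(y + 0.5 * h * k2, 0))
  k4 <- f(pmax(y + h * k3, 0))
  pmax(y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4), 0)
}
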