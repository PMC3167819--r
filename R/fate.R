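#' Fate decision of one stem cell
#'
#' Threshold logic evaluated after each tissue step, on the updated state:
#' differentiation (DF at or above `c_m`) takes precedence; otherwise the
#' cell divides if PF is at or above `c_p`, at least one neighboring site is
#' empty, and at least `tau` hours have passed since its last division; in
#' every other case (including PF above threshold with no vacant site) the
#' cell is quiescent.
#'
#' @param state A [cell_state()].
#' @param n_empty Number of currently empty neighbor sites.
#' @param now Current time (h).
#' @param config An [sc_params()] set (uses `c_p`, `c_m`, `tau`).
#' @return One of `"differentiate"`, `"divide"`, `"quiescent"`.
#' @export
decide_fate <- function(state, n_empty, now, config) {
  if (state[["df"]] >= config$c_m) return("differentiate")
  if (state[["pf"]] >= config$c_p && n_empty >= 1 &&
      now - state[["time_of_last_division"]] >= config$tau) {
    return("divide")
  }
  "quiescent"
}

#' Execute a symmetric division
#'
#' Places a daughter stem cell on one uniformly chosen empty neighbor of the
#' mother. Both mother and daughter keep the mother's intracellular state
#' with the two fate factors PF and DF reset to zero (symmetric division
#' consumes the proliferation trigger and restarts the differentiation
#' clock in both newborn cells) and the time of last division set to
#' `now`. If no empty neighbor remains at
#' execution time (another cell claimed it earlier in the same step), the
#' division is cancelled and the lattice is returned unchanged.
#'
#' @param lattice An [hex_lattice()].
#' @param mother_index Site of the dividing stem cell.
#' @param now Current time (h).
#' @return The modified lattice, with attribute `"daughter"` set to the
#'   chosen site index (or `NA` if the division was cancelled).
#' @export
apply_division <- function(lattice, mother_index, now) {
  check_site(lattice, mother_index)
  if (lattice$status[mother_index] != 1L) stop("site does not hold a stem cell")
  empties <- empty_neighbors(lattice, mother_index)
  k <- length(empties)
  if (k == 0L) {
    attr(lattice, "daughter") <- NA_integer_
    return(lattice)
  }
  j <- floor(runif(1) * k) + 1
  if (j > k) j <- k  # runif(1) == 1 guard
  daughter <- empties[[j]]
  lattice$state[mother_index, "pf"] <- 0
  lattice$state[mother_index, "df"] <- 0
  lattice$state[mother_index, "time_of_last_division"] <- now
  lattice$status[daughter] <- 1L
  lattice$state[daughter, ] <- lattice$state[mother_index, ]
  attr(lattice, "daughter") <- daughter
  lattice
}

#' Execute a differentiation
#'
#' The site switches irreversibly to the differentiated status: the ODE
#' state is dropped, the E-cadherin level is frozen at its current value
#' (the cell keeps presenting adhesion and DSL contact to its neighbors but
#' stops secreting Dkk1), and death is scheduled `phi` hours ahead.
#'
#' @param lattice An [hex_lattice()].
#' @param site_index Site of the differentiating stem cell.
#' @param now Current time (h).
#' @param config An [sc_params()] set (uses `phi`).
#' @return The modified lattice.
#' @export
apply_differentiation <- function(lattice, site_index, now, config) {
  check_site(lattice, site_index)
  if (lattice$status[site_index] != 1L) stop("site does not hold a stem cell")
  lattice$frozen_ecad[site_index] <- lattice$state[site_index, "ecad_total"]
  lattice$status[site_index] <- 2L
  lattice$state[site_index, ] <- 0
  lattice$death_time[site_index] <- now + config$phi
  lattice
}

# Micro-environmental inputs for a set of stem sites, from one synchronous
# lattice snapshot. Returns a matrix with columns wnt_ext, dkk_ext,
# bound_ecad, dsl_sum.
compute_inputs <- function(lattice, stems, params, exo_dkk) {
  n <- length(stems)
  e_self <- lattice$state[stems, "ecad_total"]
  b <- numeric(n)
  dsl <- numeric(n)
  dkk_nb <- numeric(n)
  for (d in 1:6) {
    nb_d <- lattice$nb[stems, d]
    st_d <- lattice$status[nb_d]
    e_d <- ifelse(st_d == 1L, lattice$state[nb_d, "ecad_total"],
                  ifelse(st_d == 2L, lattice$frozen_ecad[nb_d], 0))
    b <- b + params$ecad_binding_coeff * pmin(e_self, e_d)
    dsl <- dsl + params$dsl_level * (st_d > 0L)
    dkk_nb <- dkk_nb + ifelse(st_d == 1L, lattice$state[nb_d, "dkk_produced"], 0)
  }
  dkk_ext <- exo_dkk + params$ng_per_model_unit *
    (lattice$state[stems, "dkk_produced"] + dkk_nb)
  cbind(wnt_ext = rep(params$wnt_ext, n), dkk_ext = dkk_ext,
        bound_ecad = b, dsl_sum = dsl)
}

# Vectorized RHS over all stem cells: Y is n x 7, IN is n x 4.
# Element-wise identical to cell_derivatives().
vec_derivs <- function(Y, IN, params) {
  w <- wnt_signal(IN[, "wnt_ext"], IN[, "dkk_ext"], params)
  n_act <- pmin(Y[, 5], IN[, "dsl_sum"])
  cbind(
    regulatory(Y[, 2], params$dkk_synth_curve) - params$dkk_deg * Y[, 1],
    w * regulatory(IN[, "bound_ecad"], params$lef_ecad_curve) -
      params$lef_deg * Y[, 2],
    regulatory(Y[, 2], params$ecad_synth_curve) - params$ecad_deg * Y[, 3],
    regulatory(Y[, 2], params$pf_synth_curve) - params$pf_deg * Y[, 4],
    params$notch_synth - regulatory(Y[, 2], params$notch_deg_curve) * Y[, 5],
    regulatory(n_act, params$hes_synth_curve) - params$hes_deg * Y[, 6],
    regulatory(Y[, 6], params$df_synth_curve) - params$df_deg * Y[, 7]
  )
}

#' One synchronous tissue step (reference implementation)
#'
#' Advances the whole lattice by `dt` hours: (1) micro-environmental inputs
#' of every stem cell are computed from the current snapshot and frozen;
#' (2) every stem cell's ODEs advance by `dt` (RK4 substeps of at most
#' `ode_dt`); (3) stem cells execute fate decisions sequentially in a
#' uniformly random order (which resolves competition for shared empty
#' sites); (4) differentiated cells whose scheduled death time has arrived
#' vacate their sites. Deterministic given the RNG state.
#'
#' This is the pure-R reference used by the unit tests; [run_replicate()]
#' uses the compiled engine, which consumes the random-number stream in
#' exactly the same order and yields bit-identical trajectories.
#'
#' @param lattice An [hex_lattice()].
#' @param schedule A [dose_schedule()] (exogenous Dkk1, evaluated at the
#'   step start).
#' @param params An [sc_params()] set.
#' @param dt Step length (h), default 1.
#' @param t Time at the start of the step (h).
#' @param ode_dt Maximum ODE substep (h).
#' @return The lattice advanced to `t + dt`, with attribute `"events"`: a
#'   data frame of the step's divide / differentiate / die events.
#' @export
tissue_step <- function(lattice, schedule, params, dt = 1, t = 0,
                        ode_dt = 0.2) {
  stopifnot(dt > 0)
  now <- t + dt
  ev_time <- numeric(0); ev_site <- integer(0); ev_what <- character(0)
  stems <- which(lattice$status == 1L)
  if (length(stems)) {
    exo <- exogenous_dkk(t, schedule)
    IN <- compute_inputs(lattice, stems, params, exo)
    Y <- lattice$state[stems, 1:7, drop = FALSE]
    n_sub <- max(1L, as.integer(ceiling(dt / ode_dt - 1e-9)))
    h <- dt / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- vec_derivs(Y, IN, params)
      k2 <- vec_derivs(pmax(Y + 0.5 * h * k1, 0), IN, params)
      k3 <- vec_derivs(pmax(Y + 0.5 * h * k2, 0), IN, params)
      k4 <- vec_derivs(pmax(Y + h * k3, 0), IN, params)
      Y <- pmax(Y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    }
    lattice$state[stems, 1:7] <- Y
    # random visiting order: one uniform key per stem cell, stable order
    keys <- runif(length(stems))
    for (s in stems[order(keys)]) {
      st <- structure(lattice$state[s, ], class = "cell_state")
      n_empty <- length(empty_neighbors(lattice, s))
      fate <- decide_fate(st, n_empty, now, params)
      if (fate == "differentiate") {
        lattice <- apply_differentiation(lattice, s, now, params)
        ev_time <- c(ev_time, now); ev_site <- c(ev_site, s)
        ev_what <- c(ev_what, "differentiate")
      } else if (fate == "divide") {
        lattice <- apply_division(lattice, s, now)
        ev_time <- c(ev_time, now); ev_site <- c(ev_site, s)
        ev_what <- c(ev_what, "divide")
      }
    }
  }
  dying <- which(lattice$status == 2L & !is.na(lattice$death_time) &
                   lattice$death_time <= now)
  if (length(dying)) {
    lattice$status[dying] <- 0L
    lattice$frozen_ecad[dying] <- 0
    lattice$death_time[dying] <- NA_real_
    ev_time <- c(ev_time, rep(now, length(dying)))
    ev_site <- c(ev_site, dying)
    ev_what <- c(ev_what, rep("die", length(dying)))
  }
  attr(lattice, "daughter") <- NULL
  attr(lattice, "events") <- data.frame(time = ev_time, site = ev_site,
                                        event = ev_what)
  lattice
}

#' Run a tissue simulation with the reference R engine
#'
#' Repeatedly applies [tissue_step()] from `t0` to `t_end` and records the
#' stem-cell count, differentiated count and total secreted Dkk1 every
#' `record_every` hours. Intended for small lattices and unit tests; use
#' [run_replicate()] (compiled engine) for full-size experiments.
#'
#' @param lattice A seeded [hex_lattice()].
#' @param params An [sc_params()] set.
#' @param schedule A [dose_schedule()].
#' @param t_end Final time (h).
#' @param dt Tissue step (h).
#' @param ode_dt Maximum ODE substep (h).
#' @param record_every Recording interval (h); must be a multiple of `dt`.
#' @param t0 Start time (h).
#' @param collect_events If `TRUE`, accumulate the per-step event log.
#' @return A list with `lattice` (final state), `series` (data frame of
#'   time, n_stem, n_differentiated, total_dkk) and, if requested, `events`.
#' @export
run_tissue <- function(lattice, params, schedule, t_end, dt = 1,
                       ode_dt = 0.2, record_every = 6, t0 = 0,
                       collect_events = FALSE) {
  n_steps <- as.integer(round((t_end - t0) / dt))
  rec_stride <- max(1L, as.integer(round(record_every / dt)))
  rec <- function(lat, tm) {
    stems <- lat$status == 1L
    data.frame(time = tm, n_stem = sum(stems),
               n_differentiated = sum(lat$status == 2L),
               total_dkk = sum(lat$state[stems, "dkk_produced"]))
  }
  series <- vector("list", n_steps %/% rec_stride + 1L)
  series[[1L]] <- rec(lattice, t0)
  events <- if (collect_events) vector("list", n_steps) else NULL
  ri <- 1L
  for (k in seq_len(n_steps)) {
    t <- t0 + (k - 1L) * dt
    lattice <- tissue_step(lattice, schedule, params, dt = dt, t = t,
                           ode_dt = ode_dt)
    if (collect_events) events[[k]] <- attr(lattice, "events")
    if (k %% rec_stride == 0L) {
      ri <- ri + 1L
      series[[ri]] <- rec(lattice, t + dt)
    }
  }
  out <- list(lattice = lattice,
              series = do.call(rbind, series[seq_len(ri)]))
  if (collect_events) out$events <- do.call(rbind, events)
  out
}
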