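#' Configuration of a replicated dose-sweep experiment
#'
#' Captures the full protocol of the simulated Dkk1 experiments: 36 stem
#' cells seeded at random on the 40 x 20 toroidal honeycomb, exogenous Dkk1
#' applied continuously for 48 h from time zero, the tissue then simulated
#' for three months (2160 h) past the treatment, and the stem-cell count
#' averaged over the last three simulated days, with 50 replicates per dose.
#'
#' @param n_replicates Replicates per dose (default 50).
#' @param doses Dose grid in ng/mL; the default covers 0-25 ng/mL with
#'   2 ng/mL resolution around the threshold region.
#' @param treatment_duration Dkk1 exposure (h, default 48).
#' @param post_treatment_duration Simulated time after treatment ends
#'   (h, default 2160 = three months).
#' @param measurement_window Averaging window at the end of the run
#'   (h, default 72 = three days).
#' @param record_every Recording interval for the SC-count series (h).
#' @param initial_sc_count Seeded stem cells (default 36).
#' @param n_cols,n_rows Lattice dimensions (default 40 x 20).
#' @param dt Tissue step (h).
#' @param ode_dt Maximum intracellular ODE substep (h).
#' @param master_seed Master seed; per-replicate seeds are derived from it
#'   by position in the dose x replicate grid, so results do not depend on
#'   the order in which doses are run.
#' @param scenario A [mutation_scenario()] applied to `params`.
#' @param params An [sc_params()] set.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_replicates = 50,
                              doses = c(0, 1, seq(3, 25, by = 2)),
                              treatment_duration = 48,
                              post_treatment_duration = 2160,
                              measurement_window = 72,
                              record_every = 6,
                              initial_sc_count = 36,
                              n_cols = 40, n_rows = 20,
                              dt = 1, ode_dt = 0.2,
                              master_seed = 1,
                              scenario = mutation_scenario(),
                              params = sc_params()) {
  stopifnot(n_replicates >= 1, all(doses >= 0), treatment_duration > 0,
            post_treatment_duration > 0,
            measurement_window <= treatment_duration + post_treatment_duration,
            initial_sc_count >= 1, initial_sc_count <= n_cols * n_rows,
            dt > 0, ode_dt > 0, record_every >= dt)
  structure(list(
    n_replicates = as.integer(n_replicates), doses = doses,
    treatment_duration = treatment_duration,
    post_treatment_duration = post_treatment_duration,
    measurement_window = measurement_window,
    record_every = record_every,
    initial_sc_count = as.integer(initial_sc_count),
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    dt = dt, ode_dt = ode_dt,
    master_seed = as.integer(master_seed),
    scenario = scenario,
    params = validate_sc_params(params)
  ), class = "experiment_config")
}

#' Run one replicate of the dosing protocol
#'
#' Seeds `initial_sc_count` stem cells uniformly at random on an empty
#' lattice, applies the dose continuously for `treatment_duration` hours
#' from time zero, and simulates until `treatment_duration +
#' post_treatment_duration`. The mutation scenario in `config` is applied to
#' the parameters before the run. Deterministic given `seed`.
#'
#' @param config An [experiment_config()].
#' @param dose Exogenous Dkk1 concentration (ng/mL).
#' @param seed Integer seed for this replicate.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both consume the random-number stream identically and
#'   give bit-identical trajectories.
#' @return A list of class `hca_run`: `series` (data frame of time, n_stem,
#'   n_differentiated, total_dkk), `final` (occupancy counts), `events`
#'   (named totals of divisions, differentiations, deaths; compiled engine
#'   only), `dose`, `seed`.
#' @export
run_replicate <- function(config, dose = 0, seed = 1,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "experiment_config"), dose >= 0)
  params <- apply_mutation(config$params, config$scenario)
  schedule <- dose_schedule(dose, start = 0,
                            duration = config$treatment_duration)
  t_end <- config$treatment_duration + config$post_treatment_duration
  set.seed(as.integer(seed))
  lat <- hex_lattice(config$n_cols, config$n_rows)
  lat <- seed_random(lat, config$initial_sc_count, params)
  if (engine == "cpp") {
    n_steps <- as.integer(round(t_end / config$dt))
    exo <- exogenous_dkk((seq_len(n_steps) - 1) * config$dt, schedule)
    rec_stride <- max(1L, as.integer(round(config$record_every / config$dt)))
    res <- hca_run_cpp(params_to_vector(params), lat$nb, lat$status,
                       lat$state, lat$frozen_ecad, lat$death_time,
                       exo, 0, config$dt, config$ode_dt, rec_stride)
    out <- list(
      series = res$series,
      final = c(stem = sum(res$status == 1L),
                differentiated = sum(res$status == 2L),
                empty = sum(res$status == 0L)),
      events = c(divisions = res$n_divisions,
                 differentiations = res$n_differentiations,
                 deaths = res$n_deaths),
      dose = dose, seed = as.integer(seed)
    )
  } else {
    r <- run_tissue(lat, params, schedule, t_end, dt = config$dt,
                    ode_dt = config$ode_dt,
                    record_every = config$record_every)
    out <- list(series = r$series, final = occupancy(r$lattice),
                events = NULL, dose = dose, seed = as.integer(seed))
  }
  class(out) <- "hca_run"
  out
}

#' Window-averaged stem-cell count of a run
#'
#' Mean of the recorded stem-cell counts over the final `window` hours of
#' the series (all recorded points with `time >= t_end - window`).
#'
#' @param run An `hca_run` (or anything with a `series` data frame).
#' @param window Averaging window (h).
#' @return A single number.
#' @export
window_mean_sc <- function(run, window = 72) {
  s <- run$series
  t_end <- max(s$time)
  mean(s$n_stem[s$time >= t_end - window])
}

# Counter-based per-replicate seeds keyed on (master seed, dose value):
# each dose gets its own reproducible seed stream, so sweeps are
# order-independent and any (dose, replicate) cell is individually
# re-runnable. Doses are distinguished at 0.001 ng/mL resolution.
replicate_seeds <- function(master_seed, dose, n_replicates) {
  s0 <- (as.numeric(master_seed) * 69069 + round(dose * 1000) + 1) %% 2147483647
  set.seed(as.integer(s0))
  sample.int(2147483646L, n_replicates)
}

#' Run a replicated Dkk1 dose sweep
#'
#' Runs `n_replicates` seeded simulations for every dose in the grid and
#' summarises the window-averaged stem-cell counts per dose (mean, sd, SEM).
#' Per-replicate seeds are derived from the master seed by a counter scheme
#' keyed on the dose value and replicate index, so per-dose results do not
#' depend on the order (or composition) of the dose grid.
#'
#' @param config An [experiment_config()].
#' @param keep_series If `TRUE`, keep every replicate's full SC-count series
#'   (memory-heavy for full sweeps).
#' @param progress If `TRUE`, print one line per dose.
#' @return A list of class `dose_response`: `replicates` (data frame with
#'   dose, replicate, seed, window_mean, final_stem), `summary` (per-dose
#'   mean/sd/sem/n), `config`, and optionally `series`.
#' @export
run_dose_sweep <- function(config, keep_series = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  doses <- config$doses
  reps <- vector("list", length(doses) * config$n_replicates)
  series <- if (keep_series) vector("list", length(reps)) else NULL
  k <- 0L
  for (d in seq_along(doses)) {
    seeds_d <- replicate_seeds(config$master_seed, doses[d],
                               config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      run <- run_replicate(config, dose = doses[d], seed = seeds_d[r])
      k <- k + 1L
      reps[[k]] <- data.frame(
        dose = doses[d], replicate = r, seed = seeds_d[r],
        window_mean = window_mean_sc(run, config$measurement_window),
        final_stem = unname(run$final["stem"]))
      if (keep_series) {
        series[[k]] <- cbind(dose = doses[d], replicate = r, run$series)
      }
    }
    if (progress) {
      done <- do.call(rbind, reps[(k - config$n_replicates + 1L):k])
      message(sprintf("dose %5.1f ng/mL: mean SC %.1f", doses[d],
                      mean(done$window_mean)))
    }
  }
  replicates <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(split(replicates, replicates$dose), function(g) {
    data.frame(dose = g$dose[1], n = nrow(g), mean_sc = mean(g$window_mean),
               sd_sc = sd(g$window_mean),
               sem_sc = sd(g$window_mean) / sqrt(nrow(g)))
  }))
  summary <- summary[order(summary$dose), ]
  rownames(summary) <- NULL
  out <- list(replicates = replicates, summary = summary, config = config)
  if (keep_series) out$series <- do.call(rbind, series)
  class(out) <- "dose_response"
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %d doses x %d replicates\n",
              nrow(x$summary), x$config$n_replicates))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Detect the Dkk1 dose-response threshold
#'
#' Operationalises the biphasic dose response: the threshold is the largest
#' dose whose mean window-averaged stem-cell count is still at least
#' `1 - tolerance` of the untreated (dose 0) mean. The full normalised
#' curve is returned alongside. If no dose qualifies (a pathological curve
#' where even dose 0 fails), the smallest swept dose is returned flagged.
#'
#' @param result A [run_dose_sweep()] result whose grid includes dose 0.
#' @param tolerance Allowed relative drop below baseline (default 0.05).
#' @return A list of class `dkk_threshold`: `threshold` (ng/mL), `flagged`,
#'   `baseline`, and `curve` (dose, mean_sc, sem_sc, relative).
#' @export
detect_threshold <- function(result, tolerance = 0.05) {
  stopifnot(inherits(result, "dose_response"))
  s <- result$summary
  if (!any(s$dose == 0)) stop("dose grid must include the untreated dose 0")
  baseline <- s$mean_sc[s$dose == 0]
  curve <- data.frame(dose = s$dose, mean_sc = s$mean_sc, sem_sc = s$sem_sc,
                      relative = s$mean_sc / baseline)
  ok <- curve$relative >= 1 - tolerance
  ok[is.na(ok)] <- FALSE   # degenerate (extinct) baseline
  if (any(ok)) {
    thr <- max(curve$dose[ok])
    flagged <- FALSE
  } else {
    thr <- min(curve$dose)
    flagged <- TRUE
  }
  structure(list(threshold = thr, flagged = flagged, baseline = baseline,
                 tolerance = tolerance, curve = curve),
            class = "dkk_threshold")
}

#' @export
print.dkk_threshold <- function(x, ...) {
  cat(sprintf("Dkk1 dose-response threshold: %g ng/mL (baseline %.1f SCs%s)\n",
              x$threshold, x$baseline,
              if (x$flagged) "; FLAGGED: no dose met the criterion" else ""))
  invisible(x)
}
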