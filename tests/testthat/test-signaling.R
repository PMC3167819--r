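test_that("Wnt signal composes ligand activation with Dkk1 inhibition", {
  p <- test_params()
  expect_equal(wnt_signal(0, 0, p), 0)             # no ligand, no signal
  expect_equal(wnt_signal(2, 0, p),
               regulatory(2, p$wnt_signal_curve))  # no inhibitor
  expect_lt(wnt_signal(2, 1e7, p), 1e-9)           # saturating inhibition
  # monotone in both arguments
  expect_true(all(diff(wnt_signal(seq(0, 5, 0.25), 1, p)) > 0))
  expect_true(all(diff(wnt_signal(1, seq(0, 30, 1), p)) < 0))
})

test_that("zero state with zero inputs only synthesises Notch", {
  p <- test_params()
  d <- cell_derivatives(cell_state(), cell_inputs(), p)
  expect_equal(unname(d[c("dkk_produced", "pf", "hes")]), c(0, 0, 0))
  expect_equal(unname(d["notch"]), p$notch_synth)
  # DF synthesis is basal (down curve at zero HES)
  expect_equal(unname(d["df"]), p$df_synth_curve$vmax)
})

test_that("species with frozen drivers reach their closed-form steady state", {
  p <- test_params()
  # choose the ambient Wnt level whose signal exactly sustains L = l_fix;
  # LEF/TCF is then stationary and PF obeys a linear ODE with steady state
  # a_P(l_fix) / delta_P (and Notch sigma_N / d_N(l_fix))
  l_fix <- 0.8
  rate <- p$lef_deg * l_fix    # required Wnt signal intensity
  sw <- p$wnt_signal_curve
  wnt_fix <- sw$half_sat * (rate / (sw$vmax - rate))^(1 / sw$hill)
  inp <- cell_inputs(wnt_ext = wnt_fix, dkk_ext = 0, bound_ecad = 0,
                     dsl_sum = 0)
  st <- cell_state(lef_tcf = l_fix)
  half_life <- log(2) / p$pf_deg
  t_relax <- 20 * half_life
  steps <- ceiling(t_relax / 1)
  for (i in seq_len(steps)) {
    st <- integrate_cell(st, inp, p, dt = 1)
  }
  expect_equal(st[["lef_tcf"]], l_fix, tolerance = 1e-6)
  expect_equal(st[["pf"]], regulatory(l_fix, p$pf_synth_curve) / p$pf_deg,
               tolerance = 0.01)
  expect_equal(st[["notch"]],
               p$notch_synth / regulatory(l_fix, p$notch_deg_curve),
               tolerance = 0.01)
  # starting exactly at the Notch fixed point, the derivative vanishes
  st2 <- cell_state(lef_tcf = l_fix,
                    notch = p$notch_synth / regulatory(l_fix, p$notch_deg_curve))
  expect_equal(unname(cell_derivatives(st2, inp, p)["notch"]), 0,
               tolerance = 1e-12)
})

test_that("pure first-order decay matches the exponential solution", {
  p <- test_params()
  # zero inputs and zero LEF/TCF: PF decays as P0 * exp(-delta * t)
  st <- cell_state(pf = 2)
  inp <- cell_inputs()
  out <- st
  for (i in 1:24) out <- integrate_cell(out, inp, p, dt = 1, ode_dt = 0.01)
  expect_equal(out[["pf"]], 2 * exp(-p$pf_deg * 24), tolerance = 1e-6)
})

test_that("halving the substep barely changes a 24 h trajectory", {
  p <- test_params()
  st <- seed_cell_state(p)
  inp <- cell_inputs(wnt_ext = 1, dkk_ext = 4, bound_ecad = 1, dsl_sum = 2)
  a <- integrate_cell(st, inp, p, dt = 24, ode_dt = 0.2)
  b <- integrate_cell(st, inp, p, dt = 24, ode_dt = 0.1)
  rel <- abs(a[1:7] - b[1:7]) / pmax(abs(b[1:7]), 1e-12)
  expect_lt(max(rel), 1e-4)
})

test_that("levels stay non-negative from random non-negative states", {
  p <- test_params()
  set.seed(99)
  for (i in 1:25) {
    st <- cell_state(dkk_produced = runif(1, 0, 2), lef_tcf = runif(1, 0, 3),
                     ecad_total = runif(1, 0, 2), pf = runif(1, 0, 1),
                     notch = runif(1, 0, 10), hes = runif(1, 0, 1),
                     df = runif(1, 0, 2))
    inp <- cell_inputs(wnt_ext = runif(1, 0, 2), dkk_ext = runif(1, 0, 30),
                       bound_ecad = runif(1, 0, 3), dsl_sum = runif(1, 0, 6))
    out <- st
    for (k in 1:50) out <- integrate_cell(out, inp, p, dt = 1)
    expect_true(all(out[1:7] >= 0))
    expect_true(all(is.finite(out)))
  }
})

test_that("quasi-steady LEF/TCF and PF respond monotonically to Dkk1", {
  p <- test_params()
  qss <- sapply(c(0, 2, 5, 10, 20), function(dkk) {
    inp <- cell_inputs(wnt_ext = 1, dkk_ext = dkk, bound_ecad = 0.5,
                       dsl_sum = 3)
    st <- seed_cell_state(p)
    for (k in 1:300) st <- integrate_cell(st, inp, p, dt = 1)
    st[c("lef_tcf", "pf", "dkk_produced")]
  })
  expect_true(all(diff(qss["lef_tcf", ]) < 1e-9))
  expect_true(all(diff(qss["pf", ]) < 1e-9))
  expect_true(all(diff(qss["dkk_produced", ]) < 1e-9))
})

test_that("integration rejects non-positive steps", {
  p <- test_params()
  expect_error(integrate_cell(cell_state(), cell_inputs(), p, dt = 0), "dt")
  expect_error(integrate_cell(cell_state(), cell_inputs(), p, dt = -1), "dt")
})
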