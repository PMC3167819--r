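test_that("fate decisions follow the threshold logic with precedence", {
  p <- test_params(c_p = 0.5, c_m = 1.0, tau = 24)
  ready <- cell_state(pf = 0.6, df = 0.2, time_of_last_division = 0)
  expect_equal(decide_fate(ready, n_empty = 1, now = 30, p), "divide")
  # differentiation wins even with PF above threshold
  both <- cell_state(pf = 0.9, df = 1.2, time_of_last_division = 0)
  expect_equal(decide_fate(both, n_empty = 3, now = 30, p), "differentiate")
  # crowding: PF above threshold but no vacant site
  expect_equal(decide_fate(ready, n_empty = 0, now = 30, p), "quiescent")
  # refractory period since last division
  expect_equal(decide_fate(ready, n_empty = 1, now = 20, p), "quiescent")
  young <- cell_state(pf = 0.6, time_of_last_division = 10)
  expect_equal(decide_fate(young, n_empty = 1, now = 30, p), "quiescent")
  # sub-threshold everything
  idle <- cell_state(pf = 0.1, df = 0.1)
  expect_equal(decide_fate(idle, n_empty = 6, now = 100, p), "quiescent")
})

test_that("division places the daughter on an empty neighbor and resets PF", {
  p <- test_params()
  lat <- hex_lattice(10, 6)
  ring <- hex_neighbors(lat, 15)
  # block five of the six neighbors: the daughter must take the last one
  lat <- seed_stem(lat, c(15, ring[1:5]), p)
  lat$state[15, "pf"] <- 0.9
  set.seed(1)
  out <- apply_division(lat, 15, now = 48)
  expect_equal(attr(out, "daughter"), unname(ring[6]))
  expect_equal(out$status[ring[6]], 1L)
  expect_equal(unname(out$state[15, "pf"]), 0)
  expect_equal(unname(out$state[ring[6], "pf"]), 0)
  expect_equal(unname(out$state[15, "time_of_last_division"]), 48)
  # daughter inherits the rest of the mother's state
  expect_equal(unname(out$state[ring[6], "lef_tcf"]),
               unname(out$state[15, "lef_tcf"]))

  # lost race: no empty neighbor at execution time
  full <- seed_stem(hex_lattice(6, 4), 1:24, p)
  res <- apply_division(full, 1, now = 48)
  expect_true(is.na(attr(res, "daughter")))
  expect_equal(res$status, full$status)
})

test_that("daughter sites are chosen uniformly among the empties", {
  p <- test_params()
  lat <- hex_lattice(10, 6)
  ring <- hex_neighbors(lat, 15)
  lat <- seed_stem(lat, c(15, ring[1:3]), p)  # k = 3 empties remain
  empties <- ring[4:6]
  n <- 10000
  set.seed(42)
  picks <- integer(n)
  for (i in seq_len(n)) {
    picks[i] <- attr(apply_division(lat, 15, now = 48), "daughter")
  }
  counts <- table(factor(picks, levels = empties))
  # binomial 3-sigma band around n/3
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) < 3 * sigma))
})

test_that("differentiation freezes ligands and schedules death", {
  p <- test_params()
  lat <- small_lattice()
  before <- occupancy(lat)
  e_level <- lat$state[1, "ecad_total"]
  out <- apply_differentiation(lat, 1, now = 100, config = p)
  after <- occupancy(out)
  expect_equal(unname(before["stem"] - after["stem"]), 1L)
  expect_equal(unname(after["differentiated"] - before["differentiated"]), 1L)
  expect_equal(out$frozen_ecad[1], unname(e_level))
  expect_equal(out$death_time[1], 100 + p$phi)
  expect_true(all(out$state[1, ] == 0))
  # a differentiated site cannot differentiate or divide again
  expect_error(apply_differentiation(out, 1, 101, p), "stem")
  expect_error(apply_division(out, 1, 101), "stem")
})

test_that("an empty lattice is unchanged by a tissue step", {
  p <- test_params()
  lat <- hex_lattice(10, 6)
  sched <- dose_schedule(0)
  out <- tissue_step(lat, sched, p, dt = 1, t = 0)
  attr(out, "events") <- NULL
  expect_equal(out, lat)
})

test_that("a differentiated cell dies exactly at the scheduled time", {
  p <- test_params(phi = 10)
  lat <- small_lattice(params = test_params(phi = 10))
  lat <- apply_differentiation(lat, 1, now = 0, config = p)
  sched <- dose_schedule(0)
  for (k in 1:9) lat <- tissue_step(lat, sched, p, dt = 1, t = k - 1)
  expect_equal(lat$status[1], 2L)
  lat <- tissue_step(lat, sched, p, dt = 1, t = 9)
  expect_equal(lat$status[1], 0L)   # site vacated at now == death time
  ev <- attr(lat, "events")
  expect_true(any(ev$event == "die" & ev$site == 1))
})

test_that("occupancy conservation identities hold over a long run", {
  # delta(stem) = divisions - differentiations,
  # delta(diff) = differentiations - deaths,
  # delta(empty) = deaths - divisions, and the three counts always sum to
  # the lattice size; audited exhaustively over 200 steps.
  p <- test_params()
  set.seed(5)
  lat <- seed_random(hex_lattice(10, 6), 6, p)
  sched <- dose_schedule(0)
  for (k in 1:200) {
    before <- occupancy(lat)
    lat <- tissue_step(lat, sched, p, dt = 1, t = k - 1)
    after <- occupancy(lat)
    ev <- attr(lat, "events")
    n_div <- sum(ev$event == "divide")
    n_diff <- sum(ev$event == "differentiate")
    n_die <- sum(ev$event == "die")
    expect_equal(unname(after["stem"] - before["stem"]), n_div - n_diff)
    expect_equal(unname(after["differentiated"] - before["differentiated"]),
                 n_diff - n_die)
    expect_equal(unname(after["empty"] - before["empty"]), n_die - n_div)
    expect_equal(sum(after), lat$n_sites)
  }
})

test_that("stem cells are lost only through differentiation events", {
  p <- test_params()
  set.seed(11)
  lat <- seed_random(hex_lattice(10, 6), 6, p)
  sched <- dose_schedule(20, start = 0, duration = 48)  # dosing forces losses
  for (k in 1:150) {
    before <- sum(lat$status == 1L)
    lat <- tissue_step(lat, sched, p, dt = 1, t = k - 1)
    after <- sum(lat$status == 1L)
    ev <- attr(lat, "events")
    if (after < before + sum(ev$event == "divide")) {
      expect_gte(sum(ev$event == "differentiate"), 1)
    }
  }
})

test_that("identical seeds give bit-identical trajectories", {
  p <- test_params()
  run_once <- function() {
    set.seed(123)
    lat <- seed_random(hex_lattice(10, 6), 5, p)
    run_tissue(lat, p, dose_schedule(3), t_end = 120)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$series, b$series)
  expect_identical(a$lattice$status, b$lattice$status)
  expect_identical(a$lattice$state, b$lattice$state)
})
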