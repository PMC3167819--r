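test_that("the default lattice is a 40 x 20 torus with 800 six-neighbor sites", {
  lat <- hex_lattice()
  expect_equal(lat$n_sites, 800)
  expect_equal(dim(lat$nb), c(800, 6))
  # six distinct neighbors everywhere, none of them the site itself
  expect_true(all(apply(lat$nb, 1, function(r) length(unique(r)) == 6)))
  expect_true(all(lat$nb != seq_len(800)))
  # symmetry: b in nb(a) <=> a in nb(b), checked for all pairs
  for (a in seq_len(800)) {
    for (b in lat$nb[a, ]) expect_true(a %in% lat$nb[b, ])
  }
  # exhaustive directed-pair count
  expect_equal(length(lat$nb), 4800)
})

test_that("small lattices keep the same structural invariants", {
  for (dims in list(c(10, 6), c(6, 4), c(3, 4))) {
    lat <- hex_lattice(dims[1], dims[2])
    expect_true(all(apply(lat$nb, 1, function(r) length(unique(r)) == 6)))
    for (a in seq_len(lat$n_sites)) {
      for (b in lat$nb[a, ]) expect_true(a %in% lat$nb[b, ])
    }
  }
  expect_error(hex_lattice(2, 4))   # neighbors would coincide
  expect_error(hex_lattice(10, 5))  # odd row count breaks the wrap parity
})

test_that("neighbor lookup validates site indices", {
  lat <- hex_lattice(10, 6)
  expect_error(hex_neighbors(lat, 0), "site")
  expect_error(hex_neighbors(lat, 61), "site")
  expect_error(hex_neighbors(lat, 1.5), "site")
})

test_that("empty_neighbors partitions the six neighbors", {
  lat <- small_lattice()
  for (i in which(lat$status == 1L)) {
    ne <- empty_neighbors(lat, i)
    occupied <- sum(lat$status[hex_neighbors(lat, i)] > 0)
    expect_equal(length(ne) + occupied, 6)
  }
  # single seeded cell on an otherwise empty lattice
  lone <- seed_stem(hex_lattice(10, 6), 15, test_params())
  expect_length(empty_neighbors(lone, 15), 6)
  # confluent lattice: no empties anywhere
  full <- seed_stem(hex_lattice(6, 4), 1:24, test_params())
  expect_true(all(vapply(1:24, function(i)
    length(empty_neighbors(full, i)), integer(1)) == 0L))
})

test_that("bound E-cadherin follows the min rule over the six directions", {
  p <- test_params()
  kappa <- p$ecad_binding_coeff
  lone <- seed_stem(hex_lattice(10, 6), 15, p)
  b0 <- bound_ecadherin(lone, 15, kappa)
  expect_equal(b0$total, 0)            # all neighbors empty
  expect_equal(b0$per_direction, rep(0, 6))

  # all six neighbors stems with a common E level e: B = 6 * kappa * e
  lat <- hex_lattice(10, 6)
  center <- 15
  ring <- hex_neighbors(lat, center)
  lat <- seed_stem(lat, c(center, ring), p)
  e <- unname(lat$state[center, "ecad_total"])  # same seed state everywhere
  b <- bound_ecadherin(lat, center, kappa)
  expect_equal(b$total, 6 * kappa * e)
  # total is always the sum of the six per-direction terms
  expect_equal(b$total, sum(b$per_direction))

  # min() picks the lower of the two membrane levels
  lat$state[ring[1], "ecad_total"] <- e / 4
  lat$state[ring[2], "ecad_total"] <- e * 10
  b2 <- bound_ecadherin(lat, center, kappa)
  expect_equal(b2$per_direction[1], kappa * e / 4)
  expect_equal(b2$per_direction[2], kappa * e)
  expect_error(bound_ecadherin(lat, ring[1] , kappa), NA)
  empty_site <- which(lat$status == 0L)[1]
  expect_error(bound_ecadherin(lat, empty_site, kappa), "stem")
})

test_that("DSL availability counts occupied neighbors at d0 each", {
  p <- test_params()
  d0 <- p$dsl_level
  lone <- seed_stem(hex_lattice(10, 6), 15, p)
  expect_equal(dsl_available(lone, 15, d0), 0)   # isolated cell

  lat <- hex_lattice(10, 6)
  ring <- hex_neighbors(lat, 15)
  lat <- seed_stem(lat, c(15, ring), p)
  expect_equal(dsl_available(lat, 15, d0), 6 * d0)
  # a differentiated neighbor still presents DSL; an empty one does not
  lat2 <- apply_differentiation(lat, ring[1], now = 10, config = p)
  expect_equal(dsl_available(lat2, 15, d0), 6 * d0)
  lat2$status[ring[2]] <- 0L
  expect_equal(dsl_available(lat2, 15, d0), 5 * d0)
})

test_that("activated Notch is the minimum of receptor and ligand", {
  expect_equal(activated_notch(5, 3), 3)
  expect_equal(activated_notch(2, 7), 2)
  expect_equal(activated_notch(c(1, 4), c(4, 1)), c(1, 1))
  expect_equal(activated_notch(10, 0), 0)
  expect_error(activated_notch(-1, 0), "non-negative")
})

test_that("random seeding places the requested number of distinct stems", {
  p <- test_params()
  set.seed(7)
  lat <- seed_random(hex_lattice(), 36, p)
  expect_equal(unname(occupancy(lat)["stem"]), 36L)
  expect_equal(sum(lat$status == 1L), 36L)
  # occupied sites carry the seed state; empty sites carry none
  stems <- which(lat$status == 1L)
  expect_true(all(lat$state[stems, "lef_tcf"] > 0))
  expect_true(all(lat$state[-stems, ] == 0))
  expect_error(seed_stem(lat, stems[1], p), "occupied")
})

test_that("lattice snapshots export one labelled row per site", {
  lat <- small_lattice()
  df <- as.data.frame(lat)
  expect_equal(nrow(df), lat$n_sites)
  expect_equal(sum(df$status == "stem"), 4)
  expect_setequal(unique(df$status), c("stem", "empty"))
  expect_equal(df$site, seq_len(lat$n_sites))
  expect_true(all(df$row >= 1 & df$row <= lat$n_rows))
  expect_true(all(df$col >= 1 & df$col <= lat$n_cols))
})
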