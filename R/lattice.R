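#' Toroidal honeycomb lattice
#'
#' Builds the tissue grid: a hexagonal lattice with even-row-offset indexing,
#' periodic in both directions ("closed surface"), so every site has exactly
#' six distinct neighbors and no edge effects exist. The default 40 x 20
#' geometry holds 800 sites. Sites are indexed row-major (`site = (row - 1) *
#' n_cols + col`). Each site is empty, holds a stem cell (with intracellular
#' state), or holds a differentiated cell (with E-cadherin frozen at its
#' level at the moment of differentiation and a scheduled death time).
#'
#' @param n_cols,n_rows Grid dimensions; `n_rows` must be even (parity of the
#'   hexagonal row offset must survive the vertical wrap) and at least 4,
#'   `n_cols` at least 3, so that the six neighbors are distinct.
#' @return A list of class `hca_lattice` with elements `n_cols`, `n_rows`,
#'   `n_sites`, `nb` (n x 6 neighbor index matrix), `status` (0 empty,
#'   1 stem, 2 differentiated), `state` (n x 8 matrix of intracellular
#'   levels and time of last division), `frozen_ecad`, `death_time`.
#' @examples
#' lat <- hex_lattice()
#' lat$n_sites              # 800
#' hex_neighbors(lat, 1)    # six distinct sites
#' @export
hex_lattice <- function(n_cols = 40, n_rows = 20) {
  stopifnot(n_cols >= 3, n_rows >= 4, n_rows %% 2 == 0)
  n <- n_cols * n_rows
  nb <- hex_neighbor_matrix(n_cols, n_rows)
  structure(list(
    n_cols = n_cols, n_rows = n_rows, n_sites = n,
    nb = nb,
    status = integer(n),
    state = matrix(0, n, 8, dimnames = list(NULL, state_names())),
    frozen_ecad = numeric(n),
    death_time = rep(NA_real_, n)
  ), class = "hca_lattice")
}

state_names <- function() {
  c("dkk_produced", "lef_tcf", "ecad_total", "pf", "notch", "hes", "df",
    "time_of_last_division")
}

# Even-r offset hexagonal neighbors with periodic wrap (0-based internally);
# even rows are shifted half a cell to the right.
hex_neighbor_matrix <- function(n_cols, n_rows) {
  n <- n_cols * n_rows
  i <- seq_len(n) - 1L
  r <- i %/% n_cols
  c0 <- i %% n_cols
  shift <- r %% 2L == 0L  # even 0-based row: diagonal neighbors sit to the right
  dc_diag <- ifelse(shift, 1L, 0L)
  east <- (c0 + 1L) %% n_cols
  west <- (c0 - 1L) %% n_cols
  up <- (r - 1L) %% n_rows
  dn <- (r + 1L) %% n_rows
  nb <- cbind(
    e  = r * n_cols + east,
    w  = r * n_cols + west,
    ne = up * n_cols + (c0 + dc_diag) %% n_cols,
    nw = up * n_cols + (c0 + dc_diag - 1L) %% n_cols,
    se = dn * n_cols + (c0 + dc_diag) %% n_cols,
    sw = dn * n_cols + (c0 + dc_diag - 1L) %% n_cols
  )
  storage.mode(nb) <- "integer"
  nb + 1L
}

#' Neighbors of a site
#'
#' @param lattice An [hex_lattice()].
#' @param site_index Site index in `1:n_sites`.
#' @return Integer vector of the six distinct neighbor indices (directions
#'   east, west, north-east, north-west, south-east, south-west).
#' @export
hex_neighbors <- function(lattice, site_index) {
  check_site(lattice, site_index)
  lattice$nb[site_index, ]
}

#' @rdname hex_neighbors
#' @return `empty_neighbors()`: the subset of the six neighbors whose site is
#'   empty (possibly length zero), in direction order.
#' @export
empty_neighbors <- function(lattice, site_index) {
  nb <- hex_neighbors(lattice, site_index)
  nb[lattice$status[nb] == 0L]
}

check_site <- function(lattice, site_index) {
  if (!is.numeric(site_index) || length(site_index) != 1L ||
      is.na(site_index) || site_index < 1 || site_index > lattice$n_sites ||
      site_index != as.integer(site_index)) {
    stop("invalid site index")
  }
  invisible(site_index)
}

#' Site occupancy counts
#'
#' @param lattice An [hex_lattice()].
#' @return Named integer vector `c(stem, differentiated, empty)`.
#' @export
occupancy <- function(lattice) {
  c(stem = sum(lattice$status == 1L),
    differentiated = sum(lattice$status == 2L),
    empty = sum(lattice$status == 0L))
}

#' Bound E-cadherin of a stem cell
#'
#' The E-cadherin bound towards the neighbor in direction `i` is
#' `kappa * min(E_self, E_i)`, where `E_i` is the neighbor occupant's
#' E-cadherin level (current level for a stem neighbor, the frozen level for
#' a differentiated neighbor, 0 for an empty site); the total is the sum over
#' the six directions.
#'
#' @param lattice An [hex_lattice()].
#' @param site_index Index of a site holding a stem cell.
#' @param kappa Binding coefficient in (0, 1].
#' @return List with `per_direction` (length 6) and `total`.
#' @export
bound_ecadherin <- function(lattice, site_index, kappa) {
  check_site(lattice, site_index)
  if (lattice$status[site_index] != 1L) stop("site does not hold a stem cell")
  e_self <- lattice$state[site_index, "ecad_total"]
  nb <- lattice$nb[site_index, ]
  e_nb <- neighbor_ecad(lattice, nb)
  bi <- kappa * pmin(e_self, e_nb)
  list(per_direction = bi, total = sum(bi))
}

neighbor_ecad <- function(lattice, nb) {
  st <- lattice$status[nb]
  ifelse(st == 1L, lattice$state[nb, "ecad_total"],
         ifelse(st == 2L, lattice$frozen_ecad[nb], 0))
}

#' DSL ligand available to a stem cell
#'
#' Every living (stem or differentiated) neighbor presents a constant DSL
#' level `d0`; the available ligand is the sum over occupied neighbor sites.
#'
#' @param lattice An [hex_lattice()].
#' @param site_index Index of a site holding a stem cell.
#' @param d0 DSL presentation level per living cell.
#' @return Total available DSL (level units).
#' @export
dsl_available <- function(lattice, site_index, d0) {
  check_site(lattice, site_index)
  if (lattice$status[site_index] != 1L) stop("site does not hold a stem cell")
  d0 * sum(lattice$status[lattice$nb[site_index, ]] > 0L)
}

#' Activated Notch level
#'
#' Juxtacrine Notch activation is limited by whichever is scarcer: the
#' cell's total Notch receptor or the DSL ligand presented by its neighbors.
#'
#' @param notch_total Total Notch receptor level (>= 0).
#' @param dsl_sum Total available DSL (>= 0).
#' @return `min(notch_total, dsl_sum)` (vectorized).
#' @export
activated_notch <- function(notch_total, dsl_sum) {
  if (any(notch_total < 0) || any(dsl_sum < 0)) {
    stop("activated_notch inputs must be non-negative")
  }
  pmin(notch_total, dsl_sum)
}

#' Initial state of a seeded stem cell
#'
#' Seeded cells start Wnt-active but Notch-naive, as for cells freshly
#' plated from suspension: LEF/TCF, E-cadherin and the secreted Dkk1 pool
#' at the quasi-steady levels of an isolated untreated cell (no bound
#' E-cadherin, no exogenous Dkk1), the Notch receptor at its contact-free
#' baseline (synthesis over maximal degradation), and the fate factors PF,
#' HES and DF at zero, so the proliferation/differentiation race starts
#' from a clean slate while the quorum signal is live from the outset.
#'
#' @param params An [sc_params()] set.
#' @return A [cell_state()].
#' @export
seed_cell_state <- function(params) {
  w <- wnt_signal(params$wnt_ext, 0, params)
  l0 <- w * params$lef_ecad_curve$vmax / params$lef_deg
  cell_state(
    dkk_produced = regulatory(l0, params$dkk_synth_curve) / params$dkk_deg,
    lef_tcf = l0,
    ecad_total = regulatory(l0, params$ecad_synth_curve) / params$ecad_deg,
    pf = 0,
    notch = params$notch_synth / params$notch_deg_curve$vmax,
    hes = 0, df = 0, time_of_last_division = 0
  )
}

#' Seed stem cells onto a lattice
#'
#' `seed_stem()` places stem cells at given sites; `seed_random()` places `k`
#' stem cells uniformly at random among all sites by rejection sampling
#' (repeated single uniform draws, so the compiled and the R engines consume
#' the random number stream identically).
#'
#' @param lattice An [hex_lattice()].
#' @param sites Integer site indices (must be empty).
#' @param params An [sc_params()] set (for the initial cell state).
#' @param k Number of cells to place.
#' @return The modified lattice.
#' @export
seed_stem <- function(lattice, sites, params) {
  stopifnot(all(sites >= 1), all(sites <= lattice$n_sites))
  if (any(lattice$status[sites] != 0L)) stop("cannot seed an occupied site")
  st <- seed_cell_state(params)
  lattice$status[sites] <- 1L
  lattice$state[sites, ] <- matrix(unclass(st), length(sites), 8, byrow = TRUE)
  lattice
}

#' @rdname seed_stem
#' @export
seed_random <- function(lattice, k, params) {
  stopifnot(k >= 1, k <= lattice$n_sites)
  chosen <- integer(0)
  while (length(chosen) < k) {
    cand <- floor(runif(1) * lattice$n_sites) + 1
    if (cand > lattice$n_sites) cand <- lattice$n_sites  # runif(1) == 1 guard
    if (!(cand %in% chosen)) chosen <- c(chosen, as.integer(cand))
  }
  seed_stem(lattice, chosen, params)
}

#' Lattice snapshot as a data frame
#'
#' One row per site: index, row, column, status and the intracellular levels
#' (zero for empty sites; differentiated sites report the frozen E-cadherin).
#'
#' @param x An [hex_lattice()].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A `data.frame` with `n_sites` rows.
#' @export
as.data.frame.hca_lattice <- function(x, row.names = NULL, optional = FALSE, ...) {
  i <- seq_len(x$n_sites)
  status <- c("empty", "stem", "differentiated")[x$status + 1L]
  df <- data.frame(
    site = i,
    row = (i - 1L) %/% x$n_cols + 1L,
    col = (i - 1L) %% x$n_cols + 1L,
    status = status,
    x$state,
    frozen_ecad = x$frozen_ecad,
    death_time = x$death_time
  )
  rownames(df) <- NULL
  df
}
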