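#' Boundary-energy coefficient of a neighbour pair
#'
#' Classifies an adjacent pair of spins and returns the interaction
#' coefficient J its boundary contributes. Same-cell pairs (Kronecker
#' delta = 1) contribute 0, as do two ECM sites. Otherwise the
#' coefficient is `j_ecm` if either site is ECM, `j_dark` for two dark
#' cells, `j_light` for two light cells and `j_mixed` for a dark-light
#' contact.
#'
#' @param sigma_a,sigma_b Spin indices (vectorized).
#' @param params A [sim_params()] object.
#' @return Numeric vector of per-pair coefficients.
#' @export
pair_coefficient <- function(sigma_a, sigma_b, params) {
  a <- as.integer(sigma_a)
  b <- as.integer(sigma_b)
  out <- numeric(length(a))
  diff <- a != b
  ecm <- diff & (a == 0L | b == 0L)
  odd_a <- a %% 2L == 1L
  odd_b <- b %% 2L == 1L
  dark <- diff & !ecm & odd_a & odd_b
  light <- diff & !ecm & !odd_a & !odd_b
  mixed <- diff & !ecm & (odd_a != odd_b)
  out[ecm] <- params$j_ecm
  out[dark] <- params$j_dark
  out[light] <- params$j_light
  out[mixed] <- params$j_mixed
  out
}

#' Enumerate adjacent site pairs and their same-cell indicator
#'
#' Lists every unordered lattice-adjacent site pair of the 4-neighbour
#' (von Neumann) graph with non-periodic boundaries, together with the
#' spins carried and the Kronecker delta indicator (`same_cell`) used by
#' the boundary-energy term: 1 when both sites belong to the same cell,
#' 0 otherwise.
#'
#' @param state A `cpm_state`.
#' @return A data frame with columns `site_a`, `site_b` (site keys
#'   `"x_y"`, 0-based column/row), `sigma_a`, `sigma_b` and `same_cell`.
#' @export
neighbour_pairs <- function(state) {
  g <- state$grid
  ny <- nrow(g)
  nx <- ncol(g)
  key <- function(row, col) paste0(col - 1L, "_", row - 1L)
  rows <- cols <- rows2 <- cols2 <- integer(0)
  if (ny > 1L) { # vertical pairs
    idx <- expand.grid(row = seq_len(ny - 1L), col = seq_len(nx))
    rows <- idx$row; cols <- idx$col
    rows2 <- idx$row + 1L; cols2 <- idx$col
  }
  if (nx > 1L) { # horizontal pairs
    idx <- expand.grid(row = seq_len(ny), col = seq_len(nx - 1L))
    rows <- c(rows, idx$row); cols <- c(cols, idx$col)
    rows2 <- c(rows2, idx$row); cols2 <- c(cols2, idx$col + 1L)
  }
  sa <- g[cbind(rows, cols)]
  sb <- g[cbind(rows2, cols2)]
  data.frame(
    site_a = key(rows, cols), site_b = key(rows2, cols2),
    sigma_a = sa, sigma_b = sb,
    same_cell = as.integer(sa == sb),
    stringsAsFactors = FALSE
  )
}

#' Boundary (adhesion) energy of a lattice state
#'
#' Sum over all unordered adjacent site pairs of
#' `(1 - delta) * J(pair class)`: each unlike pair contributes its
#' [pair_coefficient()] once, same-cell pairs contribute nothing.
#' Adjacency is the 4-neighbour von Neumann graph with non-periodic
#' boundaries.
#'
#' @param state A `cpm_state`.
#' @param params A [sim_params()] object.
#' @return The boundary energy (numeric scalar).
#' @export
boundary_energy <- function(state, params) {
  g <- state$grid
  ny <- nrow(g)
  nx <- ncol(g)
  e <- 0
  if (ny > 1L) {
    e <- e + sum(pair_coefficient(g[-ny, , drop = FALSE],
                                  g[-1L, , drop = FALSE], params))
  }
  if (nx > 1L) {
    e <- e + sum(pair_coefficient(g[, -nx, drop = FALSE],
                                  g[, -1L, drop = FALSE], params))
  }
  e
}

#' Area-elasticity (volume) energy of a lattice state
#'
#' `lambda * sum over cells of (area - target_area)^2`. The ECM (spin 0)
#' is excluded: its target area is suppressed by default.
#'
#' @inheritParams boundary_energy
#' @return The volume energy (numeric scalar, >= 0 for `lam >= 0`).
#' @export
volume_energy <- function(state, params) {
  params$lam * sum((state$cells$area - state$cells$target_area)^2)
}

#' Full CPM Hamiltonian
#'
#' Total configuration energy: the boundary adhesion term plus the
#' area-elasticity term, with the decomposition recorded.
#'
#' @inheritParams boundary_energy
#' @return A `cpm_energy` object: list with `boundary`, `volume` and
#'   `total` (`total == boundary + volume`).
#' @examples
#' p <- sim_params(x = 2, y = 2, max_sigma = 2, lam = 0)
#' st <- lattice_state(matrix(c(1L, 2L, 2L, 1L), 2, 2), p)
#' hamiltonian(st, p)$total  # 4 mixed contacts x j_mixed
#' @export
hamiltonian <- function(state, params) {
  b <- boundary_energy(state, params)
  v <- volume_energy(state, params)
  structure(list(boundary = b, volume = v, total = b + v),
            class = "cpm_energy")
}

#' @export
print.cpm_energy <- function(x, ...) {
  cat(sprintf("H = %.6g (boundary %.6g + volume %.6g)\n",
              x$total, x$boundary, x$volume))
  invisible(x)
}

# Scalar pair coefficient on the fast path of delta_h / the MCS kernel.
pair_j <- function(a, b, params) {
  if (a == b) return(0)
  if (a == 0L || b == 0L) return(params$j_ecm)
  if (a %% 2L == 1L) {
    if (b %% 2L == 1L) params$j_dark else params$j_mixed
  } else {
    if (b %% 2L == 1L) params$j_mixed else params$j_light
  }
}

# Linear (column-major) indices of the von Neumann neighbours of site i
# on a ny x nx grid, in fixed order: up, down, left, right.
site_neighbours <- function(i, ny, nx) {
  row <- ((i - 1L) %% ny) + 1L
  col <- ((i - 1L) %/% ny) + 1L
  nbs <- integer(0)
  if (row > 1L) nbs <- c(nbs, i - 1L)
  if (row < ny) nbs <- c(nbs, i + 1L)
  if (col > 1L) nbs <- c(nbs, i - ny)
  if (col < nx) nbs <- c(nbs, i + ny)
  nbs
}

# Incremental energy change if site `target` (linear index) adopts spin
# `s_new`; only the boundary pairs touching the target and the two
# affected cells' volume terms are revisited.
delta_h_index <- function(grid, areas, target_areas, target, s_new, params) {
  s_old <- grid[target]
  if (s_old == s_new) return(0)
  nbs <- site_neighbours(target, nrow(grid), ncol(grid))
  d <- 0
  for (j in nbs) {
    sj <- grid[j]
    d <- d + pair_j(s_new, sj, params) - pair_j(s_old, sj, params)
  }
  if (params$lam != 0) {
    dv <- 0
    if (s_old > 0L) {
      a <- areas[s_old] - target_areas[s_old]
      dv <- dv + (a - 1)^2 - a^2
    }
    if (s_new > 0L) {
      a <- areas[s_new] - target_areas[s_new]
      dv <- dv + (a + 1)^2 - a^2
    }
    d <- d + params$lam * dv
  }
  d
}

#' Energy change of a proposed spin copy
#'
#' Computes `H(after) - H(before)` for the proposal in which
#' `target_site` adopts the spin currently carried by the adjacent
#' `source_site`. The computation is incremental (only the boundary
#' pairs touching the target and the two affected cells' volume terms
#' are revisited) and equals a full Hamiltonian recomputation to within
#' numerical round-off.
#'
#' @param state A `cpm_state` whose registry is consistent with its grid.
#' @param target_site,source_site Length-2 integer vectors `c(row, col)`,
#'   1-based; the sites must be 4-neighbour adjacent.
#' @param params A [sim_params()] object.
#' @return The energy difference (numeric scalar); 0 when both sites
#'   already carry the same spin.
#' @export
delta_h <- function(state, target_site, source_site, params) {
  ny <- nrow(state$grid)
  nx <- ncol(state$grid)
  ts <- as.integer(target_site)
  ss <- as.integer(source_site)
  ok <- function(s) length(s) == 2L && all(s >= 1L) &&
    s[1] <= ny && s[2] <= nx
  if (!ok(ts) || !ok(ss)) {
    stop("sites must be 1-based c(row, col) within the lattice",
         call. = FALSE)
  }
  if (sum(abs(ts - ss)) != 1L) {
    stop("source_site must be 4-neighbour adjacent to target_site",
         call. = FALSE)
  }
  target <- (ts[2] - 1L) * ny + ts[1]
  source <- (ss[2] - 1L) * ny + ss[1]
  areas <- state$cells$area
  delta_h_index(state$grid, areas, state$cells$target_area,
                target, state$grid[source], params)
}

#' Metropolis acceptance probability of a spin copy
#'
#' A proposal that does not raise the energy is always accepted. An
#' energy-raising proposal is accepted with Boltzmann probability
#' `exp(-delta / T)` when `T > 0`; at zero or negative temperature all
#' uphill moves are rejected (spin changes that lower or conserve energy
#' still occur).
#'
#' @param delta Energy change of the proposal (vectorized).
#' @param temperature Motility factor T (scalar).
#' @return Probabilities in `[0, 1]`, same length as `delta`.
#' @examples
#' acceptance_probability(-5, 10)  # 1
#' acceptance_probability(10, 10)  # exp(-1)
#' @export
acceptance_probability <- function(delta, temperature) {
  if (any(!is.finite(delta))) stop("delta must be finite", call. = FALSE)
  p <- numeric(length(delta))
  down <- delta <= 0
  p[down] <- 1
  if (temperature > 0) {
    p[!down] <- exp(-delta[!down] / temperature)
  }
  p
}
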