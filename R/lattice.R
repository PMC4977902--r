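#' Per-cell target areas
#'
#' The target area of a cell is the lattice area shared equally among all
#' cells, scaled by its class's target-area factor:
#' `A_t(sigma) = factor_tau(sigma) * x * y / max_sigma`. The ECM (spin 0)
#' carries no target area.
#'
#' @param params A [sim_params()] object.
#' @return A numeric vector of length `max_sigma`; element `s` is the
#'   target area of the cell with spin `s` (names are the spin indices).
#' @examples
#' compute_target_areas(sim_params(x = 10, y = 10, max_sigma = 4,
#'                                 target_area_factor_dark = 0.4,
#'                                 target_area_factor_light = 0.2))
#' @export
compute_target_areas <- function(params) {
  validate_params(params)
  sigma <- seq_len(params$max_sigma)
  base <- params$x * params$y / params$max_sigma
  factor <- ifelse(sigma %% 2L == 1L,
                   params$target_area_factor_dark,
                   params$target_area_factor_light)
  stats::setNames(factor * base, sigma)
}

# Build the per-cell registry for a given grid.
build_registry <- function(grid, params) {
  sigma <- seq_len(params$max_sigma)
  data.frame(
    sigma = sigma,
    tau = sigma_class(sigma),
    area = tabulate(grid, nbins = params$max_sigma),
    target_area = unname(compute_target_areas(params)),
    stringsAsFactors = FALSE
  )
}

#' Construct a lattice state from a spin grid
#'
#' Wraps an explicit spin matrix into a `cpm_state`, building the cell
#' registry (class, area, target area) from the grid. Useful for tests
#' and for setting up hand-crafted configurations.
#'
#' @param grid Integer matrix with `params$y` rows and `params$x` columns;
#'   entries are spins in `0:max_sigma` (0 = ECM).
#' @param params A [sim_params()] object.
#' @param step_count Completed MCS count recorded in the state (default 0).
#' @return A `cpm_state` object: a list with elements `grid` (the spin
#'   matrix), `cells` (the registry data frame) and `step_count`.
#' @examples
#' p <- sim_params(x = 2, y = 2, max_sigma = 2)
#' st <- lattice_state(matrix(c(1L, 2L, 2L, 1L), 2, 2), p)
#' st$cells
#' @export
lattice_state <- function(grid, params, step_count = 0L) {
  validate_params(params)
  grid <- matrix(as.integer(grid), nrow = params$y, ncol = params$x)
  if (any(is.na(grid)) || any(grid < 0L) || any(grid > params$max_sigma)) {
    stop("grid entries must be spins in 0:max_sigma", call. = FALSE)
  }
  st <- list(grid = grid, cells = build_registry(grid, params),
             step_count = as.integer(step_count))
  class(st) <- "cpm_state"
  st
}

#' Randomly initialize the lattice
#'
#' Each site is independently occupied by a cellular brick with
#' probability `matrix_density`, otherwise it is ECM. Each occupied site
#' is dark with probability `r / (1 + r)` (r = `dark_light_ratio`), else
#' light, and is then assigned uniformly to one of that class's spin
#' indices (odd spins are dark, even spins light). With `max_sigma = 1`
#' no light spin exists and every occupied site belongs to the single
#' dark cell.
#'
#' Draw order (fixed for reproducibility): one occupancy uniform per site
#' in column-major order, then one class uniform per occupied site, then
#' the dark spin assignments, then the light spin assignments.
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed; defaults to `params$seed`. Pass `NULL` to draw
#'   from the current RNG state (used internally by [run_simulation()],
#'   which seeds the stream once).
#' @return A `cpm_state` (see [lattice_state()]) with `step_count = 0`.
#' @examples
#' st <- initialize_lattice(sim_params(seed = 1))
#' st$cells
#' @export
initialize_lattice <- function(params, seed = params$seed) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$x * params$y
  grid <- integer(n)
  occupied <- stats::runif(n) < params$matrix_density
  k <- sum(occupied)
  if (k > 0L) {
    if (params$max_sigma == 1L) {
      grid[occupied] <- 1L
    } else {
      r <- params$dark_light_ratio
      dark <- stats::runif(k) < r / (1 + r)
      odd <- seq.int(1L, params$max_sigma, by = 2L)
      even <- seq.int(2L, params$max_sigma, by = 2L)
      spin <- integer(k)
      spin[dark] <- odd[sample.int(length(odd), sum(dark), replace = TRUE)]
      spin[!dark] <- even[sample.int(length(even), sum(!dark),
                                     replace = TRUE)]
      grid[occupied] <- spin
    }
  }
  lattice_state(matrix(grid, nrow = params$y, ncol = params$x), params)
}

#' Recount a cell's area from the grid
#'
#' Exact count of lattice sites carrying the given spin; the independent
#' oracle for the registry's bookkeeping (`state$cells$area`).
#'
#' @param state A `cpm_state`.
#' @param sigma A spin index: 0 (ECM) or a registered cell index.
#' @return Integer site count.
#' @export
cell_area <- function(state, sigma) {
  sigma <- as.integer(sigma)
  if (length(sigma) != 1L || is.na(sigma) ||
      (sigma != 0L && !sigma %in% state$cells$sigma)) {
    stop("unknown spin index: ", sigma, call. = FALSE)
  }
  sum(state$grid == sigma)
}

#' @export
print.cpm_state <- function(x, ...) {
  dims <- dim(x$grid)
  counts <- class_counts(x$grid, nrow(x$cells))
  cat(sprintf("CPM lattice state: %d x %d sites, %d cells, %d MCS done\n",
              dims[2], dims[1], nrow(x$cells), x$step_count))
  cat(sprintf("  bricks: %d dark, %d light, %d ECM\n",
              counts[["dark"]], counts[["light"]], counts[["ecm"]]))
  invisible(x)
}

# Named brick totals per class (ecm/dark/light) for a grid.
class_counts <- function(grid, max_sigma) {
  areas <- tabulate(grid, nbins = max_sigma)
  sigma <- seq_len(max_sigma)
  c(ecm = length(grid) - sum(areas),
    dark = sum(areas[sigma %% 2L == 1L]),
    light = sum(areas[sigma %% 2L == 0L]))
}
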