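# One Metropolis spin-copy attempt on the raw grid/area bookkeeping.
# Draw order: target site, neighbour choice, then (only if the spins
# differ) one acceptance uniform. Returns updated grid/areas + flag.
attempt_impl <- function(grid, areas, target_areas, params) {
  n <- length(grid)
  i <- sample.int(n, 1L)
  nbs <- site_neighbours(i, nrow(grid), ncol(grid))
  if (length(nbs) == 0L) { # 1x1 lattice: no valid neighbour
    return(list(grid = grid, areas = areas, accepted = FALSE))
  }
  j <- if (length(nbs) == 1L) nbs else nbs[sample.int(length(nbs), 1L)]
  s_new <- grid[j]
  s_old <- grid[i]
  if (s_new == s_old) {
    return(list(grid = grid, areas = areas, accepted = FALSE))
  }
  d <- delta_h_index(grid, areas, target_areas, i, s_new, params)
  p <- if (d <= 0) 1 else if (params$temperature > 0) {
    exp(-d / params$temperature)
  } else 0
  u <- stats::runif(1L)
  accepted <- u < p
  if (accepted) {
    grid[i] <- s_new
    if (s_old > 0L) areas[s_old] <- areas[s_old] - 1L
    if (s_new > 0L) areas[s_new] <- areas[s_new] + 1L
  }
  list(grid = grid, areas = areas, accepted = accepted)
}

#' Attempt one random spin copy
#'
#' Picks a uniformly random target site and a uniformly random one of its
#' 4-neighbours (the source). If both carry the same spin the attempt is
#' a no-op. Otherwise the target adopts the source's spin with the
#' Metropolis probability [acceptance_probability()] applied to the
#' incremental energy change [delta_h()]. Uses the current RNG state;
#' seed beforehand (e.g. `set.seed()`) for reproducibility.
#'
#' @param state A `cpm_state`.
#' @param params A [sim_params()] object.
#' @return A list with `state` (updated) and `accepted` (logical).
#' @export
attempt_spin_copy <- function(state, params) {
  res <- attempt_impl(state$grid, state$cells$area,
                      state$cells$target_area, params)
  state$grid <- res$grid
  state$cells$area <- res$areas
  list(state = state, accepted = res$accepted)
}

# Summary bookkeeping recorded after each MCS (and at step 0).
make_step_stats <- function(mcs_index, attempts, accepted, areas, n_sites) {
  sigma <- seq_along(areas)
  list(
    mcs_index = as.integer(mcs_index),
    attempts = as.integer(attempts),
    accepted = as.integer(accepted),
    brick_counts = stats::setNames(as.integer(areas), sigma),
    class_counts = c(
      ecm = n_sites - sum(areas),
      dark = sum(areas[sigma %% 2L == 1L]),
      light = sum(areas[sigma %% 2L == 0L])
    )
  )
}

#' Advance the simulation by one Monte Carlo step
#'
#' Executes exactly `substeps` spin-copy attempts, then (if
#' `target_growth_rate` is non-zero) increments every cell's target area
#' by that rate — a growing cell's target volume grows with it. Emits a
#' warning at the first step of a run when `mcs * substeps < x * y`,
#' a time budget known to produce under-sampled dynamics.
#'
#' @param state A `cpm_state`.
#' @param params A [sim_params()] object.
#' @return A list with `state` (advanced by one MCS) and `stats`, the
#'   step's bookkeeping: `mcs_index`, `attempts`, `accepted`,
#'   `brick_counts` (per spin) and `class_counts` (ecm/dark/light).
#' @export
run_mcs <- function(state, params) {
  validate_params(params)
  if (state$step_count == 0L &&
      params$mcs * params$substeps < params$x * params$y) {
    warning(sprintf(
      "mcs * substeps (%d) is below the site count x * y (%d); ",
      params$mcs * params$substeps, params$x * params$y),
      "expect under-sampled dynamics", call. = FALSE)
  }
  grid <- state$grid
  areas <- state$cells$area
  targets <- state$cells$target_area
  accepted <- 0L
  for (s in seq_len(params$substeps)) {
    res <- attempt_impl(grid, areas, targets, params)
    grid <- res$grid
    areas <- res$areas
    if (res$accepted) accepted <- accepted + 1L
  }
  if (params$target_growth_rate != 0) {
    targets <- targets + params$target_growth_rate
  }
  state$grid <- grid
  state$cells$area <- areas
  state$cells$target_area <- targets
  state$step_count <- state$step_count + 1L
  stats <- make_step_stats(state$step_count, params$substeps, accepted,
                           areas, length(grid))
  list(state = state, stats = stats)
}

#' Run a full seeded simulation
#'
#' Seeds the RNG from `params$seed`, initializes the lattice
#' ([initialize_lattice()]) and advances it by `params$mcs` Monte Carlo
#' steps, recording bookkeeping after initialization (step 0) and after
#' every MCS. One RNG stream in a fixed draw order drives both
#' initialization and dynamics, so runs are bit-reproducible.
#'
#' @param params A [sim_params()] object.
#' @param keep_state Keep the final `cpm_state` in the result
#'   (default `TRUE`).
#' @return A `cpm_trajectory`: list with `steps` (length `mcs + 1`, see
#'   [run_mcs()] for the per-step fields), `params`, and `final_state`
#'   (when `keep_state`).
#' @examples
#' traj <- run_simulation(sim_params(seed = 1))
#' length(traj$steps)  # mcs + 1
#' @export
run_simulation <- function(params, keep_state = TRUE) {
  validate_params(params)
  set.seed(params$seed)
  state <- initialize_lattice(params, seed = NULL)
  n_sites <- params$x * params$y
  steps <- vector("list", params$mcs + 1L)
  steps[[1L]] <- make_step_stats(0L, 0L, 0L, state$cells$area, n_sites)
  for (m in seq_len(params$mcs)) {
    res <- run_mcs(state, params)
    state <- res$state
    steps[[m + 1L]] <- res$stats
  }
  traj <- list(steps = steps, params = params,
               final_state = if (keep_state) state else NULL)
  class(traj) <- "cpm_trajectory"
  traj
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  first <- x$steps[[1L]]$class_counts
  last <- x$steps[[length(x$steps)]]$class_counts
  cat(sprintf("CPM trajectory: %d recorded steps (%d MCS), seed %d\n",
              length(x$steps), x$params$mcs, x$params$seed))
  cat(sprintf("  dark %d -> %d, light %d -> %d, ECM %d -> %d bricks\n",
              first[["dark"]], last[["dark"]], first[["light"]],
              last[["light"]], first[["ecm"]], last[["ecm"]]))
  invisible(x)
}

#' Tabulate a trajectory
#'
#' One row per recorded step: the step index, per-spin brick counts
#' (`sigma_1`, `sigma_2`, ...), class totals, the dark/light brick ratio
#' (`NA` when no light bricks exist) and acceptance bookkeeping. This is
#' the table [export_csv()] writes.
#'
#' @param x A `cpm_trajectory`.
#' @param ... Unused.
#' @return A data frame with `mcs + 1` rows.
#' @export
as.data.frame.cpm_trajectory <- function(x, ...) {
  k <- x$params$max_sigma
  bricks <- matrix(unlist(lapply(x$steps,
                                 function(s) as.numeric(s$brick_counts))),
                   ncol = k, byrow = TRUE)
  colnames(bricks) <- paste0("sigma_", seq_len(k))
  cls <- matrix(unlist(lapply(x$steps,
                              function(s) as.numeric(s$class_counts))),
                ncol = 3L, byrow = TRUE)
  ratio <- ifelse(cls[, 3L] > 0, cls[, 2L] / cls[, 3L], NA_real_)
  data.frame(
    step = vapply(x$steps, `[[`, integer(1L), "mcs_index"),
    bricks,
    dark_total = as.integer(cls[, 2L]),
    light_total = as.integer(cls[, 3L]),
    ecm_total = as.integer(cls[, 1L]),
    dark_light_ratio = ratio,
    accepted = vapply(x$steps, `[[`, integer(1L), "accepted"),
    attempts = vapply(x$steps, `[[`, integer(1L), "attempts")
  )
}
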