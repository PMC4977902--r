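# Shared fixtures: tiny states built in code and a brute-force energy
# oracle independent of the incremental delta_h path.

# 2x2 checkerboard of one dark (1) and one light (2) cell.
checkerboard_state <- function(params = sim_params(x = 2, y = 2,
                                                   max_sigma = 2)) {
  list(state = lattice_state(matrix(c(1L, 2L, 2L, 1L), 2, 2), params),
       params = params)
}

# Random small state for oracle comparisons.
random_state <- function(params, seed) {
  initialize_lattice(params, seed = seed)
}

# Full-recompute oracle for the energy change of "target adopts source's
# spin": difference of two complete Hamiltonian evaluations.
full_delta_h <- function(state, target, source, params) {
  g2 <- state$grid
  g2[target[1], target[2]] <- state$grid[source[1], source[2]]
  after <- lattice_state(g2, params)
  hamiltonian(after, params)$total - hamiltonian(state, params)$total
}

# A random valid (target, source) adjacent pair on an ny x nx grid.
random_proposal <- function(ny, nx) {
  repeat {
    r <- sample.int(ny, 1L)
    c <- sample.int(nx, 1L)
    nb <- list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    nb <- Filter(function(s) s[1] >= 1 && s[1] <= ny &&
                   s[2] >= 1 && s[2] <= nx, nb)
    if (length(nb) > 0) {
      return(list(target = c(r, c), source = nb[[sample.int(length(nb), 1L)]]))
    }
  }
}

# Final-step class counts of a seeded run.
final_counts <- function(params) {
  tr <- run_simulation(params, keep_state = FALSE)
  tr$steps[[length(tr$steps)]]$class_counts
}
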