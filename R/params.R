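#' Simulation parameters for the Cellular Potts Model
#'
#' Constructs and validates the full parameter set of a simulation run.
#' Defaults are the package's default preset (see [load_preset()]): a
#' 32x32 lattice, 32 Monte Carlo steps of 64 spin-copy attempts each,
#' two cells (one dark tumor cell, one light normal cell), matrix density
#' 0.8 and temperature 10.
#'
#' @param x,y Lattice width and height in sites (integers >= 1).
#' @param mcs Number of Monte Carlo steps (MCS), the simulation time unit
#'   (integer >= 0).
#' @param substeps Spin-copy attempts per MCS (integer >= 1).
#' @param max_sigma Number of cells (cellular clusters), >= 1. Odd spin
#'   indices are dark (tumor) cells, even indices light (normal) cells;
#'   spin 0 is the extracellular matrix (ECM).
#' @param matrix_density Fraction of lattice sites initially occupied by
#'   cellular bricks rather than ECM, in `[0, 1]`.
#' @param temperature Motility factor T of the Metropolis rule. May be
#'   zero or negative, in which case energy-raising copies are rejected
#'   outright.
#' @param j_ecm,j_light,j_dark,j_mixed Boundary-energy coefficients for
#'   cell-ECM, light-light, dark-dark and dark-light neighbour pairs.
#' @param lam Area-elasticity coefficient lambda, >= 0.
#' @param target_area_factor_light,target_area_factor_dark Dimensionless
#'   factors scaling each class's target area; the target area of a cell
#'   is `factor * x * y / max_sigma`.
#' @param dark_light_ratio Initial dark:light brick ratio r (> 0); an
#'   occupied site is dark with probability `r / (1 + r)`.
#' @param target_growth_rate Per-MCS increment added to every cell's
#'   target area (default 0, i.e. static targets).
#' @param seed Integer RNG seed making runs bit-reproducible.
#'
#' @return An object of class `cpm_params` (a validated named list).
#' @examples
#' p <- sim_params(seed = 1)
#' p$temperature
#' @seealso [load_preset()], [run_simulation()]
#' @export
sim_params <- function(x = 32L, y = 32L, mcs = 32L, substeps = 64L,
                       max_sigma = 2L, matrix_density = 0.8,
                       temperature = 10, j_ecm = 16, j_light = 15,
                       j_dark = 2, j_mixed = 11, lam = 0.05,
                       target_area_factor_light = 0.4,
                       target_area_factor_dark = 0.4,
                       dark_light_ratio = 1 / 4,
                       target_growth_rate = 0, seed = 42L) {
  p <- list(
    x = as.integer(x), y = as.integer(y), mcs = as.integer(mcs),
    substeps = as.integer(substeps), max_sigma = as.integer(max_sigma),
    matrix_density = as.numeric(matrix_density),
    temperature = as.numeric(temperature),
    j_ecm = as.numeric(j_ecm), j_light = as.numeric(j_light),
    j_dark = as.numeric(j_dark), j_mixed = as.numeric(j_mixed),
    lam = as.numeric(lam),
    target_area_factor_light = as.numeric(target_area_factor_light),
    target_area_factor_dark = as.numeric(target_area_factor_dark),
    dark_light_ratio = as.numeric(dark_light_ratio),
    target_growth_rate = as.numeric(target_growth_rate),
    seed = as.integer(seed)
  )
  class(p) <- "cpm_params"
  validate_params(p)
  p
}

#' Validate a `cpm_params` object
#'
#' Checks every invariant of the parameter set and stops with an
#' informative message on the first violation.
#'
#' @param params A `cpm_params` object (or a named list with the same
#'   fields).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  need <- c("x", "y", "mcs", "substeps", "max_sigma", "matrix_density",
            "temperature", "j_ecm", "j_light", "j_dark", "j_mixed", "lam",
            "target_area_factor_light", "target_area_factor_dark",
            "dark_light_ratio", "target_growth_rate", "seed")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(params$x >= 1L, "x must be >= 1")
  chk(params$y >= 1L, "y must be >= 1")
  chk(params$mcs >= 0L, "mcs must be >= 0")
  chk(params$substeps >= 1L, "substeps must be >= 1")
  chk(params$max_sigma >= 1L, "max_sigma must be >= 1")
  chk(is.finite(params$matrix_density) &&
        params$matrix_density >= 0 && params$matrix_density <= 1,
      "matrix_density must lie in [0, 1]")
  chk(is.finite(params$temperature), "temperature must be finite")
  for (j in c("j_ecm", "j_light", "j_dark", "j_mixed")) {
    chk(is.finite(params[[j]]), paste(j, "must be a finite real"))
  }
  chk(is.finite(params$lam) && params$lam >= 0, "lam must be >= 0")
  chk(is.finite(params$target_area_factor_light) &&
        params$target_area_factor_light >= 0,
      "target_area_factor_light must be >= 0")
  chk(is.finite(params$target_area_factor_dark) &&
        params$target_area_factor_dark >= 0,
      "target_area_factor_dark must be >= 0")
  chk(is.finite(params$dark_light_ratio) && params$dark_light_ratio > 0,
      "dark_light_ratio must be > 0")
  chk(is.finite(params$target_growth_rate),
      "target_growth_rate must be finite")
  chk(!is.na(params$seed), "seed must be an integer")
  invisible(params)
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("Cellular Potts Model parameters\n")
  cat(sprintf("  lattice: %d x %d (%d sites), cells: %d\n",
              x$x, x$y, x$x * x$y, x$max_sigma))
  cat(sprintf("  time: %d MCS x %d substeps, seed %d\n",
              x$mcs, x$substeps, x$seed))
  cat(sprintf("  matrix density %.3g, dark:light ratio %.3g, T = %.3g\n",
              x$matrix_density, x$dark_light_ratio, x$temperature))
  cat(sprintf("  J (ecm, light, dark, mixed) = %.3g, %.3g, %.3g, %.3g\n",
              x$j_ecm, x$j_light, x$j_dark, x$j_mixed))
  cat(sprintf("  lambda %.3g, target-area factors (light %.3g, dark %.3g)",
              x$lam, x$target_area_factor_light, x$target_area_factor_dark))
  if (x$target_growth_rate != 0) {
    cat(sprintf(", target growth %+.3g/MCS", x$target_growth_rate))
  }
  cat("\n")
  invisible(x)
}

# Cell class of a spin index: 0 = ECM, odd = dark, even = light.
sigma_class <- function(sigma) {
  ifelse(sigma == 0L, "ecm", ifelse(sigma %% 2L == 1L, "dark", "light"))
}
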