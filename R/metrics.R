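#' Per-class brick-count time series
#'
#' Extracts the number of cellular bricks of one class ("dark", "light"
#' or "ecm") at each recorded step of a trajectory — the data behind the
#' steps-vs-bricks line chart. A single cell's series is available via
#' `sigma`.
#'
#' @param trajectory A `cpm_trajectory` from [run_simulation()].
#' @param which One of `"dark"`, `"light"`, `"ecm"`; ignored when `sigma`
#'   is given.
#' @param sigma Optional spin index whose per-cell series to return.
#' @return Integer vector of length `mcs + 1`.
#' @export
class_series <- function(trajectory, which = c("dark", "light", "ecm"),
                         sigma = NULL) {
  if (!is.null(sigma)) {
    sigma <- as.integer(sigma)
    if (sigma < 1L || sigma > trajectory$params$max_sigma) {
      stop("unknown spin index: ", sigma, call. = FALSE)
    }
    return(vapply(trajectory$steps,
                  function(s) as.integer(s$brick_counts[[sigma]]),
                  integer(1L)))
  }
  which <- match.arg(which)
  vapply(trajectory$steps,
         function(s) as.integer(s$class_counts[[which]]), integer(1L))
}

#' Dark/light brick-ratio time series
#'
#' Per-step ratio of dark to light brick totals. Steps with zero light
#' bricks yield `NA` (an undefined ratio, flagged rather than an error).
#'
#' @param trajectory A `cpm_trajectory`.
#' @return Numeric vector of length `mcs + 1`, `NA` where undefined.
#' @export
dark_light_ratio_series <- function(trajectory) {
  dark <- class_series(trajectory, "dark")
  light <- class_series(trajectory, "light")
  ifelse(light > 0L, dark / light, NA_real_)
}

#' Gompertz growth ratio
#'
#' The decelerating tumor-growth law in ratio form:
#' `V_t / V_0 = exp((a / b) * (1 - exp(-b * t)))`, with growth-rate
#' constant `a` and deceleration constant `b` (both > 0, per unit time).
#' The ratio is 1 at `t = 0`, strictly increasing in `t` and saturates at
#' `exp(a / b)`.
#'
#' @param t Time(s), >= 0 (vectorized).
#' @param a Growth-rate constant (> 0).
#' @param b Deceleration constant (> 0).
#' @return Size ratio(s) `V_t / V_0`.
#' @examples
#' gompertz_ratio(1, a = 1, b = 1)  # exp(1 - exp(-1))
#' @export
gompertz_ratio <- function(t, a, b) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp((a / b) * (1 - exp(-b * t)))
}

#' Fit a Gompertz growth curve to a count series
#'
#' Least-squares fit of [gompertz_ratio()] to a brick-count (or any
#' size) series normalized by its first value, on the ratio scale with
#' unweighted residuals. Uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) from heuristic starting values, with a
#' log-spaced grid search plus `L-BFGS-B` refinement as fallback. A fit
#' that cannot be obtained is returned flagged (`converged = FALSE`), not
#' raised as an error.
#'
#' @param series Numeric vector of counts, length >= 4, first value > 0.
#' @param times Time points (default `0, 1, ..., length(series) - 1`).
#' @return A `cpm_gompertz_fit`: list with `a`, `b`, `r_squared`,
#'   `fitted` (on the original count scale), and `converged`. For a
#'   perfectly flat series the residual and total sums of squares both
#'   vanish and `r_squared` is reported as 1.
#' @examples
#' y <- 100 * gompertz_ratio(0:20, a = 0.5, b = 0.2)
#' fit_gompertz(y)$a
#' @export
fit_gompertz <- function(series, times = seq_along(series) - 1) {
  no_fit <- function(reason) {
    structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                   fitted = NULL, converged = FALSE, reason = reason),
              class = "cpm_gompertz_fit")
  }
  series <- as.numeric(series)
  if (length(series) < 4L) return(no_fit("series shorter than 4 points"))
  if (any(!is.finite(series))) return(no_fit("non-finite values in series"))
  if (series[1L] <= 0) return(no_fit("first value must be > 0"))
  if (length(times) != length(series)) {
    stop("times and series lengths differ", call. = FALSE)
  }
  y <- series / series[1L]
  t <- as.numeric(times)

  sse <- function(a, b) sum((gompertz_ratio(t, a, b) - y)^2)
  # Heuristic starts: a from the initial log-slope, a/b from the plateau.
  dt <- max(t[2L] - t[1L], .Machine$double.eps)
  a0 <- max((log(max(y[2L], 1e-8)) - log(y[1L])) / dt, 1e-3)
  plateau <- max(log(max(y)), 1e-3)
  b0 <- max(a0 / plateau, 1e-4)

  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ exp((a / b) * (1 - exp(-b * t))),
      start = list(a = a0, b = b0),
      lower = c(a = 1e-9, b = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    as.list(stats::coef(m))
  }, error = function(e) NULL)

  if (is.null(fit)) {
    # Fallback: coarse log-spaced grid, then box-constrained refinement.
    grid <- expand.grid(a = 10^seq(-4, 1, length.out = 25),
                        b = 10^seq(-4, 1, length.out = 25))
    errs <- mapply(sse, grid$a, grid$b)
    best <- grid[which.min(errs), ]
    opt <- tryCatch(
      stats::optim(c(best$a, best$b),
                   function(p) sse(p[1L], p[2L]),
                   method = "L-BFGS-B", lower = c(1e-9, 1e-9)),
      error = function(e) NULL)
    if (is.null(opt)) return(no_fit("optimization failed"))
    fit <- list(a = opt$par[1L], b = opt$par[2L])
  }

  fitted_ratio <- gompertz_ratio(t, fit$a, fit$b)
  ss_res <- sum((y - fitted_ratio)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    if (ss_res <= 1e-10) 1 else NA_real_
  }
  structure(list(a = fit$a, b = fit$b, r_squared = r2,
                 fitted = fitted_ratio * series[1L], converged = TRUE,
                 reason = NULL),
            class = "cpm_gompertz_fit")
}

#' @export
print.cpm_gompertz_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gompertz fit: no fit (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Gompertz fit: a = %.4g, b = %.4g, plateau V/V0 = %.4g, R^2 = %.4f\n",
      x$a, x$b, exp(x$a / x$b), x$r_squared))
  }
  invisible(x)
}
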