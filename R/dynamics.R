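#' Default initial state for a competition run
#'
#' Resources start at their replenishment rates (`r1 = R1`, `r2 = R2`) and a
#' total consumer abundance of `total0` is split between specialist and
#' generalist according to the initial specialist frequency. Equilibrium
#' outcomes are initial-condition independent; the split matters only for
#' transients.
#'
#' @param p A `"cr_params"` object.
#' @param init_freq Initial specialist frequency in `[0, 1]`.
#' @param total0 Initial total consumer abundance (positive).
#' @return Named numeric state vector `(r1, r2, x1, x2)`.
#' @export
initial_state <- function(p, init_freq = 0.5, total0 = 1) {
  stopifnot(inherits(p, "cr_params"),
            init_freq >= 0, init_freq <= 1, total0 > 0)
  c(r1 = p$R1, r2 = p$R2,
    x1 = init_freq * total0, x2 = (1 - init_freq) * total0)
}

# log-spaced output grid including t = 0
log_time_grid <- function(t_end, n_out, t_min = 1e-4) {
  stopifnot(t_end > 0, n_out >= 2)
  t_min <- min(t_min, t_end / 10)
  c(0, 10^seq(log10(t_min), log10(t_end), length.out = n_out))
}

#' Integrate the competition dynamics
#'
#' Solves the two-resource, two-consumer system with a stiff-capable
#' adaptive solver (`deSolve::ode`, `lsoda`) on a logarithmically spaced
#' output grid, which resolves both the fast resource transient and
#' quasi-stable phases spanning up to ~1e12 time units. Abundances that
#' undershoot zero by numerical round-off (> -1e-8) are clipped to zero.
#'
#' @param p A `"cr_params"` object.
#' @param init Optional named state vector `(r1, r2, x1, x2)`; defaults to
#'   [initial_state()] with `init_freq`.
#' @param t_end Final time (arbitrary units, > 0).
#' @param n_out Number of (log-spaced) output times.
#' @param init_freq Initial specialist frequency used when `init` is NULL.
#' @param total0 Initial total consumer abundance used when `init` is NULL.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method `deSolve` integration method.
#' @return A `"cr_trajectory"`: a data frame with columns `time`, `r1`,
#'   `r2`, `x1`, `x2`, `freq` (specialist frequency), and the parameters in
#'   `attr(, "params")`.
#' @examples
#' tr <- integrate_dynamics(model_params(b = 100), t_end = 1e3)
#' tail(tr$freq, 1)
#' @export
integrate_dynamics <- function(p, init = NULL, t_end = 1e3, n_out = 400,
                               init_freq = 0.5, total0 = 1,
                               rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  stopifnot(inherits(p, "cr_params"), t_end > 0)
  if (is.null(init)) init <- initial_state(p, init_freq, total0)
  if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
  times <- log_time_grid(t_end, n_out)
  rhs <- function(t, y, parms) list(unname(ode_rhs(y, parms)))
  sol <- deSolve::ode(y = init[c("r1", "r2", "x1", "x2")], times = times,
                      func = rhs, parms = p, method = method,
                      rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed to converge; see deSolve diagnostics",
         call. = FALSE)
  out <- as.data.frame(unclass(sol))
  names(out) <- c("time", "r1", "r2", "x1", "x2")
  for (v in c("r1", "r2", "x1", "x2")) {
    neg <- out[[v]] < 0
    if (any(out[[v]] < -1e-8))
      warning("trajectory undershoots zero beyond round-off; tighten tolerances",
              call. = FALSE)
    out[[v]][neg] <- 0
  }
  tot <- out$x1 + out$x2
  out$freq <- ifelse(tot > 0, out$x1 / tot, 0)
  structure(out, params = p, class = c("cr_trajectory", "data.frame"))
}

#' Specialist frequency at a query time
#'
#' Integrates the dynamics from the default initial-condition policy and
#' returns the specialist frequency `x1/(x1+x2)` at `t_query`.
#'
#' @param p A `"cr_params"` object.
#' @param t_query Query time (> 0).
#' @param init_freq Initial specialist frequency.
#' @param ... Passed on to [integrate_dynamics()].
#' @return A frequency in `[0, 1]`.
#' @export
frequency_at_time <- function(p, t_query = 1e3, init_freq = 0.5, ...) {
  stopifnot(t_query > 0)
  tr <- integrate_dynamics(p, t_end = t_query, init_freq = init_freq, ...)
  tail(tr$freq, 1)
}

#' Time to reach the competition equilibrium
#'
#' The first output-grid time from which the specialist frequency stays
#' within `epsilon` of its analytic equilibrium value (0 when the
#' coexistence condition fails) for the remainder of the integration
#' horizon. The equilibrium criterion `epsilon` is a first-class knob and is
#' always reported alongside the result.
#'
#' @param p A `"cr_params"` object.
#' @param init_freq Initial specialist frequency.
#' @param epsilon Frequency tolerance defining "at equilibrium".
#' @param t_max Integration horizon.
#' @param n_out Output-grid resolution.
#' @param ... Passed on to [integrate_dynamics()].
#' @return A list with `t_eq` (NA when unreached), `reached`, `epsilon`,
#'   `f_target` and `f_last` (terminal frequency).
#' @examples
#' time_to_equilibrium(model_params(b = 100), t_max = 1e6)$t_eq
#' @export
time_to_equilibrium <- function(p, init_freq = 0.5, epsilon = 1e-3,
                                t_max = 1e14, n_out = 600, ...) {
  stopifnot(epsilon > 0)
  f_target <- specialist_equilibrium_frequency(p)
  tr <- integrate_dynamics(p, t_end = t_max, n_out = n_out,
                           init_freq = init_freq, ...)
  within <- abs(tr$freq - f_target) < epsilon
  # first index from which `within` holds through the end of the horizon
  sustained <- rev(cumprod(rev(within))) == 1
  idx <- which(sustained)[1]
  if (is.na(idx)) {
    return(list(t_eq = NA_real_, reached = FALSE, epsilon = epsilon,
                f_target = f_target, f_last = tail(tr$freq, 1)))
  }
  list(t_eq = tr$time[idx], reached = TRUE, epsilon = epsilon,
       f_target = f_target, f_last = tail(tr$freq, 1))
}

#' Sweep the competition outcome across body masses
#'
#' For each body mass: the specialist frequency at `t_query` (numerical),
#' the analytic equilibrium frequency, and optionally the time to
#' equilibrium. Under the default parameterization this reproduces the
#' high-low-high structure of specialist frequency across the size spectrum
#' at quasi-stability.
#'
#' @param masses Vector of body masses (g).
#' @param p Template `"cr_params"`; its `b` is replaced per mass.
#' @param t_query Query time for the numerical frequency.
#' @param init_freq Initial specialist frequency.
#' @param include_t_eq Also compute [time_to_equilibrium()] per mass
#'   (slower).
#' @param epsilon Equilibrium tolerance passed to [time_to_equilibrium()].
#' @param t_max Horizon passed to [time_to_equilibrium()].
#' @param ... Passed on to [integrate_dynamics()].
#' @return A data frame with columns `body_mass_g`, `t_query`, `f_at_t`,
#'   `f_star`, and (if requested) `t_eq`, `eq_reached`, `epsilon`.
#' @export
mass_sweep <- function(masses, p = model_params(b = 100), t_query = 1e3,
                       init_freq = 0.5, include_t_eq = FALSE,
                       epsilon = 1e-3, t_max = 1e14, ...) {
  stopifnot(length(masses) >= 1, all(masses > 0))
  rows <- lapply(masses, function(b) {
    pb <- suppressWarnings(update_params(p, b = b))
    row <- data.frame(body_mass_g = b, t_query = t_query,
                      f_at_t = frequency_at_time(pb, t_query, init_freq, ...),
                      f_star = specialist_equilibrium_frequency(pb))
    if (include_t_eq) {
      te <- time_to_equilibrium(pb, init_freq, epsilon, t_max, ...)
      row$t_eq <- te$t_eq
      row$eq_reached <- te$reached
      row$epsilon <- te$epsilon
    }
    row
  })
  do.call(rbind, rows)
}

#' Sweep one model parameter across a mass grid
#'
#' Repeats [mass_sweep()] for each value of a varied parameter, returning a
#' tidy table. Varying the mortality-shape parameters `beta`/`gamma` leaves
#' the analytic equilibrium frequency untouched but changes the timescale;
#' decreasing `alpha` or `R2` raises the specialist's equilibrium frequency
#' at every mass.
#'
#' @param vary One of `"k1"`, `"k2"`, `"alpha"`, `"beta"`, `"gamma"`,
#'   `"R1"`, `"R2"`, `"g"`, `"kappa"`.
#' @param values Values the varied parameter takes.
#' @param masses Vector of body masses (g).
#' @param p Template `"cr_params"`.
#' @param ... Passed on to [mass_sweep()].
#' @return A data frame with `parameter_name`, `parameter_value` plus the
#'   [mass_sweep()] columns.
#' @export
parameter_sweep <- function(vary, values, masses,
                            p = model_params(b = 100), ...) {
  allowed <- c("k1", "k2", "alpha", "beta", "gamma", "R1", "R2", "g", "kappa")
  if (!is.character(vary) || length(vary) != 1 || !vary %in% allowed)
    stop("`vary` must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  out <- lapply(values, function(v) {
    args <- stats::setNames(list(v), vary)
    pv <- do.call(update_params, c(list(p), args))
    cbind(parameter_name = vary, parameter_value = v,
          mass_sweep(masses, pv, ...))
  })
  do.call(rbind, out)
}

#' Write a sweep result as a tidy CSV
#'
#' Writes the output of [mass_sweep()] or [parameter_sweep()] with a header
#' comment recording the package version, so reruns are traceable.
#'
#' @param x Sweep data frame.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the header (the sweeps themselves
#'   are deterministic).
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# divergesize %s seed=%s",
                     as.character(utils::packageVersion("divergesize")), seed),
             con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}
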