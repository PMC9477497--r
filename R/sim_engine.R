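#' Solver settings
#'
#' @param rel_tol,abs_tol Integration tolerances (positive). The defaults are
#'   tight because reserve turnover is fast relative to structural growth and
#'   the mass-balance audit is expected to close to 1e-6.
#' @param max_step Maximum step size (d) or `NULL` for solver default.
#' @param stiff Use the stiff-capable `lsoda` switching method (default) or
#'   explicit `adams`.
#' @param t_span Length-2 numeric, integration window (d), `t1 > t0`.
#' @param record_every Output cadence (d).
#' @return List of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = NULL,
                            stiff = TRUE, t_span = c(0, 500),
                            record_every = 1) {
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("solver_settings: tolerances must be positive", call. = FALSE)
  if (length(t_span) != 2L || t_span[2L] <= t_span[1L])
    stop("solver_settings: t_span must be (t0, t1) with t1 > t0",
         call. = FALSE)
  if (record_every <= 0)
    stop("solver_settings: record_every must be positive", call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 stiff = stiff, t_span = as.numeric(t_span),
                 record_every = record_every),
            class = "solver_settings")
}

# clip tiny integrator undershoots; anything worse is a genuine failure
clip_nonneg <- function(y, tol = 1e-9, where = "state") {
  bad <- y < -tol
  if (any(bad)) {
    stop("negative ", where, " beyond tolerance: ",
         paste(names(y)[bad], format(y[bad]), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  pmax(y, 0)
}

#' Adaptive ODE integration with optional terminal event
#'
#' Thin wrapper around [deSolve::ode()] used by both models and by test
#' problems. States are projected onto the nonnegative orthant at every
#' recorded step (undershoots beyond 1e-9 raise an error rather than being
#' silently clipped). If `rootfunc` is supplied, integration terminates at
#' its first sign change and the crossing time is reported.
#'
#' @param func Function `(t, y) -> derivative vector` (named as `y`).
#' @param y0 Named numeric initial state.
#' @param settings [solver_settings()].
#' @param rootfunc Optional function `(t, y) -> numeric` whose zero crossing
#'   terminates integration.
#' @param times Optional explicit record times (overrides
#'   `t_span`/`record_every`).
#' @param nonneg Project states onto `>= 0` (default TRUE; disable for test
#'   problems with signed states).
#' @return List with `times`, `states` (matrix, one row per record) and
#'   `troot` (event time or `NA`).
#' @export
integrate_ode <- function(func, y0, settings = solver_settings(),
                          rootfunc = NULL, times = NULL, nonneg = TRUE) {
  if (is.null(times)) {
    times <- seq(settings$t_span[1L], settings$t_span[2L],
                 by = settings$record_every)
    if (times[length(times)] < settings$t_span[2L])
      times <- c(times, settings$t_span[2L])
  }
  nm <- names(y0)
  wrap <- function(t, y, parms) {
    names(y) <- nm
    if (nonneg) y <- clip_nonneg(y)
    list(func(t, y))
  }
  args <- list(y = y0, times = times, func = wrap, parms = NULL,
               method = if (settings$stiff) "lsoda" else "adams",
               rtol = settings$rel_tol, atol = settings$abs_tol)
  if (!is.null(settings$max_step)) args$hmax <- settings$max_step
  if (!is.null(rootfunc)) {
    args$rootfunc <- function(t, y, parms) {
      names(y) <- nm
      if (nonneg) y <- pmax(y, 0)
      rootfunc(t, y)
    }
  }
  out <- try(do.call(deSolve::ode, args), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integrate_ode: solver failure: ", attr(out, "condition")$message,
         call. = FALSE)
  states <- unname(as.matrix(out[, -1L, drop = FALSE]))
  colnames(states) <- nm
  if (nonneg) states <- t(apply(states, 1L, clip_nonneg))
  if (length(nm) == 1L) {
    states <- matrix(states, ncol = 1L, dimnames = list(NULL, nm))
  }
  troot <- attr(out, "troot")
  list(times = unname(out[, 1L]), states = states,
       troot = if (length(troot)) troot[1L] else NA_real_)
}

#' Simulate the root-shoot plant DEB model
#'
#' Integrates [plant_derivatives()] under a forcing scenario, detecting
#' carbon-starvation death as a terminal event, and assembles a trajectory
#' with the full flux ledger at every record time.
#'
#' @param params [plant_params()].
#' @param scenario [make_scenario()].
#' @param state0 Initial state ([plant_state()]).
#' @param settings [solver_settings()].
#' @param detect_starvation Detect and terminate on starvation
#'   (default TRUE).
#' @return Object of class `deb_trajectory`: `times`, `states`, `ledgers`
#'   (matrices), `events` (list), `alive`, plus `params`, `scenario`,
#'   `settings` and `metadata` (parameter hash).
#' @export
simulate_plant <- function(params, scenario, state0 = plant_state(),
                           settings = solver_settings(),
                           detect_starvation = TRUE) {
  stopifnot(inherits(params, "plant_params"),
            inherits(scenario, "env_scenario"))
  func <- function(t, y) plant_derivatives(t, y, scenario, params)$deriv
  rootf <- if (detect_starvation) {
    function(t, y) {
      d <- plant_derivatives(t, y, scenario, params)
      starvation_indicator(y, d$ledger, params)
    }
  } else NULL
  sol <- integrate_ode(func, state0, settings, rootfunc = rootf)
  ledgers <- t(vapply(seq_along(sol$times), function(i) {
    plant_derivatives(sol$times[i], sol$states[i, ], scenario, params)$ledger
  }, plant_derivatives(sol$times[1L], sol$states[1L, ], scenario,
                       params)$ledger))
  events <- list()
  alive <- TRUE
  if (!is.na(sol$troot)) {
    i_last <- nrow(sol$states)
    d <- plant_derivatives(sol$troot, sol$states[i_last, ], scenario, params)
    chk <- starvation_check(sol$states[i_last, ], d$ledger, params,
                            t = sol$troot)
    if (!chk$alive) {
      alive <- FALSE
      events <- list(chk$event)
    }
  }
  structure(list(model = "root_shoot", times = sol$times,
                 states = sol$states, ledgers = ledgers, events = events,
                 alive = alive, params = params,
                 scenario_label = scenario$label, settings = settings,
                 metadata = list(param_hash = param_hash(params),
                                 seed = scenario$seed)),
            class = "deb_trajectory")
}

#' @export
print.deb_trajectory <- function(x, ...) {
  cat(sprintf("<deb_trajectory> model=%s, %d records over t=[%g, %g] d%s\n",
              x$model, length(x$times), min(x$times), max(x$times),
              if (!x$alive) sprintf(", DEAD (%s at t=%.4g)",
                                    x$events[[1L]]$organ,
                                    x$events[[1L]]$time) else ""))
  cat("  final state: ",
      paste(colnames(x$states),
            format(x$states[nrow(x$states), ], digits = 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Specific growth rate from a trajectory tail
#'
#' Log-linear least-squares fit of a positive trajectory variable over the
#' final fraction of the run; in the exponential (balanced-growth) regime the
#' slope is the specific growth rate and R^2 is ~1.
#'
#' @param traj `deb_trajectory` (or any list with `times` and `states`).
#' @param variable Column name in `traj$states`.
#' @param tail_frac Fraction of the record (by time) used for the fit.
#' @return List with `rate` (d^-1) and `r_squared`.
#' @export
growth_rate <- function(traj, variable, tail_frac = 0.2) {
  t_all <- traj$times
  x_all <- traj$states[, variable]
  t_min <- max(t_all) - tail_frac * (max(t_all) - min(t_all))
  sel <- t_all >= t_min
  x <- x_all[sel]; tt <- t_all[sel]
  if (any(x <= 0))
    stop("growth_rate: '", variable, "' must be positive over the tail",
         call. = FALSE)
  if (max(x) == min(x)) return(list(rate = 0, r_squared = 1))
  fit <- stats::lm(log(x) ~ tt)
  list(rate = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared)
}

#' Temperature-rescaling consistency check
#'
#' When every rate parameter shares one Arrhenius temperature, simulating at
#' constant temperature T2 must equal the T1 simulation with time rescaled by
#' the ratio of Arrhenius factors. The T2 run is recorded exactly at the
#' rescaled times of the T1 records, so states are compared index by index
#' without interpolation.
#'
#' @param params [plant_params()].
#' @param state0 Initial state.
#' @param T1,T2 Constant temperatures (K).
#' @param env_levels Named list of constant `co2`, `light`, `soil_n` levels.
#' @param horizon Length of the T1 run (d).
#' @param settings [solver_settings()] (its `t_span` is overridden).
#' @return Maximum relative state discrepancy across records.
#' @export
time_rescale_check <- function(params, state0 = plant_state(),
                               T1 = 293.15, T2 = 303.15,
                               env_levels = list(co2 = 1, light = 1,
                                                 soil_n = 1),
                               horizon = 100,
                               settings = solver_settings()) {
  sc <- function(T_kelvin) {
    make_scenario("constant", c(env_levels, list(temperature = T_kelvin)),
                  label = sprintf("T=%gK", T_kelvin))
  }
  A1 <- arrhenius_factor(T1, params$T_ref, params$T_A)
  A2 <- arrhenius_factor(T2, params$T_ref, params$T_A)
  t1 <- seq(0, horizon, by = settings$record_every)
  f1 <- function(t, y) plant_derivatives(t, y, sc(T1), params)$deriv
  f2 <- function(t, y) plant_derivatives(t, y, sc(T2), params)$deriv
  s1 <- integrate_ode(f1, state0, settings, times = t1)
  s2 <- integrate_ode(f2, state0, settings, times = t1 * A1 / A2)
  scale <- pmax(abs(s1$states), 1e-8)
  max(abs(s1$states - s2$states) / scale)
}

# stable content hash of a parameter object (JSON-serialized, md5)
param_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
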