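#' Arrhenius temperature correction factor
#'
#' Dimensionless multiplier applied uniformly to all physiological rates:
#' `exp(T_A / T_ref - T_A / T)`. Equals 1 at the reference temperature and is
#' monotone increasing in `T` for `T_A > 0`.
#'
#' @param T_kelvin Body/environment temperature (K, > 0).
#' @param T_ref Reference temperature (K, > 0).
#' @param T_A Arrhenius temperature (K, >= 0); 0 disables temperature
#'   sensitivity.
#' @return Dimensionless rate multiplier.
#' @examples
#' arrhenius_factor(303.15, 293.15, 8000)  # ~2.46
#' @export
arrhenius_factor <- function(T_kelvin, T_ref, T_A) {
  if (any(T_kelvin <= 0) || T_ref <= 0) {
    stop("arrhenius_factor: temperatures must be positive kelvin",
         call. = FALSE)
  }
  if (T_A < 0) stop("arrhenius_factor: T_A must be >= 0", call. = FALSE)
  exp(T_A / T_ref - T_A / T_kelvin)
}

#' Construct an environmental forcing scenario
#'
#' Scenarios prescribe the four forcing channels — CO2, light, soil nitrogen
#' and temperature — as pure functions of time (days). The environment is a
#' boundary condition: the plant does not deplete it.
#'
#' Kinds:
#' * `"constant"`: fixed levels; params `co2`, `light`, `soil_n`,
#'   `temperature`.
#' * `"step"`: per-channel level switch; params as constant plus
#'   `step_channel`, `step_time`, `step_value` (level after the switch).
#' * `"seasonal"`: sinusoidal channels; per channel either a fixed level or
#'   `<channel>_amplitude` and `period` (days) around the mean level;
#'   channel values are floored at zero.
#' * `"noisy"`: lognormal multiplicative noise on a base scenario; params of
#'   the base kind plus `noise_sd` (sd of log-noise), `noise_dt` (noise
#'   refresh interval, days) and `seed`. Reproducible from the seed; the
#'   noise path is a deterministic function of time once built.
#'
#' @param kind One of `"constant"`, `"step"`, `"seasonal"`, `"noisy"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param label Scenario label.
#' @return An object of class `env_scenario` with function fields `co2`,
#'   `light`, `soil_n`, `temperature`, each mapping time (d) to a value.
#' @examples
#' sc <- make_scenario("constant", list(co2 = 1, light = 1, soil_n = 1,
#'                                      temperature = 293.15))
#' sc$soil_n(100)
#' @export
make_scenario <- function(kind = c("constant", "step", "seasonal", "noisy"),
                          params = list(), label = kind) {
  kind <- match.arg(kind)
  channels <- c("co2", "light", "soil_n", "temperature")
  defaults <- list(co2 = 1, light = 1, soil_n = 1, temperature = 293.15)

  get_level <- function(ch) {
    v <- params[[ch]]
    if (is.null(v)) v <- defaults[[ch]]
    if (!is.numeric(v) || !is.finite(v) || v < 0 ||
        (ch == "temperature" && v <= 0)) {
      stop("make_scenario: invalid level for channel '", ch, "'",
           call. = FALSE)
    }
    v
  }

  fns <- switch(kind,
    constant = {
      lv <- lapply(channels, get_level)
      names(lv) <- channels
      lapply(lv, function(v) {
        force(v)
        function(t) rep_len(v, length(t))
      })
    },
    step = {
      need <- c("step_channel", "step_time", "step_value")
      miss <- setdiff(need, names(params))
      if (length(miss)) {
        stop("make_scenario(step): missing keys: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      if (!params$step_channel %in% channels) {
        stop("make_scenario(step): unknown channel '", params$step_channel,
             "'", call. = FALSE)
      }
      lv <- lapply(channels, get_level)
      names(lv) <- channels
      out <- lapply(lv, function(v) {
        force(v)
        function(t) rep_len(v, length(t))
      })
      ch <- params$step_channel
      v0 <- lv[[ch]]
      v1 <- params$step_value
      ts <- params$step_time
      if (!is.numeric(v1) || v1 < 0 || (ch == "temperature" && v1 <= 0)) {
        stop("make_scenario(step): invalid step_value", call. = FALSE)
      }
      out[[ch]] <- function(t) ifelse(t < ts, v0, v1)
      out
    },
    seasonal = {
      period <- params$period
      if (is.null(period) || !is.numeric(period) || period <= 0) {
        stop("make_scenario(seasonal): missing or invalid key: period",
             call. = FALSE)
      }
      out <- list()
      for (ch in channels) {
        mean_v <- get_level(ch)
        amp <- params[[paste0(ch, "_amplitude")]]
        if (is.null(amp)) amp <- 0
        local({
          m <- mean_v; a <- amp; p <- period
          out[[ch]] <<- function(t) pmax(m + a * sin(2 * pi * t / p), 0)
        })
      }
      out
    },
    noisy = {
      base_kind <- params$base_kind
      if (is.null(base_kind)) base_kind <- "constant"
      if (identical(base_kind, "noisy")) {
        stop("make_scenario(noisy): base_kind cannot itself be 'noisy'",
             call. = FALSE)
      }
      need <- c("noise_sd", "seed")
      miss <- setdiff(need, names(params))
      if (length(miss)) {
        stop("make_scenario(noisy): missing keys: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      noise_dt <- params$noise_dt
      if (is.null(noise_dt)) noise_dt <- 1
      horizon <- params$horizon
      if (is.null(horizon)) horizon <- 2000
      base <- make_scenario(base_kind, params, label = "base")
      n_steps <- ceiling(horizon / noise_dt) + 1L
      # pre-drawn piecewise-constant lognormal path per channel (not T)
      paths <- local({
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
          get(".Random.seed", globalenv()) else NULL
        set.seed(as.integer(params$seed))
        p <- lapply(c("co2", "light", "soil_n"), function(ch)
          exp(stats::rnorm(n_steps, -params$noise_sd^2 / 2, params$noise_sd)))
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        names(p) <- c("co2", "light", "soil_n")
        p
      })
      out <- list()
      for (ch in c("co2", "light", "soil_n")) {
        local({
          b <- base[[ch]]; path <- paths[[ch]]; dt <- noise_dt
          out[[ch]] <<- function(t) {
            i <- pmin(pmax(floor(t / dt), 0) + 1L, length(path))
            b(t) * path[i]
          }
        })
      }
      out$temperature <- base$temperature
      out
    }
  )

  sc <- structure(c(fns[channels],
                    list(kind = kind, label = label,
                         seed = params$seed %||% NA_integer_)),
                  class = "env_scenario")
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.env_scenario <- function(x, ...) {
  v0 <- vapply(c("co2", "light", "soil_n", "temperature"),
               function(ch) x[[ch]](0), numeric(1))
  cat(sprintf("<env_scenario '%s'> kind=%s; at t=0: co2=%g light=%g soil_n=%g T=%gK\n",
              x$label, x$kind, v0[1], v0[2], v0[3], v0[4]))
  invisible(x)
}

#' Tabulate a scenario's channels over time
#'
#' @param scenario An [make_scenario()] object.
#' @param times Numeric vector of times (d).
#' @return data.frame with columns `t`, `co2`, `light`, `soil_n`,
#'   `temperature`.
#' @export
scenario_table <- function(scenario, times) {
  stopifnot(inherits(scenario, "env_scenario"))
  data.frame(t = times,
             co2 = scenario$co2(times),
             light = scenario$light(times),
             soil_n = scenario$soil_n(times),
             temperature = scenario$temperature(times))
}
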