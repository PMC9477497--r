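#' Default run configuration
#'
#' The fully specified default configuration (the `constant-balanced`
#' fixture): the root-shoot model in a constant, normalized environment.
#' Every [load_config()] result is this list with user overrides applied.
#'
#' @return Nested named list with blocks `model`, `plant`, `env`, `solver`,
#'   `state`, `output`, `seed`.
#' @export
default_config <- function() {
  list(model = "root_shoot",
       plant = unclass(plant_params()),
       rsl = {
         r <- unclass(rsl_params())
         r[c("a_C", "a_N", "y_C", "y_N", "mu", "rule", "fp_tol",
             "fp_max_iter", "fp_damping")]
       },
       env = list(kind = "constant", co2 = 1, light = 1, soil_n = 1,
                  temperature = 293.15),
       solver = list(rel_tol = 1e-8, abs_tol = 1e-10, stiff = TRUE,
                     t_span = c(0, 500), record_every = 1),
       state = list(M_V_S = 1, M_V_R = 1, m_EC_S = 0.3, m_EN_S = 0.3,
                    m_EC_R = 0.3, m_EN_R = 0.3),
       output = list(dir = ".", format = "csv"),
       seed = 1L)
}

config_known_keys <- function() {
  list(top = c("model", "plant", "rsl", "env", "solver", "state", "output",
               "seed"),
       plant = names(formals(plant_params)),
       rsl = c("a_C", "a_N", "y_C", "y_N", "mu", "rule", "fp_tol",
               "fp_max_iter", "fp_damping"),
       env = c("kind", "co2", "light", "soil_n", "temperature",
               "step_channel", "step_time", "step_value", "period",
               "co2_amplitude", "light_amplitude", "soil_n_amplitude",
               "temperature_amplitude", "base_kind", "noise_sd", "noise_dt",
               "horizon", "seed"),
       solver = c("rel_tol", "abs_tol", "max_step", "stiff", "t_span",
                  "record_every"),
       state = c(plant_state_names()[1:6], "m_L", "m_S", "m_R"),
       output = c("dir", "format"))
}

merge_config <- function(base, user, path, errors) {
  for (k in names(user)) {
    if (!k %in% names(base)) {
      errors$msgs <- c(errors$msgs,
                       paste0("unknown key '", path, k, "'"))
      next
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."),
                                errors)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads YAML (or JSON — valid JSON is valid YAML) from `path`, fills in
#' every missing key from [default_config()], rejects unknown keys with
#' their location, and validates all parameter blocks, aggregating every
#' violation into one error message. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML or JSON config file.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user))
    stop("config file must contain a mapping: ", path, call. = FALSE)
  validate_config(user)
}

#' Validate a configuration list
#'
#' @param user Partial configuration (list); missing keys take defaults.
#' @return Validated `run_config` list.
#' @export
validate_config <- function(user = list()) {
  errors <- new.env()
  errors$msgs <- character()
  # unknown-key pass against the key schema (values may be scalars or lists)
  known <- config_known_keys()
  for (k in names(user)) {
    if (!k %in% known$top) {
      errors$msgs <- c(errors$msgs, paste0("unknown key '", k, "'"))
    } else if (k %in% c("plant", "rsl", "env", "solver", "state", "output")) {
      bad <- setdiff(names(user[[k]]), known[[k]])
      if (length(bad))
        errors$msgs <- c(errors$msgs,
                         paste0("unknown key '", k, ".", bad, "'"))
    }
  }
  cfg <- default_config()
  for (k in intersect(names(user), known$top)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      keep <- intersect(names(user[[k]]), known[[k]])
      cfg[[k]][keep] <- user[[k]][keep]
    } else if (!is.list(cfg[[k]])) {
      cfg[[k]] <- user[[k]]
    }
  }
  if (!cfg$model %in% c("root_shoot", "root_stem_leaf"))
    errors$msgs <- c(errors$msgs,
                     paste0("model: must be 'root_shoot' or ",
                            "'root_stem_leaf' (got '", cfg$model, "')"))
  check <- function(expr, block) {
    tryCatch({ expr; NULL },
             error = function(e)
               errors$msgs <<- c(errors$msgs,
                                 paste0(block, ": ", conditionMessage(e))))
  }
  check(do.call(plant_params, cfg$plant), "plant")
  check(do.call(rsl_params, cfg$rsl), "rsl")
  check(make_scenario(cfg$env$kind,
                      cfg$env[setdiff(names(cfg$env), "kind")]), "env")
  check(do.call(solver_settings,
                cfg$solver[!vapply(cfg$solver, is.null, TRUE)]), "solver")
  if (length(errors$msgs))
    stop("invalid configuration:\n  - ",
         paste(errors$msgs, collapse = "\n  - "), call. = FALSE)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Named fixture configurations
#'
#' The shipped scenario library:
#' * `constant-balanced` — root-shoot model, constant normalized environment
#'   supporting balanced exponential growth (the default).
#' * `n-poor` — soil nitrogen cut to 5% of the balanced level.
#' * `seasonal-light` — sinusoidal light (period 365 d, amplitude 0.5).
#' * `starvation` — all resources zero from t = 0; the plant runs down its
#'   reserves and dies of carbon starvation.
#' * `fig3a` — root-stem-leaf model, minimum rule, leaf-deficient start.
#' * `fig3b` — as `fig3a` with the parallel complementary SU.
#' * `fig3c` — PCSU availability-ratio sweep configuration.
#'
#' @param name Fixture name.
#' @return A validated `run_config`.
#' @export
fixture_config <- function(name = c("constant-balanced", "n-poor",
                                    "seasonal-light", "starvation",
                                    "fig3a", "fig3b", "fig3c")) {
  name <- match.arg(name)
  user <- switch(name,
    "constant-balanced" = list(),
    "n-poor" = list(env = list(kind = "constant", soil_n = 0.05)),
    "seasonal-light" = list(env = list(kind = "seasonal", period = 365,
                                       light_amplitude = 0.5)),
    "starvation" = list(env = list(kind = "constant", co2 = 0, light = 0,
                                   soil_n = 0),
                        solver = list(t_span = c(0, 200),
                                      record_every = 0.25)),
    "fig3a" = list(model = "root_stem_leaf",
                   rsl = list(rule = "minimum"),
                   solver = list(t_span = c(0, 300), record_every = 0.5)),
    "fig3b" = list(model = "root_stem_leaf",
                   rsl = list(rule = "pcsu"),
                   solver = list(t_span = c(0, 300), record_every = 0.5)),
    "fig3c" = list(model = "root_stem_leaf",
                   rsl = list(rule = "pcsu"),
                   solver = list(t_span = c(0, 400), record_every = 1)))
  validate_config(user)
}

#' Execute a validated configuration
#'
#' @param cfg A `run_config` from [load_config()], [validate_config()] or
#'   [fixture_config()].
#' @return The resulting `deb_trajectory`.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  settings <- do.call(solver_settings,
                      cfg$solver[!vapply(cfg$solver, is.null, TRUE)])
  if (cfg$model == "root_shoot") {
    params <- do.call(plant_params, cfg$plant)
    env_params <- cfg$env[setdiff(names(cfg$env), "kind")]
    if (identical(cfg$env$kind, "noisy") && is.null(env_params$seed))
      env_params$seed <- cfg$seed
    scenario <- make_scenario(cfg$env$kind, env_params)
    st <- cfg$state[plant_state_names()[1:6]]
    state0 <- do.call(plant_state, st[!vapply(st, is.null, TRUE)])
    simulate_plant(params, scenario, state0, settings)
  } else {
    params <- do.call(rsl_params, cfg$rsl)
    st <- cfg$state[c("m_L", "m_S", "m_R")]
    st <- st[!vapply(st, is.null, TRUE)]
    state0 <- if (length(st)) do.call(rsl_state, st) else rsl_state()
    simulate_rsl(params, state0, settings)
  }
}

#' Write a trajectory to CSV with reproducibility metadata
#'
#' RFC 4180 CSV preceded by `#`-prefixed metadata lines (model, parameter
#' hash, seed, solver settings and the parameter JSON needed to re-audit the
#' file). Columns: time, every state variable, every ledger entry.
#'
#' @param traj A `deb_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  meta <- c(
    paste0("# model: ", traj$model),
    paste0("# param_hash: ", traj$metadata$param_hash),
    paste0("# seed: ", traj$metadata$seed),
    paste0("# solver: rel_tol=", traj$settings$rel_tol,
           " abs_tol=", traj$settings$abs_tol,
           " t_span=", paste(traj$settings$t_span, collapse = ":"),
           " record_every=", traj$settings$record_every),
    paste0("# params: ",
           jsonlite::toJSON(unclass(traj$params), auto_unbox = TRUE,
                            digits = NA)),
    paste0("# alive: ", traj$alive))
  df <- data.frame(t = traj$times, traj$states, traj$ledgers,
                   check.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' Reconstructs enough of the trajectory (states, ledgers, parameters) to
#' re-run [mass_balance_audit()].
#'
#' @param path CSV file path.
#' @return A `deb_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  model_line <- grep("^# model: ", meta, value = TRUE)
  params_line <- grep("^# params: ", meta, value = TRUE)
  if (!length(model_line) || !length(params_line))
    stop("not a trajectory CSV (missing metadata header): ", path,
         call. = FALSE)
  model <- sub("^# model: ", "", model_line[1L])
  params <- jsonlite::fromJSON(sub("^# params: ", "", params_line[1L]))
  df <- tryCatch(
    utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                    check.names = FALSE),
    error = function(e) stop("cannot parse trajectory CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!"t" %in% names(df) || nrow(df) < 2L)
    stop("malformed trajectory CSV (no time column or too few rows): ", path,
         call. = FALSE)
  state_cols <- if (model == "root_shoot") plant_state_names()
    else c("m_L", "m_S", "m_R")
  missing_cols <- setdiff(state_cols, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing state columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (model == "root_shoot") {
    params <- do.call(plant_params, params[names(formals(plant_params))])
  } else {
    params <- do.call(rsl_params,
                      params[intersect(names(params),
                                       config_known_keys()$rsl)])
  }
  ledger_cols <- setdiff(names(df), c("t", state_cols))
  structure(list(model = model, times = df$t,
                 states = as.matrix(df[state_cols]),
                 ledgers = as.matrix(df[ledger_cols]), events = list(),
                 alive = TRUE, params = params, scenario_label = "file",
                 settings = solver_settings(t_span = range(df$t)),
                 metadata = list(param_hash = param_hash(params),
                                 seed = NA_integer_)),
            class = "deb_trajectory")
}

#' Summarize a trajectory as a JSON-ready record
#'
#' @param traj A `deb_trajectory`.
#' @return List with final state, tail growth rates, audit errors and
#'   events.
#' @export
trajectory_summary <- function(traj) {
  final <- as.list(traj$states[nrow(traj$states), ])
  out <- list(model = traj$model, t_final = max(traj$times),
              alive = traj$alive, final_state = final,
              events = traj$events, metadata = traj$metadata)
  if (traj$model == "root_shoot") {
    if (traj$alive && all(traj$states[, "M_V_S"] > 0)) {
      out$growth_rate_shoot <- growth_rate(traj, "M_V_S")$rate
      out$growth_rate_root <- growth_rate(traj, "M_V_R")$rate
    }
    aud <- mass_balance_audit(traj)
    out$audit <- list(max_rel_C = aud$max_rel_C, max_rel_N = aud$max_rel_N)
  } else {
    out$fractions <- as.list(rsl_fractions(traj$states[nrow(traj$states), ]))
    out$outcome <- classify_outcome(traj)
  }
  out
}

#' Write a trajectory summary as JSON
#' @inheritParams write_trajectory_csv
#' @export
write_summary_json <- function(traj, path) {
  jsonlite::write_json(trajectory_summary(traj), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
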