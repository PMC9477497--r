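#' Parameters for the root-stem-leaf allocation model
#'
#' Three organs in series: the leaf acquires carbon, the root acquires
#' nitrogen, and the stem sits between them, so carbon reaching the root and
#' nitrogen reaching the leaf must first pass the stem's own growth SU,
#' which keeps what it uses and shares both surpluses onward. Contrasting
#' the Liebig minimum rule with the parallel complementary SU at every organ
#' exposes the failure mode of perfectly efficient SUs: the stem never has
#' to share both surpluses at once, and the plant collapses to stems.
#'
#' @param a_C Specific C acquisition by the leaf (resource mass^-1 d^-1).
#' @param a_N Specific N acquisition by the root.
#' @param y_C,y_N Length-3 stoichiometric yields (C and N per unit new mass)
#'   for organs in the order leaf, stem, root. The default stem stoichiometry
#'   is carbon-rich and nitrogen-poor relative to leaf and root, as wood is;
#'   this also makes the within-step flux resolution well-posed for the
#'   minimum rule (proportional stem stoichiometry leaves the allocation
#'   between stem and terminal organs indeterminate at exactly balanced
#'   streams).
#' @param mu Length-3 specific turnover rates (d^-1), same order.
#' @param rule `"minimum"` or `"pcsu"`, applied at all three growth SUs.
#' @param fp_tol Convergence tolerance of the within-step fixed-point flux
#'   resolution (relative to the acquisition scale).
#' @param fp_max_iter Iteration cap; generous, because the damped map
#'   contracts slowly near an SU limitation switch.
#' @param fp_damping Damping factor in (0, 1].
#' @return List of class `rsl_params`; `alpha` (= `a_C / a_N`) is always
#'   recomputed from the stored rates.
#' @export
rsl_params <- function(a_C = 1, a_N = 1,
                       y_C = c(1, 1.5, 1), y_N = c(1, 0.5, 1),
                       mu = c(0.1, 0.1, 0.1),
                       rule = c("pcsu", "minimum"),
                       fp_tol = 1e-10, fp_max_iter = 5000, fp_damping = 0.5) {
  rule <- match.arg(rule)
  if (a_C <= 0 || a_N <= 0) stop("acquisition rates must be positive",
                                 call. = FALSE)
  if (length(y_C) != 3L || length(y_N) != 3L || length(mu) != 3L)
    stop("y_C, y_N and mu must have length 3 (leaf, stem, root)",
         call. = FALSE)
  if (any(y_C <= 0) || any(y_N <= 0) || any(mu < 0))
    stop("yields must be positive and turnover nonnegative", call. = FALSE)
  if (fp_tol <= 0 || fp_max_iter < 1 || fp_damping <= 0 || fp_damping > 1)
    stop("invalid fixed-point settings", call. = FALSE)
  structure(list(a_C = a_C, a_N = a_N, alpha = a_C / a_N,
                 y_C = stats::setNames(y_C, c("L", "S", "R")),
                 y_N = stats::setNames(y_N, c("L", "S", "R")),
                 mu = stats::setNames(mu, c("L", "S", "R")),
                 rule = rule, fp_tol = fp_tol,
                 fp_max_iter = as.integer(fp_max_iter),
                 fp_damping = fp_damping),
            class = "rsl_params")
}

#' @export
print.rsl_params <- function(x, ...) {
  cat(sprintf("<rsl_params> rule=%s, a_C=%g, a_N=%g (alpha=%g), mu=(%s)\n",
              x$rule, x$a_C, x$a_N, x$alpha,
              paste(format(x$mu), collapse = ", ")))
  invisible(x)
}

#' Initial state of the root-stem-leaf model
#'
#' The default is the leaf-deficient fixture: leaf mass well below stem and
#' root mass.
#'
#' @param m_L,m_S,m_R Organ masses (leaf, stem, root), nonnegative.
#' @return Named numeric vector.
#' @export
rsl_state <- function(m_L = 0.1, m_S = 1, m_R = 1) {
  y <- c(m_L = m_L, m_S = m_S, m_R = m_R)
  if (anyNA(y) || any(y < 0))
    stop("rsl_state: masses must be nonnegative", call. = FALSE)
  y
}

#' Organ mass fractions
#' @param state Named mass vector (`m_L`, `m_S`, `m_R`).
#' @return Named fractions summing to 1 (all zero if total mass is 0).
#' @export
rsl_fractions <- function(state) {
  tot <- sum(state)
  if (tot <= 0) return(c(f_L = 0, f_S = 0, f_R = 0))
  stats::setNames(as.numeric(state) / tot, c("f_L", "f_S", "f_R"))
}

#' Resolve the coupled synthesizing-unit fluxes of the three-organ chain
#'
#' Acquisition is local and linear in mass (`A_C = a_C * m_L` at the leaf,
#' `A_N = a_N * m_R` at the root). The leaf SU sees its own carbon plus the
#' nitrogen the stem passes on; the root SU sees its own nitrogen plus the
#' carbon the stem passes on; the stem SU sees the two organ surpluses. The
#' mutual dependence (stem pass-through feeds the organs, organ surpluses
#' feed the stem) is resolved by damped fixed-point iteration on the two
#' stem pass-through fluxes, initialized from zero transfer so the flux
#' resolution is a pure function of the state.
#'
#' @param state Named mass vector ([rsl_state()]).
#' @param params [rsl_params()].
#' @return List with growth rates `g` (named L/S/R), acquisition `A_C`/`A_N`,
#'   stem pass-through `C_to_root`/`N_to_leaf`, organ-to-stem surpluses
#'   `C_leaf_to_stem`/`N_root_to_stem`, terminal (excreted) rejections
#'   `N_lost_leaf`/`C_lost_root`, iteration count `iter` and `converged`.
#' @export
rsl_fluxes <- function(state, params) {
  if (anyNA(state) || any(state < 0))
    stop("rsl_fluxes: masses must be nonnegative", call. = FALSE)
  A_C <- params$a_C * state[["m_L"]]
  A_N <- params$a_N * state[["m_R"]]
  yC <- unname(params$y_C); yN <- unname(params$y_N)
  rule <- params$rule
  scale <- max(1, A_C, A_N)
  # scalar two-substrate SU kernel, specialized by rule (hot loop)
  su2 <- if (rule == "minimum") {
    function(r1, r2) if (r1 <= 0 || r2 <= 0) 0 else min(r1, r2)
  } else {
    function(r1, r2) if (r1 <= 0 || r2 <= 0) 0 else
      1 / (1 / r1 + 1 / r2 - 1 / (r1 + r2))
  }

  pass <- function(x) {
    # x = c(C passed stem->root, N passed stem->leaf); clip roundoff residue
    g_L <- su2(A_C / yC[1L], max(x[2L], 0) / yN[1L])
    C_ls <- max(A_C - yC[1L] * g_L, 0)     # leaf C surplus -> stem
    g_R <- su2(max(x[1L], 0) / yC[3L], A_N / yN[3L])
    N_rs <- max(A_N - yN[3L] * g_R, 0)     # root N surplus -> stem
    g_S <- su2(C_ls / yC[2L], N_rs / yN[2L])
    list(x_new = pmax(c(C_ls - yC[2L] * g_S, N_rs - yN[2L] * g_S), 0),
         g = c(L = g_L, S = g_S, R = g_R), C_ls = C_ls, N_rs = N_rs,
         N_lost_leaf = x[2L] - yN[1L] * g_L,
         C_lost_root = x[1L] - yC[3L] * g_R)
  }

  x1 <- 0; x2 <- 0
  converged <- FALSE
  iter <- 0L
  residual <- Inf
  tol <- params$fp_tol * scale
  damp <- params$fp_damping
  # scalar form of pass() for the hot loop
  while (iter < params$fp_max_iter) {
    iter <- iter + 1L
    g_L <- su2(A_C / yC[1L], x2 / yN[1L])
    C_ls <- max(A_C - yC[1L] * g_L, 0)
    g_R <- su2(x1 / yC[3L], A_N / yN[3L])
    N_rs <- max(A_N - yN[3L] * g_R, 0)
    g_S <- su2(C_ls / yC[2L], N_rs / yN[2L])
    n1 <- max(C_ls - yC[2L] * g_S, 0)
    n2 <- max(N_rs - yN[2L] * g_S, 0)
    residual <- max(abs(n1 - x1), abs(n2 - x2))
    if (residual <= tol) {
      converged <- TRUE
      x1 <- n1; x2 <- n2
      break
    }
    x1 <- (1 - damp) * x1 + damp * n1
    x2 <- (1 - damp) * x2 + damp * n2
  }
  x <- c(x1, x2)
  if (!converged) {
    stop(sprintf(paste0("rsl_fluxes: fixed point failed to converge in %d ",
                        "iterations (residual %.3g, masses L=%.3g S=%.3g ",
                        "R=%.3g, rule=%s)"),
                 params$fp_max_iter, residual,
                 state[["m_L"]], state[["m_S"]], state[["m_R"]], rule),
         call. = FALSE)
  }
  res <- pass(x)  # evaluate once more at the converged transfer
  list(g = res$g, A_C = unname(A_C), A_N = unname(A_N),
       C_to_root = res$x_new[1L], N_to_leaf = res$x_new[2L],
       C_leaf_to_stem = res$C_ls, N_root_to_stem = res$N_rs,
       N_lost_leaf = max(res$N_lost_leaf, 0),
       C_lost_root = max(res$C_lost_root, 0),
       iter = iter, converged = converged)
}

#' Time derivatives of the root-stem-leaf model
#'
#' `dm_i/dt = growth_i - mu_i * m_i` with growth rates from [rsl_fluxes()].
#'
#' @param t Time (d; unused, the model is autonomous).
#' @param state Named mass vector.
#' @param params [rsl_params()].
#' @return Named derivative vector.
#' @export
rsl_derivatives <- function(t, state, params) {
  fl <- rsl_fluxes(state, params)
  c(m_L = fl$g[["L"]] - params$mu[["L"]] * state[["m_L"]],
    m_S = fl$g[["S"]] - params$mu[["S"]] * state[["m_S"]],
    m_R = fl$g[["R"]] - params$mu[["R"]] * state[["m_R"]])
}

#' Simulate the root-stem-leaf model
#'
#' @param params [rsl_params()].
#' @param state0 Initial masses ([rsl_state()]).
#' @param settings [solver_settings()].
#' @return A `deb_trajectory` (model `"root_stem_leaf"`) whose ledgers hold
#'   the resolved SU fluxes at every record.
#' @export
simulate_rsl <- function(params, state0 = rsl_state(),
                         settings = solver_settings(t_span = c(0, 300),
                                                    record_every = 0.5)) {
  stopifnot(inherits(params, "rsl_params"))
  func <- function(t, y) rsl_derivatives(t, y, params)
  sol <- integrate_ode(func, state0, settings)
  ledgers <- t(vapply(seq_along(sol$times), function(i) {
    fl <- rsl_fluxes(sol$states[i, ], params)
    c(g_L = fl$g[["L"]], g_S = fl$g[["S"]], g_R = fl$g[["R"]],
      A_C = fl$A_C, A_N = fl$A_N,
      C_to_root = fl$C_to_root, N_to_leaf = fl$N_to_leaf,
      C_leaf_to_stem = fl$C_leaf_to_stem, N_root_to_stem = fl$N_root_to_stem,
      N_lost_leaf = fl$N_lost_leaf, C_lost_root = fl$C_lost_root)
  }, numeric(11L)))
  structure(list(model = "root_stem_leaf", times = sol$times,
                 states = sol$states, ledgers = ledgers, events = list(),
                 alive = TRUE, params = params, scenario_label = "none",
                 settings = settings,
                 metadata = list(param_hash = param_hash(params),
                                 seed = NA_integer_)),
            class = "deb_trajectory")
}

#' Classify the long-run outcome of a root-stem-leaf trajectory
#'
#' @param traj Trajectory from [simulate_rsl()].
#' @param eps Small fraction used for the dominance/positivity thresholds.
#' @param window Tail fraction of the record used to assess trends.
#' @return One of `"COLLAPSE_TO_STEM"`, `"BALANCED_GROWTH"`, `"EXTINCTION"`,
#'   `"UNRESOLVED"`.
#' @export
classify_outcome <- function(traj, eps = 0.01, window = 0.2) {
  s <- traj$states
  n <- nrow(s)
  i0 <- max(1L, which.max(traj$times >= max(traj$times) -
                            window * diff(range(traj$times))))
  f_end <- rsl_fractions(s[n, ])
  decaying <- s[n, "m_L"] <= s[i0, "m_L"] && s[n, "m_R"] <= s[i0, "m_R"]
  if (f_end[["f_S"]] > 1 - eps && decaying) return("COLLAPSE_TO_STEM")
  if (sum(s[n, ]) < eps) return("EXTINCTION")
  f_tail <- t(apply(s[i0:n, , drop = FALSE], 1L, rsl_fractions))
  total_growing <- sum(s[n, ]) > sum(s[i0, ])
  if (all(f_tail > eps) && total_growing) return("BALANCED_GROWTH")
  "UNRESOLVED"
}

#' Sweep the carbon:nitrogen availability ratio
#'
#' For each value of `alpha` the leaf's specific carbon acquisition is set to
#' `alpha * a_N` (nitrogen acquisition held fixed) and the model is
#' integrated until the organ mass fractions are quasi-steady. Because
#' acquisition is linear in mass the dynamics are homogeneous of degree one,
#' so the state is renormalized to unit total mass after every integration
#' window; this leaves the fractions and the specific growth rate untouched
#' while avoiding overflow on long runs. A row is flagged unconverged when
#' the fractions still drift by more than `drift_tol` across the final
#' window at the horizon.
#'
#' @param alpha_grid Vector of availability ratios (default
#'   `10^seq(-2, 2, length.out = 41)`).
#' @param params Base [rsl_params()] (its `a_N` is kept; `rule` should be
#'   `"pcsu"` -- the minimum rule collapses to stems).
#' @param state0 Initial masses.
#' @param horizon Maximum integration time per ratio (d).
#' @param window Drift-assessment window (d).
#' @param drift_tol Convergence tolerance on the fraction drift per window.
#' @return data.frame with columns `alpha`, `f_L`, `f_S`, `f_R`,
#'   `converged`, `growth_rate` (specific rate of total mass on the final
#'   ray, d^-1).
#' @export
run_alpha_sweep <- function(alpha_grid = 10^seq(-2, 2, length.out = 41),
                            params = rsl_params(), state0 = rsl_state(),
                            horizon = 3000, window = 100,
                            drift_tol = 1e-6) {
  if (any(alpha_grid <= 0))
    stop("run_alpha_sweep: alpha values must be positive", call. = FALSE)
  y_start <- state0
  rows <- lapply(alpha_grid, function(alpha) {
    p <- rsl_params(a_C = alpha * params$a_N, a_N = params$a_N,
                    y_C = params$y_C, y_N = params$y_N, mu = params$mu,
                    rule = params$rule, fp_tol = params$fp_tol,
                    fp_max_iter = params$fp_max_iter,
                    fp_damping = params$fp_damping)
    func <- function(t, y) rsl_derivatives(t, y, p)
    y <- y_start
    t0 <- 0
    drift <- Inf
    while (t0 < horizon && drift >= drift_tol) {
      sol <- integrate_ode(func, y, solver_settings(t_span = c(t0, t0 + window),
                                                    record_every = window / 10),
                           nonneg = TRUE)
      f <- t(apply(sol$states, 1L, rsl_fractions))
      drift <- max(abs(f[nrow(f), ] - f[1L, ]))
      y <- sol$states[nrow(sol$states), ]
      y <- y / sum(y)          # renormalize: dynamics are degree-1 homogeneous
      t0 <- t0 + window
    }
    y_start <<- y
    f_end <- rsl_fractions(y)
    fl <- rsl_fluxes(y, p)
    data.frame(alpha = alpha, f_L = f_end[["f_L"]], f_S = f_end[["f_S"]],
               f_R = f_end[["f_R"]], converged = drift < drift_tol,
               growth_rate = sum(fl$g) - sum(p$mu * y))
  })
  do.call(rbind, rows)
}
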