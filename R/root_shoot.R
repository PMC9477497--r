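#' Parameter set for the root-shoot plant DEB model
#'
#' Builds and validates the full parameterization of the two-organ plant
#' model: a shoot that fixes carbon and a root that takes up nitrogen, each
#' carrying structural biomass plus a reduced-carbon and a nitrogen-rich
#' reserve. Defaults are in normalized units (all half-saturations 1,
#' maximum specific assimilation 1) chosen so that the default constant
#' environment supports balanced exponential growth; they are fixture values,
#' not measurements.
#'
#' @param j_CAm Max specific CH2O assimilation
#'   (C-mol (C-mol shoot structure)^-1 d^-1).
#' @param j_NAm Max specific N uptake (N-mol (C-mol root structure)^-1 d^-1).
#' @param K_C,K_L,K_N Half-saturation constants for CO2, light and soil N
#'   (environment units).
#' @param nu_EC,nu_EN First-order reserve turnover rates (d^-1), shared by
#'   shoot and root (one rate per reserve class).
#' @param p_M_S,p_M_R Specific somatic maintenance
#'   (C-mol (C-mol structure)^-1 d^-1).
#' @param y_EC_V,y_EN_V C-mol of C reserve / N-rich reserve consumed per
#'   C-mol of new structure.
#' @param n_NV N:C ratio of structure (N-mol C-mol^-1).
#' @param n_NE N:C ratio of the nitrogen-rich reserve.
#' @param y_C_EN C-mol CH2O consumed per C-mol of N-rich reserve synthesized
#'   (>= 1; the excess is assimilation overhead CO2).
#' @param lambda_N Fraction of root N uptake routed directly to the shoot
#'   assembly SU (xylem split, 0-1).
#' @param kappa_P_S,kappa_P_R Fraction of each organ's growth-SU output
#'   diverted to products (0-1).
#' @param h_V Structure senescence rate (d^-1).
#' @param sigma Resorption fraction of senesced biomass (0-1).
#' @param eta_T Translocation efficiency (0-1]; losses are respired (C) or
#'   shed as litter (N).
#' @param T_ref,T_A Arrhenius reference and Arrhenius temperature (K).
#' @param eps_death Reserve-density threshold below which an organ in
#'   maintenance deficit is declared starved (default 0.02: reserves below
#'   2% of structural mass no longer buffer maintenance).
#' @param light_mode `"multiplicative"` (light is a saturating multiplier on
#'   shoot assimilation) or `"pcsu"` (CO2 and light combined by a parallel
#'   complementary SU).
#' @return A validated list of class `plant_params`.
#' @export
plant_params <- function(j_CAm = 1, j_NAm = 0.08,
                         K_C = 1, K_L = 1, K_N = 1,
                         nu_EC = 0.2, nu_EN = 0.2,
                         p_M_S = 0.05, p_M_R = 0.05,
                         y_EC_V = 1.2, y_EN_V = 0.4,
                         n_NV = 0.1, n_NE = 0.25, y_C_EN = 1.25,
                         lambda_N = 0.5,
                         kappa_P_S = 0.1, kappa_P_R = 0.1,
                         h_V = 0.01, sigma = 0.5,
                         eta_T = 0.95,
                         T_ref = 293.15, T_A = 8000,
                         eps_death = 0.02,
                         light_mode = c("multiplicative", "pcsu")) {
  p <- list(j_CAm = j_CAm, j_NAm = j_NAm, K_C = K_C, K_L = K_L, K_N = K_N,
            nu_EC = nu_EC, nu_EN = nu_EN, p_M_S = p_M_S, p_M_R = p_M_R,
            y_EC_V = y_EC_V, y_EN_V = y_EN_V, n_NV = n_NV, n_NE = n_NE,
            y_C_EN = y_C_EN, lambda_N = lambda_N,
            kappa_P_S = kappa_P_S, kappa_P_R = kappa_P_R,
            h_V = h_V, sigma = sigma, eta_T = eta_T,
            T_ref = T_ref, T_A = T_A, eps_death = eps_death,
            light_mode = match.arg(light_mode))
  validate_plant_params(p)
  class(p) <- "plant_params"
  p
}

validate_plant_params <- function(p) {
  pos <- c("j_CAm", "j_NAm", "K_C", "K_L", "K_N", "nu_EC", "nu_EN",
           "p_M_S", "p_M_R", "y_EC_V", "y_EN_V", "n_NV", "n_NE", "y_C_EN",
           "T_ref", "eps_death")
  bad <- character()
  for (k in pos) {
    v <- p[[k]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      bad <- c(bad, paste0(k, " must be positive (got ", format(v), ")"))
  }
  for (k in c("lambda_N", "kappa_P_S", "kappa_P_R", "sigma")) {
    v <- p[[k]]
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 1)
      bad <- c(bad, paste0(k, " must lie in [0, 1] (got ", format(v), ")"))
  }
  if (!is.numeric(p$eta_T) || p$eta_T <= 0 || p$eta_T > 1)
    bad <- c(bad, paste0("eta_T must lie in (0, 1] (got ",
                         format(p$eta_T), ")"))
  if (!is.numeric(p$h_V) || !is.finite(p$h_V) || p$h_V < 0)
    bad <- c(bad, "h_V must be >= 0")
  if (!is.numeric(p$T_A) || !is.finite(p$T_A) || p$T_A < 0)
    bad <- c(bad, "T_A must be >= 0")
  if (is.numeric(p$y_EN_V) && is.numeric(p$n_NE) && is.numeric(p$n_NV) &&
      p$y_EN_V * p$n_NE < p$n_NV - 1e-12)
    bad <- c(bad, paste0("stoichiometric closure violated: ",
                         "y_EN_V * n_NE (", format(p$y_EN_V * p$n_NE),
                         ") < n_NV (", format(p$n_NV),
                         "); the N-reserve flux cannot supply the N in ",
                         "new structure"))
  if (is.numeric(p$y_C_EN) && p$y_C_EN < 1)
    bad <- c(bad, "y_C_EN must be >= 1 (a C-mol of N-reserve contains one C-mol)")
  if (is.numeric(p$n_NV) && is.numeric(p$n_NE) && p$n_NV > p$n_NE)
    bad <- c(bad, "n_NV must be <= n_NE (resorbed N is repackaged as N-reserve)")
  if (length(bad))
    stop("invalid plant parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params> root-shoot DEB parameter set\n")
  nm <- setdiff(names(x), "light_mode")
  cat(paste0("  ", nm, " = ", vapply(x[nm], format, ""), collapse = "\n"),
      "\n  light_mode = ", x$light_mode, "\n", sep = "")
  invisible(x)
}

#' Names of the root-shoot model state variables
#'
#' Structural masses, reserve densities and the cumulative audit pools in
#' the order used by the integrator.
#' @return Character vector.
#' @export
plant_state_names <- function() {
  c("M_V_S", "M_V_R", "m_EC_S", "m_EN_S", "m_EC_R", "m_EN_R",
    "M_P", "M_litter_C", "M_litter_N", "M_CO2", "N_excess",
    "M_A_C", "M_A_N")
}

#' Initial state for the root-shoot model
#'
#' @param M_V_S,M_V_R Structural mass of shoot and root (C-mol).
#' @param m_EC_S,m_EN_S,m_EC_R,m_EN_R Reserve densities
#'   (C-mol reserve per C-mol structure).
#' @return Named numeric state vector (cumulative pools start at 0).
#' @export
plant_state <- function(M_V_S = 1, M_V_R = 1,
                        m_EC_S = 0.3, m_EN_S = 0.3,
                        m_EC_R = 0.3, m_EN_R = 0.3) {
  y <- c(M_V_S, M_V_R, m_EC_S, m_EN_S, m_EC_R, m_EN_R,
         0, 0, 0, 0, 0, 0, 0)
  names(y) <- plant_state_names()
  if (anyNA(y) || any(y < 0))
    stop("plant_state: masses and densities must be nonnegative",
         call. = FALSE)
  y
}

#' Resource acquisition fluxes
#'
#' Potential assimilation scales linearly with the acquiring organ's
#' structural mass (V1-morphy) and saturates hyperbolically with the
#' environmental concentration; all rates carry the Arrhenius factor.
#'
#' @param state Named state vector ([plant_state()]).
#' @param env List/row with `co2`, `light`, `soil_n`, `temperature` at the
#'   current time.
#' @param params [plant_params()].
#' @return List with `J_A_C` (C-mol d^-1) and `J_A_N` (N-mol d^-1).
#' @export
acquisition <- function(state, env, params) {
  arr <- arrhenius_factor(env$temperature, params$T_ref, params$T_A)
  f_C <- saturating_uptake(env$co2, 1, params$K_C)
  f_L <- saturating_uptake(env$light, 1, params$K_L)
  f_N <- saturating_uptake(env$soil_n, 1, params$K_N)
  f_CL <- if (params$light_mode == "multiplicative") {
    f_C * f_L
  } else {
    # CO2 x light as complementary substrates of the photosynthetic SU
    production_rate(c(f_C, f_L), "pcsu")
  }
  list(J_A_C = state[["M_V_S"]] * params$j_CAm * f_CL * arr,
       J_A_N = state[["M_V_R"]] * params$j_NAm * f_N * arr)
}

#' Reserve mobilization (catabolic) fluxes
#'
#' First-order turnover: each reserve releases `nu * m * M_V` per day.
#'
#' @inheritParams acquisition
#' @return List of catabolic fluxes `J_EC_S`, `J_EN_S`, `J_EC_R`, `J_EN_R`
#'   (C-mol d^-1), already temperature-corrected.
#' @param arr Arrhenius factor (precomputed; default 1).
#' @export
mobilization <- function(state, params, arr = 1) {
  list(J_EC_S = params$nu_EC * state[["m_EC_S"]] * state[["M_V_S"]] * arr,
       J_EN_S = params$nu_EN * state[["m_EN_S"]] * state[["M_V_S"]] * arr,
       J_EC_R = params$nu_EC * state[["m_EC_R"]] * state[["M_V_R"]] * arr,
       J_EN_R = params$nu_EN * state[["m_EN_R"]] * state[["M_V_R"]] * arr)
}

# maintenance + growth SU for one organ; all fluxes in C-mol/d
organ_maintenance_growth <- function(J_EC, J_EN, M_V, p_M, kappa_P, params,
                                     arr = 1) {
  demand <- p_M * M_V * arr
  pay_C <- min(demand, J_EC)
  pay_EN <- min(demand - pay_C, J_EN)
  deficit <- demand - pay_C - pay_EN
  C_avail <- J_EC - pay_C
  EN_avail <- J_EN - pay_EN
  rho <- c(C_avail / params$y_EC_V, EN_avail / params$y_EN_V)
  j_synth <- production_rate(rho, "pcsu")
  surplus_C <- C_avail - params$y_EC_V * j_synth
  surplus_EN <- EN_avail - params$y_EN_V * j_synth
  if (min(surplus_C, surplus_EN) < -1e-9 * max(1, J_EC, J_EN))
    stop("organ_maintenance_growth: negative growth-SU surplus", call. = FALSE)
  list(maint_paid_C = pay_C, maint_paid_EN = pay_EN, deficit = deficit,
       maint_CO2 = pay_C + pay_EN,
       maint_N_excess = params$n_NE * pay_EN,
       j_synth = j_synth,
       growth_struct = (1 - kappa_P) * j_synth,
       growth_prod = kappa_P * j_synth,
       growth_CO2 = (params$y_EC_V + params$y_EN_V - 1) * j_synth,
       growth_N_excess = (params$n_NE * params$y_EN_V - params$n_NV) * j_synth,
       surplus_C = max(surplus_C, 0), surplus_EN = max(surplus_EN, 0))
}

#' Maintenance payment and growth for both organs
#'
#' Per organ: maintenance demand `p_M * M_V` is paid from the mobilized
#' C-reserve flux first, then from the carbon of the mobilized N-rich
#' reserve; any shortfall is reported as a deficit. The remaining mobilized
#' fluxes feed the organ's growth SU (a PCSU with yields `y_EC_V`, `y_EN_V`),
#' whose output is split between structure and products by `kappa_P`; its
#' rejected fluxes are the organ's surplus, destined for translocation.
#'
#' @param cat Catabolic fluxes from [mobilization()].
#' @inheritParams acquisition
#' @param arr Arrhenius factor for the maintenance demand.
#' @return List with per-organ sublists `S` and `R` (see
#'   `organ_maintenance_growth` fields).
#' @export
maintenance_and_growth <- function(cat, state, params, arr = 1) {
  list(
    S = organ_maintenance_growth(cat$J_EC_S, cat$J_EN_S, state[["M_V_S"]],
                                 params$p_M_S, params$kappa_P_S, params, arr),
    R = organ_maintenance_growth(cat$J_EC_R, cat$J_EN_R, state[["M_V_R"]],
                                 params$p_M_R, params$kappa_P_R, params, arr)
  )
}

#' Surplus-sharing translocation
#'
#' Each organ exports only the fluxes its own growth SU rejected. The root's
#' surpluses and the shoot's N-reserve surplus arrive in the partner organ's
#' corresponding reserve; the shoot's CH2O surplus is the phloem stream that
#' feeds the root assembly SU. All transfers are multiplied by the
#' translocation efficiency `eta_T`; the carbon of the losses is respired
#' and their nitrogen becomes litter.
#'
#' @param mg Output of [maintenance_and_growth()].
#' @param params [plant_params()].
#' @return List with delivered fluxes `C_to_root_assembly`, `EN_to_root`,
#'   `C_to_shoot`, `EN_to_shoot` and loss totals `loss_CO2`, `loss_N`.
#' @export
translocate <- function(mg, params) {
  eta <- params$eta_T
  loss <- (1 - eta)
  list(C_to_root_assembly = eta * mg$S$surplus_C,
       EN_to_root = eta * mg$S$surplus_EN,
       C_to_shoot = eta * mg$R$surplus_C,
       EN_to_shoot = eta * mg$R$surplus_EN,
       loss_CO2 = loss * (mg$S$surplus_C + mg$S$surplus_EN +
                          mg$R$surplus_C + mg$R$surplus_EN),
       loss_N = loss * params$n_NE * (mg$S$surplus_EN + mg$R$surplus_EN))
}

#' Reserve assembly with N-reserve priority
#'
#' Fig-5-style assimilate routing: in each organ the SU forming the
#' nitrogen-rich reserve has priority, and the C-reserve "SU" receives the
#' CH2O it rejects. The root assembly PCSU runs first on the phloem CH2O
#' stream and the local share `(1 - lambda_N)` of N uptake; the N it rejects
#' rides the xylem to the shoot assembly PCSU, which also receives the whole
#' photosynthate flux and the direct share `lambda_N` of N uptake. N rejected
#' by the shoot SU is excreted (tracked as `N_excess`).
#'
#' @param J_A_C,J_A_N Assimilation fluxes from [acquisition()].
#' @param C_to_root CH2O flux delivered to the root assembly SU
#'   (phloem stream from [translocate()]).
#' @param params [plant_params()].
#' @return List with per-organ N-reserve synthesis `j_EN_S`/`j_EN_R`
#'   (C-mol d^-1), C-reserve inflows `rej_C_S`/`rej_C_R`, overhead
#'   `CO2_S`/`CO2_R`, the root-to-shoot forwarded N `rej_N_R` and the
#'   excreted `rej_N_S` (N-mol d^-1).
#' @export
assemble_reserves <- function(J_A_C, J_A_N, C_to_root, params) {
  yields <- c(params$y_C_EN, params$n_NE)
  # root first: priority SU on (phloem CH2O, local N share)
  root_in <- c(C_to_root, (1 - params$lambda_N) * J_A_N)
  rho_R <- root_in / yields
  j_R <- production_rate(rho_R, "pcsu")
  rej_R <- root_in - yields * j_R
  # shoot second: photosynthate + direct N share + root-rejected N
  shoot_in <- c(J_A_C, params$lambda_N * J_A_N + rej_R[2L])
  rho_S <- shoot_in / yields
  j_S <- production_rate(rho_S, "pcsu")
  rej_S <- shoot_in - yields * j_S
  if (min(rej_R, rej_S) < -1e-9 * max(1, J_A_C, J_A_N))
    stop("assemble_reserves: negative rejection flux", call. = FALSE)
  list(j_EN_R = j_R, rej_C_R = max(rej_R[1L], 0),
       CO2_R = (params$y_C_EN - 1) * j_R,
       rej_N_R = max(rej_R[2L], 0),
       j_EN_S = j_S, rej_C_S = max(rej_S[1L], 0),
       CO2_S = (params$y_C_EN - 1) * j_S,
       rej_N_S = max(rej_S[2L], 0))
}

#' Senescence and resorption
#'
#' Each structure loses `h_V * M_V` per day. A fraction `sigma` of the lost
#' biomass is resorbed: its nitrogen is repackaged into the organ's N-rich
#' reserve (as `n_NV/n_NE` C-mol of reserve per C-mol senesced, carrying the
#' N) and the remaining resorbed carbon refills the C reserve; the
#' unresorbed remainder becomes litter. Carbon and nitrogen are conserved
#' exactly.
#'
#' @inheritParams acquisition
#' @param arr Arrhenius factor applied to the senescence rate.
#' @return Per-organ list with `sen` (structure loss), `res_EC`, `res_EN`
#'   (reserve inflows, C-mol d^-1), `lit_C`, `lit_N`.
#' @export
senesce_and_resorb <- function(state, params, arr = 1) {
  per_organ <- function(M_V) {
    sen <- params$h_V * M_V * arr
    r <- params$n_NV / params$n_NE   # C-mol N-reserve per senesced C-mol
    list(sen = sen,
         res_EN = params$sigma * sen * r,
         res_EC = params$sigma * sen * (1 - r),
         lit_C = (1 - params$sigma) * sen,
         lit_N = (1 - params$sigma) * sen * params$n_NV)
  }
  list(S = per_organ(state[["M_V_S"]]), R = per_organ(state[["M_V_R"]]))
}

#' Right-hand side of the root-shoot DEB model
#'
#' Assembles the full flux cascade — acquisition, mobilization, maintenance
#' and growth, surplus translocation, priority reserve assembly, senescence
#' with resorption — into time derivatives of the state, and returns the
#' complete instantaneous flux ledger alongside for auditing.
#'
#' @param t Time (d).
#' @param state Named state vector ([plant_state()]).
#' @param scenario [make_scenario()] object.
#' @param params [plant_params()].
#' @param alive Logical; a dead plant has all-zero derivatives and fluxes.
#' @return List with `deriv` (named vector, same layout as `state`) and
#'   `ledger` (named numeric vector of every instantaneous flux).
#' @export
plant_derivatives <- function(t, state, scenario, params, alive = TRUE) {
  if (anyNA(state) || any(!is.finite(state)))
    stop("plant_derivatives: non-finite state at t=", t, call. = FALSE)
  if (!alive) {
    zero <- plant_derivatives(t, state, scenario, params, alive = TRUE)
    return(list(deriv = 0 * zero$deriv, ledger = 0 * zero$ledger))
  }
  env <- list(co2 = scenario$co2(t), light = scenario$light(t),
              soil_n = scenario$soil_n(t),
              temperature = scenario$temperature(t))
  arr <- arrhenius_factor(env$temperature, params$T_ref, params$T_A)

  acq <- acquisition(state, env, params)
  cat <- mobilization(state, params, arr)
  mg <- maintenance_and_growth(cat, state, params, arr)
  tr <- translocate(mg, params)
  asm <- assemble_reserves(acq$J_A_C, acq$J_A_N, tr$C_to_root_assembly, params)
  sr <- senesce_and_resorb(state, params, arr)

  M_V_S <- state[["M_V_S"]]; M_V_R <- state[["M_V_R"]]

  dM_V_S <- mg$S$growth_struct - sr$S$sen
  dM_V_R <- mg$R$growth_struct - sr$R$sen

  # reserve mass balances, then density form with net-growth dilution
  dM_EC_S <- asm$rej_C_S + tr$C_to_shoot + sr$S$res_EC - cat$J_EC_S
  dM_EN_S <- asm$j_EN_S + tr$EN_to_shoot + sr$S$res_EN - cat$J_EN_S
  dM_EC_R <- asm$rej_C_R + sr$R$res_EC - cat$J_EC_R
  dM_EN_R <- asm$j_EN_R + tr$EN_to_root + sr$R$res_EN - cat$J_EN_R
  density_rate <- function(dM_E, m, M_V, dM_V) {
    if (M_V <= 0) return(0)
    dM_E / M_V - m * dM_V / M_V
  }

  dCO2 <- mg$S$maint_CO2 + mg$R$maint_CO2 +
    mg$S$growth_CO2 + mg$R$growth_CO2 +
    asm$CO2_S + asm$CO2_R + tr$loss_CO2
  dLitC <- sr$S$lit_C + sr$R$lit_C
  dLitN <- sr$S$lit_N + sr$R$lit_N + tr$loss_N
  dNex <- mg$S$maint_N_excess + mg$R$maint_N_excess +
    mg$S$growth_N_excess + mg$R$growth_N_excess + asm$rej_N_S

  deriv <- c(
    M_V_S = dM_V_S, M_V_R = dM_V_R,
    m_EC_S = density_rate(dM_EC_S, state[["m_EC_S"]], M_V_S, dM_V_S),
    m_EN_S = density_rate(dM_EN_S, state[["m_EN_S"]], M_V_S, dM_V_S),
    m_EC_R = density_rate(dM_EC_R, state[["m_EC_R"]], M_V_R, dM_V_R),
    m_EN_R = density_rate(dM_EN_R, state[["m_EN_R"]], M_V_R, dM_V_R),
    M_P = mg$S$growth_prod + mg$R$growth_prod,
    M_litter_C = dLitC, M_litter_N = dLitN,
    M_CO2 = dCO2, N_excess = dNex,
    M_A_C = acq$J_A_C, M_A_N = acq$J_A_N)

  ledger <- c(
    J_A_C = acq$J_A_C, J_A_N = acq$J_A_N,
    J_EC_cat_S = cat$J_EC_S, J_EN_cat_S = cat$J_EN_S,
    J_EC_cat_R = cat$J_EC_R, J_EN_cat_R = cat$J_EN_R,
    maint_CO2_S = mg$S$maint_CO2, maint_CO2_R = mg$R$maint_CO2,
    maint_N_excess_S = mg$S$maint_N_excess,
    maint_N_excess_R = mg$R$maint_N_excess,
    maint_deficit_S = mg$S$deficit, maint_deficit_R = mg$R$deficit,
    j_synth_S = mg$S$j_synth, j_synth_R = mg$R$j_synth,
    growth_struct_S = mg$S$growth_struct, growth_struct_R = mg$R$growth_struct,
    growth_prod_S = mg$S$growth_prod, growth_prod_R = mg$R$growth_prod,
    growth_CO2_S = mg$S$growth_CO2, growth_CO2_R = mg$R$growth_CO2,
    growth_N_excess_S = mg$S$growth_N_excess,
    growth_N_excess_R = mg$R$growth_N_excess,
    surplus_C_S = mg$S$surplus_C, surplus_EN_S = mg$S$surplus_EN,
    surplus_C_R = mg$R$surplus_C, surplus_EN_R = mg$R$surplus_EN,
    tr_C_to_root_assembly = tr$C_to_root_assembly,
    tr_EN_to_root = tr$EN_to_root,
    tr_C_to_shoot = tr$C_to_shoot, tr_EN_to_shoot = tr$EN_to_shoot,
    tr_loss_CO2 = tr$loss_CO2, tr_loss_N = tr$loss_N,
    asm_j_EN_S = asm$j_EN_S, asm_j_EN_R = asm$j_EN_R,
    asm_rej_C_S = asm$rej_C_S, asm_rej_C_R = asm$rej_C_R,
    asm_CO2_S = asm$CO2_S, asm_CO2_R = asm$CO2_R,
    asm_rej_N_R = asm$rej_N_R, asm_rej_N_S = asm$rej_N_S,
    sen_S = sr$S$sen, sen_R = sr$R$sen,
    res_EC_S = sr$S$res_EC, res_EN_S = sr$S$res_EN,
    res_EC_R = sr$R$res_EC, res_EN_R = sr$R$res_EN,
    lit_C_S = sr$S$lit_C, lit_N_S = sr$S$lit_N,
    lit_C_R = sr$R$lit_C, lit_N_R = sr$R$lit_N)

  if (anyNA(deriv) || any(!is.finite(deriv))) {
    stop("plant_derivatives: non-finite derivative at t=", t, "; ledger: ",
         paste(names(ledger), format(ledger), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  list(deriv = deriv, ledger = ledger)
}

#' Instantaneous elemental closure of a flux ledger
#'
#' Recombines the primitive ledger entries into input, output and storage
#' rates for carbon and nitrogen; for a correctly wired right-hand side both
#' balances are zero to rounding.
#'
#' @param ledger Named flux vector as returned by [plant_derivatives()].
#' @param params [plant_params()].
#' @return List with `C_balance` and `N_balance`
#'   (input - output - storage, ~0).
#' @export
ledger_closure <- function(ledger, params) {
  l <- as.list(ledger)
  # carbon storage rate reconstructed flux by flux
  dV <- (l$growth_struct_S - l$sen_S) + (l$growth_struct_R - l$sen_R)
  dP <- l$growth_prod_S + l$growth_prod_R
  dEC <- (l$asm_rej_C_S + l$tr_C_to_shoot + l$res_EC_S - l$J_EC_cat_S) +
    (l$asm_rej_C_R + l$res_EC_R - l$J_EC_cat_R)
  dEN <- (l$asm_j_EN_S + l$tr_EN_to_shoot + l$res_EN_S - l$J_EN_cat_S) +
    (l$asm_j_EN_R + l$tr_EN_to_root + l$res_EN_R - l$J_EN_cat_R)
  dCO2 <- l$maint_CO2_S + l$maint_CO2_R + l$growth_CO2_S + l$growth_CO2_R +
    l$asm_CO2_S + l$asm_CO2_R + l$tr_loss_CO2
  dLitC <- l$lit_C_S + l$lit_C_R
  C_balance <- l$J_A_C - dCO2 - dLitC - (dV + dP + dEC + dEN)
  n_NV <- params$n_NV; n_NE <- params$n_NE
  dNex <- l$maint_N_excess_S + l$maint_N_excess_R +
    l$growth_N_excess_S + l$growth_N_excess_R + l$asm_rej_N_S
  dLitN <- l$lit_N_S + l$lit_N_R + l$tr_loss_N
  N_balance <- l$J_A_N - dNex - dLitN - n_NV * (dV + dP) - n_NE * dEN
  list(C_balance = C_balance, N_balance = N_balance)
}

#' Starvation check
#'
#' An organ dies of carbon starvation when it cannot pay its maintenance
#' costs (positive deficit) while both of its reserves are depleted below
#' `eps_death`.
#'
#' @param state Named state vector.
#' @param ledger Flux ledger at the same instant.
#' @param params [plant_params()].
#' @param t Time of evaluation (for the event record).
#' @return List with `alive` (logical) and `event` (NULL, or a record with
#'   `time`, `organ`, `deficit`).
#' @export
starvation_check <- function(state, ledger, params, t = NA_real_) {
  # threshold with a tiny slack so the event-located state (where the larger
  # reserve sits exactly at eps_death) is classified consistently
  eps <- params$eps_death * (1 + 1e-9)
  for (organ in c("S", "R")) {
    deficit <- ledger[[paste0("maint_deficit_", organ)]]
    m_EC <- state[[paste0("m_EC_", organ)]]
    m_EN <- state[[paste0("m_EN_", organ)]]
    if (deficit > 0 && m_EC <= eps && m_EN <= eps) {
      return(list(alive = FALSE,
                  event = list(type = "starvation", time = t, organ = organ,
                               deficit = deficit)))
    }
  }
  list(alive = TRUE, event = NULL)
}

# continuous indicator for event detection: crosses zero at starvation
starvation_indicator <- function(state, ledger, params) {
  g <- 1
  for (organ in c("S", "R")) {
    if (ledger[[paste0("maint_deficit_", organ)]] > 0) {
      g <- min(g, max(state[[paste0("m_EC_", organ)]],
                      state[[paste0("m_EN_", organ)]]) - params$eps_death)
    }
  }
  g
}
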