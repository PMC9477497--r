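test_that("parameter validation enforces ranges and stoichiometric closure", {
  expect_s3_class(plant_params(), "plant_params")
  expect_error(plant_params(eta_T = 1.5), "eta_T")
  expect_error(plant_params(eta_T = 1.5), "\\(0, 1\\]")
  expect_error(plant_params(lambda_N = -0.1), "lambda_N")
  expect_error(plant_params(j_CAm = 0), "j_CAm")
  # N supplied by the reserve flux must cover the N bound into structure
  expect_error(plant_params(y_EN_V = 0.2, n_NE = 0.25, n_NV = 0.1),
               "closure")
  # several violations are aggregated into one message
  err <- tryCatch(plant_params(eta_T = 2, sigma = 3), error = conditionMessage)
  expect_match(err, "eta_T")
  expect_match(err, "sigma")
})

test_that("acquisition scales linearly with structure and saturates with the environment", {
  p <- plant_params()
  env <- list(co2 = 1, light = 1, soil_n = 1, temperature = p$T_ref)
  s0 <- plant_state(M_V_S = 0, M_V_R = 1)
  expect_identical(acquisition(s0, env, p)$J_A_C, 0)
  s1 <- plant_state(M_V_S = 1, M_V_R = 1)
  s2 <- plant_state(M_V_S = 2, M_V_R = 1)
  a1 <- acquisition(s1, env, p); a2 <- acquisition(s2, env, p)
  expect_equal(a2$J_A_C, 2 * a1$J_A_C, tolerance = 1e-12)
  # at half-saturation in CO2 and light, j_CAm = 1, M_V_S = 2: 2 * 1/2 * 1/2
  expect_equal(a2$J_A_C, 0.5, tolerance = 1e-12)
  # alternative PCSU coupling of CO2 and light is below the product form at
  # equal arrivals
  p2 <- plant_params(light_mode = "pcsu")
  expect_equal(acquisition(s2, env, p2)$J_A_C,
               2 * production_rate(c(0.5, 0.5), "pcsu"), tolerance = 1e-12)
})

test_that("reserve assembly gives the nitrogen-rich reserve priority", {
  p <- plant_params()
  # no nitrogen anywhere: every CH2O flux ends up in the C reserves
  asm <- assemble_reserves(J_A_C = 1, J_A_N = 0, C_to_root = 0.5, p)
  expect_identical(asm$j_EN_S, 0)
  expect_identical(asm$j_EN_R, 0)
  expect_equal(asm$rej_C_S, 1)
  expect_equal(asm$rej_C_R, 0.5)
  # balanced scaled arrivals at the shoot SU synthesize at 2/3 of the
  # minimum-rule reference
  # (with no phloem carbon the root SU forwards its whole N share, so the
  # shoot SU sees the full J_A_N)
  rho_ref <- 0.8
  asm2 <- assemble_reserves(J_A_C = rho_ref * p$y_C_EN,
                            J_A_N = rho_ref * p$n_NE,
                            C_to_root = 0, p)
  expect_equal(asm2$j_EN_S, 2 / 3 * rho_ref, tolerance = 1e-12)
  # lambda_N = 1 with no phloem carbon: root synthesizes nothing and all
  # uptake N reaches the shoot SU
  p3 <- plant_params(lambda_N = 1)
  asm3 <- assemble_reserves(J_A_C = 0, J_A_N = 2, C_to_root = 0, p3)
  expect_identical(asm3$j_EN_R, 0)
  expect_equal(asm3$rej_N_S, 2, tolerance = 1e-12)
})

test_that("maintenance is paid before growth and surpluses are rejected", {
  p <- plant_params()
  s <- plant_state()
  # catabolic C flux exactly covers maintenance: no growth, no deficit,
  # the whole N-reserve flux is surplus
  demand <- p$p_M_S * 1
  cat <- list(J_EC_S = demand, J_EN_S = 0.3, J_EC_R = 0, J_EN_R = 0)
  mg <- maintenance_and_growth(cat, s, p)
  expect_equal(mg$S$j_synth, 0)
  expect_equal(mg$S$deficit, 0)
  expect_equal(mg$S$surplus_EN, 0.3 - 0, tolerance = 1e-12)
  # nothing mobilized: the full demand is a deficit
  cat0 <- list(J_EC_S = 0, J_EN_S = 0, J_EC_R = 0, J_EN_R = 0)
  mg0 <- maintenance_and_growth(cat0, s, p)
  expect_equal(mg0$S$deficit, p$p_M_S)
  expect_equal(mg0$R$deficit, p$p_M_R)
  # maintenance falls back on the N-reserve carbon and excretes its N
  cat1 <- list(J_EC_S = 0.02, J_EN_S = 0.1, J_EC_R = 0, J_EN_R = 0)
  mg1 <- maintenance_and_growth(cat1, s, p)
  expect_equal(mg1$S$maint_paid_EN, p$p_M_S - 0.02, tolerance = 1e-12)
  expect_equal(mg1$S$maint_N_excess, p$n_NE * (p$p_M_S - 0.02),
               tolerance = 1e-12)
})

test_that("growth splits between structure and products by kappa_P", {
  p <- plant_params(kappa_P_S = 0.2)
  # equal scaled arrivals after maintenance: synthesis = 2/3 * min reference
  rho <- 0.5
  cat <- list(J_EC_S = p$p_M_S + rho * p$y_EC_V, J_EN_S = rho * p$y_EN_V,
              J_EC_R = 0, J_EN_R = 0)
  mg <- maintenance_and_growth(cat, plant_state(), p)
  expect_equal(mg$S$j_synth, 2 / 3 * rho, tolerance = 1e-12)
  expect_equal(mg$S$growth_struct, 0.8 * mg$S$j_synth, tolerance = 1e-12)
  expect_equal(mg$S$growth_prod, 0.2 * mg$S$j_synth, tolerance = 1e-12)
})

test_that("translocation delivers surpluses to the partner with eta_T efficiency", {
  p <- plant_params(eta_T = 1)
  mg <- list(S = list(surplus_C = 0.4, surplus_EN = 0.1),
             R = list(surplus_C = 0.2, surplus_EN = 0.3))
  tr <- translocate(mg, p)
  # lossless: everything exported arrives somewhere
  total_out <- 0.4 + 0.1 + 0.2 + 0.3
  total_in <- tr$C_to_root_assembly + tr$EN_to_root + tr$C_to_shoot +
    tr$EN_to_shoot
  expect_equal(total_in, total_out, tolerance = 1e-12)
  expect_identical(tr$loss_CO2, 0)
  p9 <- plant_params(eta_T = 0.9)
  mg1 <- list(S = list(surplus_C = 1, surplus_EN = 0),
              R = list(surplus_C = 0, surplus_EN = 0))
  tr9 <- translocate(mg1, p9)
  expect_equal(tr9$C_to_root_assembly, 0.9, tolerance = 1e-12)
  expect_equal(tr9$loss_CO2, 0.1, tolerance = 1e-12)
})

test_that("senescence conserves carbon and nitrogen through resorption", {
  p <- plant_params(h_V = 0.01, sigma = 0.5)
  sr <- senesce_and_resorb(plant_state(M_V_S = 100, M_V_R = 1), p)
  expect_equal(sr$S$sen, 1, tolerance = 1e-12)
  expect_equal(sr$S$res_EC + sr$S$res_EN, 0.5, tolerance = 1e-12)
  expect_equal(sr$S$lit_C, 0.5, tolerance = 1e-12)
  # element-by-element closure of the senescence pathway
  expect_equal(sr$S$res_EC + sr$S$res_EN + sr$S$lit_C, sr$S$sen,
               tolerance = 1e-14)
  expect_equal(p$n_NE * sr$S$res_EN + sr$S$lit_N, p$n_NV * sr$S$sen,
               tolerance = 1e-14)
  p0 <- plant_params(h_V = 0)
  sr0 <- senesce_and_resorb(plant_state(), p0)
  expect_identical(sr0$S$sen, 0)
  expect_identical(sr0$R$lit_C, 0)
  # full resorption leaves no litter
  p1 <- plant_params(sigma = 1)
  sr1 <- senesce_and_resorb(plant_state(), p1)
  expect_identical(sr1$S$lit_C, 0)
  expect_identical(sr1$S$lit_N, 0)
})

test_that("the right-hand side conserves carbon and nitrogen exactly", {
  sc <- const_scenario()
  set.seed(11)
  for (i in 1:12) {
    p <- plant_params(j_NAm = stats::runif(1, 0.02, 0.3),
                      eta_T = stats::runif(1, 0.5, 1),
                      sigma = stats::runif(1, 0, 1),
                      lambda_N = stats::runif(1, 0, 1),
                      kappa_P_S = stats::runif(1, 0, 0.5))
    s <- plant_state(M_V_S = stats::runif(1, 0.1, 5),
                     M_V_R = stats::runif(1, 0.1, 5),
                     m_EC_S = stats::runif(1, 0, 1),
                     m_EN_S = stats::runif(1, 0, 1),
                     m_EC_R = stats::runif(1, 0, 1),
                     m_EN_R = stats::runif(1, 0, 1))
    d <- plant_derivatives(0, s, sc, p)
    bal <- ledger_closure(d$ledger, p)
    expect_lt(abs(bal$C_balance), 1e-12)
    expect_lt(abs(bal$N_balance), 1e-12)
    expect_true(all(d$ledger >= 0))
  }
})

test_that("the empty state is absorbing and dead plants have zero derivatives", {
  sc <- const_scenario()
  p <- plant_params()
  s0 <- plant_state(M_V_S = 0, M_V_R = 0, m_EC_S = 0, m_EN_S = 0,
                    m_EC_R = 0, m_EN_R = 0)
  d <- plant_derivatives(0, s0, sc, p)
  expect_true(all(d$deriv == 0))
  s1 <- plant_state()
  d_dead <- plant_derivatives(0, s1, sc, p, alive = FALSE)
  expect_true(all(d_dead$deriv == 0))
  expect_true(all(d_dead$ledger == 0))
})

test_that("starvation requires a deficit with both reserves depleted", {
  p <- plant_params()
  sc <- const_scenario()
  s_ok <- plant_state()
  led_ok <- plant_derivatives(0, s_ok, sc, p)$ledger
  expect_true(starvation_check(s_ok, led_ok, p)$alive)
  # deficit with exhausted shoot reserves: dead even if root reserves full
  s_bad <- plant_state(m_EC_S = 0, m_EN_S = 0, m_EC_R = 0.5, m_EN_R = 0.5)
  led_bad <- plant_derivatives(0, s_bad, const_scenario(co2 = 0, light = 0,
                                                        soil_n = 0),
                               p)$ledger
  expect_gt(led_bad[["maint_deficit_S"]], 0)
  chk <- starvation_check(s_bad, led_bad, p, t = 12)
  expect_false(chk$alive)
  expect_identical(chk$event$organ, "S")
  expect_identical(chk$event$time, 12)
})

test_that("cutting soil nitrogen drains N reserves and accumulates carbon", {
  p <- plant_params()
  # start from the balanced-growth interior state, then remove soil N
  bal <- simulate_plant(p, const_scenario(),
                        settings = solver_settings(t_span = c(0, 300),
                                                   record_every = 5))
  s_bal <- bal$states[nrow(bal$states), ]
  s0 <- plant_state(M_V_S = 1, M_V_R = 1,
                    m_EC_S = s_bal[["m_EC_S"]], m_EN_S = s_bal[["m_EN_S"]],
                    m_EC_R = s_bal[["m_EC_R"]], m_EN_R = s_bal[["m_EN_R"]])
  npoor <- simulate_plant(p, const_scenario(soil_n = 0.05), state0 = s0,
                          settings = solver_settings(t_span = c(0, 100),
                                                     record_every = 2))
  final <- npoor$states[nrow(npoor$states), ]
  expect_lt(final[["m_EN_S"]], s0[["m_EN_S"]])
  expect_lt(final[["m_EN_R"]], s0[["m_EN_R"]])
  expect_gt(final[["m_EC_S"]], s0[["m_EC_S"]])
  expect_gt(final[["m_EC_R"]], s0[["m_EC_R"]])
})

test_that("a corrupted ledger is caught by the audit", {
  p <- plant_params()
  traj <- simulate_plant(p, const_scenario(),
                         settings = solver_settings(t_span = c(0, 50),
                                                    record_every = 1))
  clean <- mass_balance_audit(traj)
  expect_lt(clean$max_ledger_C, 1e-10)
  traj$ledgers[10, "growth_CO2_S"] <- traj$ledgers[10, "growth_CO2_S"] + 0.25
  dirty <- mass_balance_audit(traj)
  expect_gt(dirty$max_ledger_C, 0.2 / max(1, traj$ledgers[10, "J_A_C"]))
})
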