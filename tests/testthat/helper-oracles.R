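# Stochastic binding-site oracle for the parallel complementary SU.
#
# One SU with one binding site per substrate; substrate i arrives with
# exponential inter-arrival times at scaled rate rho_i; a product is
# released the instant both sites are occupied, emptying both. The cycle
# time is max(Exp(rho1), Exp(rho2)), so the long-run production rate is
# n_cycles / total_time. Independent of the closed-form implementation.
su_stochastic_rate <- function(rho1, rho2, n_cycles = 20000, seed = 1) {
  withr::with_seed(seed, {
    cycles <- pmax(stats::rexp(n_cycles, rho1), stats::rexp(n_cycles, rho2))
  })
  mean_ct <- mean(cycles)
  rate <- 1 / mean_ct
  se_ct <- stats::sd(cycles) / sqrt(n_cycles)
  list(rate = rate, se = rate^2 * se_ct)   # delta method
}

# Brute-force nested-grid search for the root-stem-leaf flux fixed point:
# minimizes the residual of the two stem pass-through fluxes over a grid,
# refining around the best cell. Independent of the damped iteration.
rsl_grid_oracle <- function(state, params, rounds = 10, n = 41) {
  A_C <- params$a_C * state[["m_L"]]
  A_N <- params$a_N * state[["m_R"]]
  yC <- params$y_C; yN <- params$y_N
  resid <- function(x) {
    g_L <- production_rate(c(A_C / yC[["L"]], x[2] / yN[["L"]]), params$rule)
    C_ls <- max(A_C - yC[["L"]] * g_L, 0)
    g_R <- production_rate(c(x[1] / yC[["R"]], A_N / yN[["R"]]), params$rule)
    N_rs <- max(A_N - yN[["R"]] * g_R, 0)
    g_S <- production_rate(c(C_ls / yC[["S"]], N_rs / yN[["S"]]), params$rule)
    x_new <- pmax(c(C_ls - yC[["S"]] * g_S, N_rs - yN[["S"]] * g_S), 0)
    max(abs(x_new - x))
  }
  lo <- c(0, 0)
  hi <- c(A_C, A_N)
  best <- c(0, 0)
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = n)
    g2 <- seq(lo[2], hi[2], length.out = n)
    vals <- outer(g1, g2, Vectorize(function(a, b) resid(c(a, b))))
    idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[idx[1]], g2[idx[2]])
    step <- c(diff(range(g1)) / (n - 1), diff(range(g2)) / (n - 1))
    lo <- pmax(best - 2 * step, 0)
    hi <- best + 2 * step
  }
  best
}

const_scenario <- function(co2 = 1, light = 1, soil_n = 1, temp = 293.15) {
  make_scenario("constant", list(co2 = co2, light = light, soil_n = soil_n,
                                 temperature = temp))
}
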