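test_that("SU specification validates its stoichiometry", {
  expect_s3_class(su_spec("pcsu", c(1, 2), "growth"), "su_spec")
  expect_error(su_spec("pcsu", c(1, -1), "bad"), "bad")
  expect_error(su_spec("pcsu", c(1, Inf)), "finite")
  expect_error(su_spec("liebig", c(1, 1)))
})

test_that("scaled arrivals divide each flux by its yield", {
  su <- su_spec("pcsu", c(2, 1))
  expect_equal(scaled_arrivals(c(2, 1), su), c(1, 1))
  expect_equal(scaled_arrivals(c(0, 5), su_spec("pcsu", c(1, 1))), c(0, 5))
  expect_equal(scaled_arrivals(3, su_spec("minimum", 1.5, "one")), 2)
})

test_that("length mismatch error names the SU label", {
  su <- su_spec("pcsu", c(1, 1), label = "assembly-root")
  expect_error(scaled_arrivals(c(1, 2, 3), su), "assembly-root")
  expect_error(scaled_arrivals(c(-1, 2), su), "nonnegative")
})

test_that("production rates match the closed forms", {
  # equal balanced arrivals: PCSU runs at exactly 2/3 of the minimum rule
  expect_identical(production_rate(c(1, 1), "minimum"), 1)
  expect_equal(production_rate(c(1, 1), "pcsu"), 2 / 3, tolerance = 1e-15)
  expect_equal(production_rate(c(2, 1), "pcsu"), 6 / 7, tolerance = 1e-15)
  expect_identical(production_rate(c(2, 1), "minimum"), 1)
  # missing complementary substrate stalls production under either rule
  expect_identical(production_rate(c(0, 1), "pcsu"), 0)
  expect_identical(production_rate(c(0, 1), "minimum"), 0)
  # single-substrate SUs process everything
  expect_identical(production_rate(5, "pcsu"), 5)
  expect_identical(production_rate(5, "minimum"), 5)
  expect_error(production_rate(c(-1, 1), "pcsu"), "nonnegative")
})

test_that("PCSU is less efficient than the minimum rule and monotone", {
  grid <- expand.grid(r1 = c(0.1, 0.5, 1, 2, 10), r2 = c(0.1, 1, 3, 10))
  for (i in seq_len(nrow(grid))) {
    rho <- c(grid$r1[i], grid$r2[i])
    j_min <- production_rate(rho, "minimum")
    j_pc <- production_rate(rho, "pcsu")
    expect_lt(j_pc, j_min)
    # monotone nondecreasing in each argument
    expect_gte(production_rate(rho + c(0.1, 0), "pcsu"), j_pc)
    expect_gte(production_rate(rho + c(0, 0.1), "pcsu"), j_pc)
  }
  # exactly 2/3 at equal arrivals, for any magnitude
  for (rho in c(1e-6, 0.03, 1, 47, 1e8)) {
    expect_equal(production_rate(c(rho, rho), "pcsu") / rho, 2 / 3,
                 tolerance = 1e-12)
  }
  # saturating limit: abundant partner substrate recovers the minimum rule
  expect_equal(production_rate(c(1, 1e12), "pcsu"), 1, tolerance = 1e-9)
})

test_that("inclusion-exclusion generalization agrees with the k = 2 form", {
  for (rho in list(c(1, 1), c(2, 1), c(0.3, 7))) {
    byhand <- 1 / (1 / rho[1] + 1 / rho[2] - 1 / sum(rho))
    expect_equal(production_rate(rho, "pcsu"), byhand, tolerance = 1e-14)
  }
  # k = 3 with one substrate in vast excess reduces to the k = 2 case
  expect_equal(production_rate(c(1, 2, 1e14), "pcsu"),
               production_rate(c(1, 2), "pcsu"), tolerance = 1e-9)
  # k = 3 is below every pairwise k = 2 rate (extra requirement slows it)
  j3 <- production_rate(c(1, 1, 1), "pcsu")
  expect_lt(j3, production_rate(c(1, 1), "pcsu"))
  expect_gt(j3, 0)
})

test_that("substrate conservation holds at every SU", {
  set.seed(42)
  for (i in 1:20) {
    yields <- stats::runif(2, 0.2, 3)
    arrivals <- stats::runif(2, 0, 5)
    for (rule in c("minimum", "pcsu")) {
      su <- su_spec(rule, yields)
      out <- su_process(arrivals, su)
      expect_equal(out$consumed + out$rejected, arrivals, tolerance = 1e-12)
      expect_true(all(out$rejected >= 0))
    }
  }
})

test_that("rejection kinetics recover the closed-form surpluses", {
  su <- su_spec("pcsu", c(1, 1))
  j <- production_rate(c(1, 1), "pcsu")
  expect_equal(rejected_fluxes(c(1, 1), su, j), c(1, 1) / 3,
               tolerance = 1e-12)
  su_min <- su_spec("minimum", c(1, 1))
  expect_equal(rejected_fluxes(c(2, 1), su_min, 1), c(1, 0))
  expect_equal(rejected_fluxes(c(0, 0), su, 0), c(0, 0))
  # an inconsistent production rate signals a wiring bug
  expect_error(rejected_fluxes(c(1, 1), su, 2), "inconsistency")
})

test_that("saturating uptake is hyperbolic in the concentration", {
  expect_equal(saturating_uptake(1, j_max = 2, K = 1), 1)   # half-saturation
  expect_identical(saturating_uptake(0, 2, 1), 0)
  expect_equal(saturating_uptake(3, 2, 1), 1.5)
  conc <- seq(0, 50, by = 0.5)
  j <- saturating_uptake(conc, 2, 1)
  expect_true(all(diff(j) > 0))
  expect_true(all(j < 2))
  expect_error(saturating_uptake(-1, 2, 1), "nonnegative")
})

test_that("deterministic PCSU rate matches the stochastic binding-site oracle", {
  rhos <- c(0.5, 1, 2)
  for (r1 in rhos) {
    for (r2 in rhos) {
      oracle <- su_stochastic_rate(r1, r2, n_cycles = 20000,
                                   seed = 1000 + 100 * r1 + r2)
      expect_lt(abs(production_rate(c(r1, r2), "pcsu") - oracle$rate),
                3 * oracle$se)
    }
  }
})
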