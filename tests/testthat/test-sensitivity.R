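test_that("parameter sampling is seeded, unbiased and respects zero errors", {
  reg <- broccoli_params()
  d1 <- sample_parameters(reg, 500, seed = 11)
  d2 <- sample_parameters(reg, 500, seed = 11)
  expect_identical(d1, d2)                       # determinism contract
  expect_equal(colnames(d1), reg$name)
  # law of large numbers: column means within 4 se of the base values
  for (i in seq_len(nrow(reg))) {
    expect_lt(abs(mean(d1[, i]) - reg$base[i]),
              4 * reg$abs_error[i] / sqrt(500) + 1e-12)
  }
  # zero errors give exactly the base vector
  reg0 <- reg; reg0$abs_error[] <- 0
  expect_equal(as.numeric(sample_parameters(reg0, 1, seed = 1)),
               reg$base, tolerance = 1e-15)
  expect_true(all(d1 > 0))
})

test_that("Monte Carlo BOF collapses to the deterministic value without noise", {
  reg0 <- broccoli_params(); reg0$abs_error[] <- 0
  mc <- monte_carlo_bof(reg0, n = 200, seed = 3)
  expect_identical(mc$sd, 0)
  expect_equal(mc$mean, frozen$bof_base, tolerance = 1e-10)
})

test_that("OAT ranges are signed, deterministic and reject unknown names", {
  expect_error(oat_bof_range(name = "bogus"), "unknown parameter")
  expect_gt(oat_bof_range(name = "W_p"), 0)
  expect_lt(oat_bof_range(name = "k_m"), 0)
  # a parameter with zero error contributes a zero range
  reg <- broccoli_params()
  reg$abs_error[reg$name == "Ea_max"] <- 0
  expect_identical(oat_bof_range(reg, "Ea_max"), 0)
  # V_T cancels out of the BOF balance entirely
  expect_equal(oat_bof_range(name = "V_T"), 0, tolerance = 1e-12)
  # OAT table is consistent with the single-parameter ranges
  oat <- oat_bof_all()
  expect_equal(oat$range_s[oat$name == "W_p"], oat_bof_range(name = "W_p"))
  expect_true(all(diff(oat$abs_range) <= 0))     # sorted by magnitude
})

test_that("Pareto shares are normalised variance contributions", {
  oat <- oat_bof_all()
  pc <- pareto_contributions(oat)
  expect_equal(sum(pc$share), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$share) <= 0))
  expect_equal(tail(pc$cumulative, 1), 1, tolerance = 1e-12)
  # single nonzero range takes the whole share
  one <- single_error_registry("W_p")
  pc1 <- pareto_contributions(oat_bof_all(one))
  expect_equal(pc1$share[1], 1, tolerance = 1e-12)
  expect_equal(pc1$name[1], "W_p")
  # all-zero ranges are rejected
  reg0 <- broccoli_params(); reg0$abs_error[] <- 0
  expect_error(pareto_contributions(oat_bof_all(reg0)), "zero")
})

test_that("correlation signs follow the OAT sensitivity signs", {
  mc <- monte_carlo_bof(n = 10000, seed = 5)
  r <- bof_correlations(mc)
  oat <- oat_bof_all()
  for (nm in oat$name[oat$abs_range > 1e-9]) {
    expect_equal(sign(r$r[r$name == nm]), sign(oat$range_s[oat$name == nm]),
                 info = nm)
  }
  # single-factor limit: all output variance from one input
  one <- monte_carlo_bof(single_error_registry("W_p"), n = 2000, seed = 8)
  r1 <- bof_correlations(one)
  expect_gt(r1$r[r1$name == "W_p"], 0.999)
  expect_true(all(r1$constant[r1$name != "W_p"]))
  expect_true(all(r1$r[r1$name != "W_p"] == 0))
})

test_that("quadrature of OAT half-ranges reconstructs the Monte Carlo spread", {
  mc <- monte_carlo_bof(n = 10000, seed = 13)
  oat <- oat_bof_all()
  quad <- sqrt(sum((oat$abs_range / 2)^2))
  expect_lt(abs(quad - mc$sd) / mc$sd, 0.15)
})

test_that("Monte Carlo results are bit-reproducible under a fixed seed", {
  a <- monte_carlo_bof(n = 1000, seed = 99)
  b <- monte_carlo_bof(n = 1000, seed = 99)
  expect_identical(a$bof, b$bof)
  expect_identical(a$draws, b$draws)
})

test_that("O2-trajectory perturbations respond to the perturbed load", {
  prof <- temperature_profile(12, 20)
  cfg <- sim_config(dt = 30)
  # heavier load consumes faster: set point reached earlier than baseline
  up <- oat_o2_delta(name = "W_p", profile = prof, sign = 1, cfg = cfg)
  expect_lt(up$summary$time_to_setpoint_h[2], up$summary$time_to_setpoint_h[1])
  down <- oat_o2_delta(name = "W_p", profile = prof, sign = -1, cfg = cfg)
  expect_gt(down$summary$time_to_setpoint_h[2], down$summary$time_to_setpoint_h[1])
  # post-pulldown both arms oscillate below the set point (at 20 degC the
  # hourly sawtooth spans ~1.5 points, so its mean sits near 2.2-2.3%)
  expect_true(all(up$summary$o2_mean > 2.0 & up$summary$o2_mean < 3.0))
  # zero perturbation leaves the trajectory untouched
  reg <- broccoli_params()
  reg$abs_error[reg$name == "Ea_max"] <- 0
  null <- oat_o2_delta(reg, name = "Ea_max", profile = prof, cfg = cfg)
  expect_true(all(null$delta$delta_o2 == 0))
})
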