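test_that("Arrhenius factor matches the closed form and its limits", {
  # zero activation energy: the factor is the bare pre-exponential
  for (T in c(-10, 0, 10, 25)) {
    expect_identical(arrhenius_factor(1, 0, T), 1)
  }
  expect_equal(arrhenius_factor(2.76e17, 8.63e4, 10), frozen$vmax_10,
               tolerance = 1e-12)
  expect_equal(arrhenius_factor(9.90e19, 1.03e5, 10), frozen$rmin_10,
               tolerance = 1e-12)
  expect_error(arrhenius_factor(NA, 1e4, 10), "finite")
  expect_error(arrhenius_factor(-1, 1e4, 10), "positive")
  # strictly increasing in temperature
  temps <- seq(0, 25, by = 1)
  vals <- arrhenius_factor(2.76e17, 8.63e4, temps)
  expect_true(all(diff(vals) > 0))
})

test_that("Arrhenius temperature ratio obeys the closed-form Q10 identity", {
  rg <- ma_constants()$rg
  for (T in c(0, 5, 10, 15)) {
    for (ea in c(5e4, 8.63e4, 1.03e5)) {
      ratio <- arrhenius_factor(1e18, ea, T + 10) / arrhenius_factor(1e18, ea, T)
      expect_equal(ratio, exp(ea * 10 / (rg * (T + 273) * (T + 283))),
                   tolerance = 1e-12)
    }
  }
})

test_that("specific respiration reproduces the enzyme-kinetic form", {
  # zero substrate: Michaelis term vanishes, only the low-O2 residual remains
  expect_equal(respiration_specific(base_p, gas_conditions(0, 15, 10)),
               frozen$rmin_10, tolerance = 1e-12)
  expect_equal(respiration_specific(base_p, gas_conditions(3, 15, 10)),
               frozen$resp_specific_10, tolerance = 1e-12)
  # infinite inhibition constant collapses to plain Michaelis-Menten
  p_noinhib <- respiration_params(ki = 1e15)
  g <- gas_conditions(3, 15, 10)
  plain <- frozen$vmax_10 * 3 / (19.6 + 3) + frozen$rmin_10
  expect_equal(respiration_specific(p_noinhib, g), plain, tolerance = 1e-9)
})

test_that("respiration is monotone in temperature, O2 and CO2", {
  rate <- function(o2, co2, T) respiration_specific(base_p, gas_conditions(o2, co2, T))
  expect_true(all(diff(sapply(seq(0, 25, 1), function(T) rate(3, 15, T))) > 0))
  expect_true(all(diff(sapply(seq(0, 21, 0.5), function(o2) rate(o2, 15, 10))) > 0))
  expect_true(all(diff(sapply(seq(0, 30, 1), function(co2) rate(3, co2, 10))) < 0))
})

test_that("respiration saturates below Vmax + Rmin at zero CO2", {
  sat <- respiration_specific(base_p, gas_conditions(100, 0, 10))
  expect_lt(sat, frozen$vmax_10 + frozen$rmin_10)
  expect_gt(sat, 0.8 * frozen$vmax_10)  # close to saturation at 100% O2
})

test_that("whole-box respiration scales linearly with product weight", {
  g <- gas_conditions(3, 15, 10)
  expect_equal(respiration_box(base_p, g, 16), frozen$resp_box_10,
               tolerance = 1e-12)
  expect_equal(respiration_box(base_p, g, 32),
               2 * respiration_box(base_p, g, 16))
  expect_equal(respiration_box_s(base_p, g, 16) * 3600,
               respiration_box(base_p, g, 16))
  expect_error(respiration_box(base_p, g, 0), "positive")
  expect_error(respiration_box(base_p, g, -2), "positive")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(respiration_params(km = -1), "positive")
  expect_error(gas_conditions(-1, 15, 10), "\\[0, 100\\]")
  expect_error(gas_conditions(3, 15, 80), "degC")
  expect_error(diffusion_params(k_on = 1e-9, k_off = 2e-8), "k_on > k_off")
  expect_error(control_settings(o2_set = 25), "\\(0, 21\\)")
})

test_that("registry serialises losslessly to JSON and YAML", {
  reg <- broccoli_params()
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_registry(reg, path)
    back <- read_registry(path)
    expect_equal(back$name, reg$name)
    expect_equal(back$base, reg$base, tolerance = 1e-12)
    expect_equal(back$abs_error, reg$abs_error, tolerance = 1e-12)
  }
})
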