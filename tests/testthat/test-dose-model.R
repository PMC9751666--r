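# Closed-form expectations below are hand-derivable:
#   r0 = 29 / (1 + 2^(-21/163))          = 15.147 mGy/day per injection
#   D(inf) = 2 r0 (163/ln 2) / 1000      = 7.124 Gy

test_that("pinned-peak calibration splits the peak over decayed injections", {
  m <- dose_model()   # Ca-45, injections at 4 and 7 wk, peak 29 mGy/day
  r0 <- 29 / (1 + 2 ^ (-21 / 163))
  expect_equal(unname(coef(m)), rep(r0, 2), tolerance = 1e-12)
  # single injection: r0 is the peak itself
  m1 <- dose_model(schedule = list(injection_event(4)),
                   peak_dose_rate_mGy_per_day = 12)
  expect_equal(unname(coef(m1)), 12)
})

test_that("dose rate follows summed exponential decay from each injection", {
  m <- dose_model()
  expect_equal(dose_rate_at(m, 7), 29)              # just after 2nd injection
  expect_equal(dose_rate_at(m, 3.9), 0)             # before first injection
  expect_equal(dose_rate_at(m, 7 + 163 / 7), 14.5,  # one half-life later
               tolerance = 1e-3)
  # nonincreasing between injections
  ages <- seq(7.01, 80, by = 0.1)
  expect_true(all(diff(dose_rate_at(m, ages)) < 0))
})

test_that("cumulative dose matches the closed form and printed envelopes", {
  m <- dose_model()
  d <- cumulative_dose_at(m, c(34.3, 57.6, 80.9))
  expect_equal(d, c(4.098, 5.612, 6.368), tolerance = 1e-3)
  ref <- ca45_reference_dose_ranges()
  expect_true(all(d >= ref$lower_Gy & d <= ref$upper_Gy))
  expect_equal(cumulative_dose_at(m, 4), 0)
  # infinite-time limit: sum r0_i * tau
  r0 <- 29 / (1 + 2 ^ (-21 / 163))
  expect_equal(cumulative_dose_at(m, 1e5), 2 * r0 * 163 / log(2) / 1000,
               tolerance = 1e-9)
})

test_that("trapezoid integration agrees with the closed form to 0.1%", {
  m <- dose_model()
  for (age in c(20, 34.3, 57.6, 80.9)) {
    cf <- cumulative_dose_at(m, age)
    tr <- cumulative_dose_at(m, age, method = "trapezoid", step_days = 0.1)
    expect_lt(abs(tr - cf) / cf, 1e-3)
  }
})

test_that("cumulative dose is nondecreasing with derivative = dose rate", {
  m <- dose_model()
  ages <- seq(0, 81, by = 0.05)
  cum <- cumulative_dose_at(m, ages)
  expect_true(all(diff(cum) >= 0))
  # numerical derivative vs dose rate away from injection discontinuities
  mid <- seq(8, 80, by = 0.5)
  h <- 0.005
  deriv <- (cumulative_dose_at(m, mid + h) -
              cumulative_dose_at(m, mid - h)) / (2 * h) * 1000 / 7  # mGy/day
  expect_equal(deriv, dose_rate_at(m, mid), tolerance = 1e-3)
})

test_that("physical-mass calibration reproduces first-principles arithmetic", {
  # 740 kBq into ~20 g of irradiated tissue (3.7e7 Bq/kg), retention 0.879,
  # Delta 1.233e-14, phi 0.9 -> ~31 mGy/day
  m <- dose_model(calibration = "physical_mass", source_mass_kg = 0.020)
  expect_equal(sum(coef(m)[1]), 31.1, tolerance = 0.01)
  # exact scale invariance: doubling the source mass halves every rate
  m2 <- dose_model(calibration = "physical_mass", source_mass_kg = 0.040)
  expect_equal(coef(m2), coef(m) / 2)
  expect_equal(dose_rate_at(m2, 30), dose_rate_at(m, 30) / 2)
  # ddref is a plain divisor
  m3 <- dose_model(calibration = "physical_mass", source_mass_kg = 0.020,
                   ddref = 2)
  expect_equal(coef(m3), coef(m) / 2)
})

test_that("model configuration errors are caught", {
  expect_error(dose_model(schedule = list()), "schedule")
  expect_error(dose_model(calibration = "physical_mass"), "source_mass_kg")
  expect_error(dose_model(absorbed_fraction = 0), "absorbed_fraction")
  expect_error(dose_model(retention_fraction = 1.5), "retention_fraction")
  expect_error(dose_model(ddref = 0.5), "ddref")
  expect_error(dose_model(peak_dose_rate_mGy_per_day = -1), "peak")
})

test_that("YAML config round-trips into an equivalent model", {
  cfg <- list(
    nuclide = "Ca-45",
    schedule = list(list(age_weeks = 4), list(age_weeks = 7)),
    calibration = "pinned_peak_rate",
    peak_dose_rate_mGy_per_day = 29)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  m <- read_dose_config(path)
  expect_s3_class(m, "dose_model")
  expect_equal(coef(m), coef(dose_model()))
  expect_equal(cumulative_dose_at(m, 34.3),
               cumulative_dose_at(dose_model(), 34.3))
  # custom nuclide block
  cfg2 <- list(
    nuclide = list(name = "Sr-89", half_life_days = 50.5,
                   mean_beta_energy_MeV = 0.583,
                   max_beta_energy_MeV = 1.495),
    schedule = list(list(age_weeks = 4)))
  yaml::write_yaml(cfg2, path)
  m2 <- read_dose_config(path)
  expect_equal(m2$nuclide$half_life_days, 50.5)
  # missing schedule is a configuration error
  yaml::write_yaml(list(nuclide = "Ca-45"), path)
  expect_error(read_dose_config(path), "schedule")
})

test_that("predict and timecourse expose rate and cumulative dose", {
  m <- dose_model()
  expect_equal(predict(m, c(7, 34.3), type = "rate"),
               dose_rate_at(m, c(7, 34.3)))
  expect_equal(predict(m, 34.3, type = "cumulative"),
               cumulative_dose_at(m, 34.3))
  tc <- dose_timecourse(m, seq(0, 10, by = 0.5))
  expect_named(tc, c("age_weeks", "dose_rate_mGy_day", "cumulative_Gy"))
  expect_true(all(tc$dose_rate_mGy_day >= 0))
  expect_output(print(summary(m)), "Absorbed dose summary")
})
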