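test_that("presets and named locations resolve to the standard values", {
  expect_equal(implant_A$diffusivity, 2e-6)
  expect_equal(implant_B$diffusivity, 5e-6)
  expect_equal(implant_A$length, 0.013)
  expect_equal(location_y("B1", implant_A), 0.00975)
  expect_equal(location_y("B2", implant_A), 0.0065)
  expect_equal(location_y("B3", implant_A), 0.00325)
  expect_equal(location_y(0.004, implant_A), 0.004)
  expect_error(location_y("B4", implant_A), "B1")
})

test_that("figure datasets reproduce the documented qualitative behaviour", {
  f2 <- figure_dataset(2)
  expect_setequal(unique(f2$t0_s), c(0.2, 2))
  at0 <- subset(f2, t_s == 0)
  expect_equal(at0$temperature_C, rep(60, 2))
  # the short-exposure curve drops faster
  at1 <- subset(f2, t_s == f2$t_s[51])
  expect_lt(at1$temperature_C[at1$t0_s == 0.2], at1$temperature_C[at1$t0_s == 2])

  f3 <- figure_dataset(3)
  expect_setequal(unique(f3$t_s), c(9, 12, 15, 18))
  # at every fixed interior y the temperature decreases from t = 9 to 18 s
  for (y in unique(f3$y_m)[c(20, 50, 80)]) {
    Ty <- f3$temperature_C[f3$y_m == y][order(unique(f3$t_s))]
    expect_true(all(diff(Ty) < 0))
  }

  f5 <- figure_dataset(5)
  pkA <- exposure_sweep(implant_A, hot_load(2), 2, "B2")
  pkB <- exposure_sweep(implant_B, hot_load(2), 2, "B2")
  expect_gt(pkB$T_peak_C, pkA$T_peak_C)   # good conductor peaks higher
  expect_lt(pkB$t_peak_s, pkA$t_peak_s)   # ... and faster
  expect_equal(length(unique(f5$series)), 2)

  expect_equal(unique(figure_dataset(6)$t0_s), c(2, 5, 8, 11, 14))
  expect_equal(unique(figure_dataset(7)$t0_s), c(1, 2, 3, 5, 6))
  expect_error(figure_dataset(9), "fig_id")
})

test_that("exposure sweep peaks increase with t0 and hit ~41 degC at t0 = tau", {
  sw <- exposure_sweep(implant_A, hot_load(2), c(2, 5, 8, 11, 14), "B2")
  expect_equal(sw$t0_s, c(2, 5, 8, 11, 14))
  expect_true(all(diff(sw$T_peak_C) > 0))
  # at t0 = tau the B2 peak is about 41 degC for either material
  pkA <- exposure_sweep(implant_A, hot_load(2), intrinsic_time(implant_A), "B2")
  pkB <- exposure_sweep(implant_B, hot_load(2), intrinsic_time(implant_B), "B2")
  expect_equal(pkA$T_peak_C, 41, tolerance = 0.5 / 41)
  expect_equal(pkB$T_peak_C, 41, tolerance = 0.5 / 41)
  # cross-material coincidence: the peak is set by t0/tau alone
  expect_lt(abs(pkA$T_peak_C - pkB$T_peak_C), 0.3)
  expect_error(exposure_sweep(implant_A, hot_load(2), numeric(0)), "t0_values")
})

test_that("time above threshold measures the exceedance set", {
  ld <- hot_load(2)
  # B2 peak for implant A at t0 = 2 is far below the 47 degC necrosis threshold
  expect_equal(time_above_threshold(implant_A, ld, "B2", 47), 0)
  # the interior never exceeds the boundary maximum
  expect_equal(time_above_threshold(implant_A, ld, "B2", 60), 0)
  # the transient excess above body temperature lasts a positive time
  expect_gt(time_above_threshold(implant_A, ld, "B2", 37.5), 0)
  # consistency with the peak: threshold just below the peak is exceeded
  pk <- peak_temperature(implant_A, ld, location_y("B2", implant_A))
  expect_gt(time_above_threshold(implant_A, ld, "B2", pk$T_peak - 0.2), 0)
  expect_equal(time_above_threshold(implant_A, ld, "B2", pk$T_peak + 0.1), 0)
})

test_that("CEM43 dose follows the halving rule and its conventions", {
  # one hour at 44 degC counts as 120 equivalent minutes
  expect_equal(cem43_history(c(0, 3600), c(44, 44)), 120)
  # ten minutes at exactly 43 degC counts as ten minutes
  expect_equal(cem43_history(c(0, 600), c(43, 43)), 10)
  # 45 degC: time-to-effect halves again -> 4x rate
  expect_equal(cem43_history(c(0, 900), c(45, 45)), 60)
  # below the 39 degC cutoff the dose is zero
  expect_equal(cem43_history(c(0, 3600), c(38, 38)), 0)
  # between cutoff and breakpoint the sub-43 factor 0.25 applies
  expect_equal(cem43_history(c(0, 60), c(42, 42)), 0.25)
})

test_that("CEM43 is additive over time partitions and stable under resampling", {
  ts <- seq(0, 100, length.out = 501)
  temps <- 37 + 8 * exp(-(ts - 30)^2 / 200)   # smooth pulse peaking at 45 degC
  whole <- cem43_history(ts, temps)
  cut <- 251
  part <- cem43_history(ts[1:cut], temps[1:cut]) +
    cem43_history(ts[cut:501], temps[cut:501])
  expect_equal(part, whole)
  ts2 <- seq(0, 100, length.out = 1001)
  temps2 <- 37 + 8 * exp(-(ts2 - 30)^2 / 200)
  expect_equal(cem43_history(ts2, temps2), whole, tolerance = 0.01)
})

test_that("threshold report bundles peak, exceedance and dose coherently", {
  ld <- hot_load(8.6)
  rep <- threshold_report(implant_A, ld, "B2", threshold = 42)
  expect_s3_class(rep, "threshold_report")
  expect_gte(rep$T_peak, 37)
  expect_gte(rep$time_above, 0)
  expect_gte(rep$cem43_minutes, 0)
  # the 41 degC peak never reaches the 42 degC injury threshold
  expect_lt(rep$T_peak, 42)
  expect_equal(rep$time_above, 0)
})
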