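test_that("Fourier coefficients of the ramp match the quadrature oracle", {
  L <- 0.013
  expect_equal(fourier_coefficient(1, L), 2 * L / pi)
  expect_equal(fourier_coefficient(2, L), -L / pi)
  for (n in 1:10) {
    oracle <- (2 / L) * stats::integrate(
      function(y) y * sin(n * pi * y / L), 0, L,
      rel.tol = 1e-13, abs.tol = 1e-16)$value
    expect_equal(fourier_coefficient(n, L), oracle, tolerance = 1e-10)
  }
  expect_error(fourier_coefficient(0, L), "n")
})

test_that("particular component carries the boundary data linearly", {
  ld <- hot_load(2)
  L <- implant_A$length
  expect_equal(particular_component(implant_A, ld, 5, 0), 37)
  expect_equal(particular_component(implant_A, ld, 0, L), 60)
  expect_equal(particular_component(implant_A, ld, 2, L / 2), 37 + 11.5 * exp(-1))
  # linear in y at fixed t
  ys <- seq(0, L, length.out = 7)
  w <- particular_component(implant_A, ld, rep(3, 7), ys)
  expect_equal(diff(w, differences = 2), rep(0, 5), tolerance = 1e-12)
  expect_equal(particular_component(implant_A, ld, 3, L), load_temperature(ld, 3))
  expect_error(particular_component(implant_A, ld, 1, L * 1.01), "within")
})

test_that("mode amplitudes start at -(-1)^(n+1)/n and decay to zero", {
  ld <- hot_load(2)
  for (n in 1:6)
    expect_equal(mode_amplitude(n, 0, ld, implant_A), -(-1)^(n + 1) / n)
  expect_equal(mode_amplitude(1:4, rep(500, 4), ld, implant_A), rep(0, 4),
               tolerance = 1e-12)
})

test_that("resonance branch is the continuous limit of the general branch", {
  tau <- intrinsic_time(implant_A)
  for (n in 1:3) {
    t0_res <- tau / n^2
    ld_res <- thermal_load(exposure_time = t0_res)
    ts <- seq(0, 10 * t0_res, length.out = 41)
    d_res <- mode_amplitude(rep(n, 41), ts, ld_res, implant_A)
    for (eps in c(-1e-6, 1e-6)) {
      ld_near <- thermal_load(exposure_time = t0_res * (1 + eps))
      d_near <- mode_amplitude(rep(n, 41), ts, ld_near, implant_A)
      expect_lt(max(abs(d_near - d_res)), 1e-4)
    }
  }
  # resonance limit formula vanishes at t = t0
  ld <- thermal_load(exposure_time = intrinsic_time(implant_A))
  expect_equal(mode_amplitude(1, ld$exposure_time, ld, implant_A), 0,
               tolerance = 1e-9)
})

test_that("temperature field matches both boundaries exactly", {
  ld <- hot_load(2)
  L <- implant_A$length
  set.seed(11)
  ts <- sort(runif(25, 0, 40))
  expect_equal(implant_temperature(implant_A, ld, ts, rep(0, 25)), rep(37, 25))
  expect_equal(implant_temperature(implant_A, ld, ts, rep(L, 25)),
               load_temperature(ld, ts), tolerance = 1e-12)
})

test_that("initial condition is recovered away from the load corner", {
  ld <- hot_load(2)
  cfg <- series_config(n_terms = 2000)
  ys <- seq(0, 0.9 * implant_A$length, length.out = 40)
  T0 <- implant_temperature(implant_A, ld, rep(0, 40), ys, cfg)
  expect_lt(max(abs(T0 - 37)), 0.05 * 23)
})

test_that("field relaxes to body temperature at long times", {
  for (t0 in c(0.2, 2, 8.6)) {
    ld <- hot_load(t0)
    tl <- 10 * max(t0, intrinsic_time(implant_A))
    ys <- seq(0, implant_A$length, length.out = 21)
    Tl <- implant_temperature(implant_A, ld, rep(tl, 21), ys)
    expect_lt(max(abs(Tl - 37)), 0.01)
  }
})

test_that("solution depends on geometry/material only through tau", {
  ld <- hot_load(2)
  m1 <- implant_model(0.013, 2e-6)
  m2 <- implant_model(0.026, 8e-6)   # same tau, doubled length
  expect_equal(intrinsic_time(m1), intrinsic_time(m2))
  fr <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  ts <- c(0.5, 2, 5, 10, 20)
  for (t in ts) {
    T1 <- implant_temperature(m1, ld, rep(t, 5), fr * m1$length)
    T2 <- implant_temperature(m2, ld, rep(t, 5), fr * m2$length)
    expect_lt(max(abs(T1 - T2)), 1e-9)
  }
})

test_that("maximum principle holds away from the start-up corner", {
  ld <- hot_load(2)
  set.seed(7)
  ts <- runif(300, 0.05, 30)
  ys <- runif(300, 0, implant_A$length)
  Tv <- implant_temperature(implant_A, ld, ts, ys)
  expect_true(all(Tv >= 37 - 1e-6 & Tv <= 60 + 1e-6))
})

test_that("temperature excess is linear in the load amplitude", {
  L <- implant_A$length
  ld1 <- thermal_load(60, 37, 2)    # dT = 23
  ld2 <- thermal_load(83, 37, 2)    # dT = 46
  ld3 <- thermal_load(14, 37, 2)    # dT = -23 (cold load)
  ts <- c(0.5, 2, 8); ys <- c(L / 4, L / 2, 3 * L / 4)
  e1 <- implant_temperature(implant_A, ld1, ts, ys) - 37
  e2 <- implant_temperature(implant_A, ld2, ts, ys) - 37
  e3 <- implant_temperature(implant_A, ld3, ts, ys) - 37
  expect_equal(e2, 2 * e1, tolerance = 1e-10)
  expect_equal(e3, -e1, tolerance = 1e-10)
})

test_that("evaluate_field agrees with pointwise calls and handles edge cases", {
  ld <- hot_load(2)
  L <- implant_A$length
  grid <- evaluation_grid(c(0.5, 5, 15), c(0, L / 4, L / 2, 3 * L / 4, L))
  fld <- evaluate_field(implant_A, ld, grid)
  expect_identical(dim(fld$values), c(3L, 5L))
  expect_identical(fld$method, "analytic")
  for (i in 1:3) for (j in 1:5)
    expect_equal(fld$values[i, j],
                 implant_temperature(implant_A, ld, grid$times[i], grid$positions[j]))
  # boundary column reproduces the load curve
  expect_equal(fld$values[, 5], load_temperature(ld, grid$times), tolerance = 1e-12)
  # degenerate constant load gives the uniform field
  ldc <- thermal_load(40, 40, 2)
  fldc <- evaluate_field(implant_A, ldc, grid)
  expect_equal(as.vector(fldc$values), rep(40, 15))
  # single-cell grid at t = 0 recovers the initial condition to series accuracy
  one <- evaluate_field(implant_A, ld, evaluation_grid(0, L / 2))
  expect_equal(one$values[1, 1], 37, tolerance = 0.1)
  expect_error(evaluate_field(implant_A, ld, evaluation_grid(1, 2 * L)), "within")
})
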