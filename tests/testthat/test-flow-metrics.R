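test_that("Reynolds number follows rho U D / mu with unit safety", {
  expect_equal(reynolds(10.14, 2.82), 28.5948, tolerance = 1e-6)
  expect_equal(reynolds(20.57, 2.82), 58.0074, tolerance = 1e-6)
  expect_equal(reynolds(0, 2.82), 0)
  # SI route: same number from m-based inputs with explicit conversion
  props <- fluid_props()
  re_si <- props$density * (10.14e-3) * (2.82e-3) / props$viscosity
  expect_equal(reynolds(10.14, 2.82, props), re_si)
  expect_error(reynolds(-1, 2), ">= 0")
  expect_error(reynolds(1, 0), "> 0")
})

test_that("representative velocity is the peak area-normalized flow rate", {
  wf <- generate_waveform(15.3, 1, 8)
  a <- pi * (2.82 / 2)^2
  expect_equal(representative_velocity(wf, a), 15.3 * pi / a,
               tolerance = 1e-12)
  expect_equal(representative_velocity(generate_waveform(0, 1, 8), a), 0)
  expect_equal(representative_velocity(wf, 2 * a),
               representative_velocity(wf, a) / 2)
  expect_error(representative_velocity(wf, 0), "> 0")
})

test_that("equivalent diameter inverts the circle area", {
  expect_equal(equivalent_diameter(6.246), 2.82, tolerance = 1e-3)
  expect_equal(equivalent_diameter(c(pi, pi)), 2)
  areas <- c(5.1, 6.3, 7.2, 5.9)
  expect_equal(equivalent_diameter(areas),
               equivalent_diameter(rev(areas)))
  expect_error(equivalent_diameter(numeric(0)))
  expect_error(equivalent_diameter(c(1, -2)))
})

test_that("consistency error implements the across-section deviation rule", {
  q <- sin(2 * pi * (0:7) / 8)
  same <- cbind(q, q, q, q)
  r <- consistency_error(same)
  expect_equal(r$error, 0)
  expect_false(r$excluded)
  # one section scaled by 1.4 at the peak phase: deviation 0.3*Qpk against
  # a mean peaking at 1.1*Qpk
  pert <- same
  pk <- which.max(q)
  pert[pk, 4] <- 1.4 * q[pk]
  r2 <- consistency_error(pert)
  expect_equal(r2$error, 0.3 / 1.1, tolerance = 1e-12)
  expect_true(r2$excluded)
  # degenerate all-zero series
  r3 <- consistency_error(matrix(0, 8, 4))
  expect_equal(r3$error, 0)
  expect_false(r3$excluded)
  expect_error(consistency_error(matrix(q, ncol = 1)), "2 sections")
})

test_that("exclusion threshold is a strict inequality", {
  # two constant sections 1.25 and 0.75: mean 1, deviation 0.25 exactly
  r <- consistency_error(cbind(rep(1.25, 8), rep(0.75, 8)))
  expect_equal(r$error, 0.25, tolerance = 1e-12)
  expect_false(r$excluded)
  r2 <- consistency_error(cbind(rep(1.26, 8), rep(0.74, 8)))
  expect_true(r2$excluded)
})

test_that("flow_metrics assembles a consistent record", {
  wf <- generate_waveform(15.3, 1, 64)
  a <- pi * (2.82 / 2)^2
  fm <- flow_metrics(wf, area = a)
  expect_equal(fm$d_mm, 2.82, tolerance = 1e-12)
  expect_equal(fm$re, reynolds(fm$u_mm_s, fm$d_mm), tolerance = 1e-12)
  expect_false(fm$excluded)
})
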