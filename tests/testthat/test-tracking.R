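test_that("lattice seeding keeps strictly interior points of a unit cube", {
  mesh <- box_mesh(1, 1, 1, 0.25)
  pp <- seed_particles(mesh, 0.25)
  # closed lattice has 5^3 = 125 points; the 98 on the boundary are dropped
  expect_equal(nrow(pp$pos), 27L)
  expect_true(all(pp$pos > 0 & pp$pos < 1))
  expect_identical(pp$pos, pp$origin)
})

test_that("huge spacing yields an empty (or singleton) set with a warning", {
  mesh <- box_mesh(1, 1, 1, 0.25)
  expect_warning(pp <- seed_particles(mesh, 50), "spacing")
  expect_lte(nrow(pp$pos), 1L)
})

test_that("particles do not move in a zero field", {
  mesh <- ventricle_fixture()
  fld <- synthetic_field(mesh, function(x, y, z) cbind(0 * x, 0 * x, 0 * x))
  pp <- seed_particles(mesh, 1.2)
  adv <- advect_particles(pp, fld, tracking_config(n_cycles = 5L))
  expect_identical(adv$pos, pp$pos)
  expect_true(all(adv$status == 0L))
})

test_that("constant fields are integrated exactly by the Runge-Kutta schemes", {
  mesh <- box_mesh(4, 1, 1, 0.25)
  u0 <- c(0.21, 0.05, -0.03)
  fld <- synthetic_field(mesh, function(x, y, z) {
    cbind(u0[1] + 0 * x, u0[2] + 0 * x, u0[3] + 0 * x)
  }, period = 2)
  pp <- manual_particles(rbind(c(0.5, 0.5, 0.5)), rbind(c(0.5, 0.5, 0.5)))
  for (scheme in c("rk4", "rk2")) {
    adv <- advect_particles(pp, fld, tracking_config(n_cycles = 1L,
                                                     integrator = scheme,
                                                     substeps = 1L))
    expect_equal(as.vector(adv$pos), c(0.5, 0.5, 0.5) + 2 * u0,
                 tolerance = 1e-12)
  }
})

test_that("solid-body rotation returns tracers to their start", {
  mesh <- tube_fixture(0.35, 2, 8)
  om <- 2 * pi           # one revolution per period (period = 1)
  fld <- synthetic_field(mesh, function(x, y, z) {
    cbind(-om * y, om * x, 0 * x)
  }, period = 1, phases = 8L)
  r0 <- 0.6
  pp <- manual_particles(rbind(c(r0, 0, 4)), rbind(c(r0, 0, 4)))
  adv <- advect_particles(pp, fld, tracking_config(n_cycles = 1L,
                                                   substeps = 16L))
  expect_lt(sqrt(sum((adv$pos - pp$pos)^2)), 1e-3 * r0)
})

test_that("advection forward then backward through a frozen field reverses", {
  mesh <- tube_fixture(0.35, 2, 8)
  fld <- synthetic_field(mesh, function(x, y, z) {
    cbind(0.1 * z - 0.2 * y, 0.15 * x, 0.3 * (1 - (x^2 + y^2) / 4))
  }, period = 1, phases = 4L)
  fldb <- fld
  fldb$u <- -fld$u
  pts <- rbind(c(0.3, 0.2, 3), c(-0.5, 0.1, 5))
  pp <- manual_particles(pts, pts)
  fw <- advect_particles(pp, fld, tracking_config(n_cycles = 2L, substeps = 8L))
  bw <- advect_particles(fw, fldb, tracking_config(n_cycles = 2L, substeps = 8L))
  expect_equal(bw$pos, pts, tolerance = 1e-6)
})

test_that("particles crossing an outlet freeze and never re-enter", {
  mesh <- box_mesh(4, 1, 1, 0.25, labeled = TRUE)  # outlet at x = 4
  fld <- synthetic_field(mesh, function(x, y, z) {
    cbind(1 + 0 * x, 0 * x, 0 * x)
  }, period = 1, phases = 4L)
  pts <- rbind(c(3.4, 0.5, 0.5), c(0.6, 0.5, 0.5))
  pp <- manual_particles(pts, pts)
  adv <- advect_particles(pp, fld, tracking_config(n_cycles = 1L, substeps = 4L))
  expect_equal(adv$status, c(1L, 0L))
  frozen <- adv$pos[1L, ]
  adv2 <- advect_particles(adv, fld, tracking_config(n_cycles = 3L, substeps = 4L))
  expect_identical(adv2$pos[1L, ], frozen)
  expect_equal(adv2$status[1L], 1L)
  # origins never change
  expect_identical(adv2$origin, pts)
})

test_that("divergence-free transport preserves local particle density", {
  mesh <- tube_fixture(0.35, 2, 8)
  om <- 2 * pi
  fld <- synthetic_field(mesh, function(x, y, z) {
    cbind(-om * y, om * x, 0 * x)
  }, period = 1, phases = 8L)
  pp <- seed_particles(mesh, 0.3)
  inside_ball <- function(pos) {
    sum(sqrt((pos[, 1L])^2 + (pos[, 2L])^2 + (pos[, 3L] - 4)^2) < 0.7)
  }
  n0 <- inside_ball(pp$pos)
  adv <- advect_particles(pp, fld, tracking_config(n_cycles = 3L, substeps = 8L))
  expect_lt(abs(inside_ball(adv$pos) - n0) / n0, 0.05)
})
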