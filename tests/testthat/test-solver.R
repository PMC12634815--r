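test_that("wall program satisfies the discrete flux constraint exactly", {
  mesh <- ventricle_fixture()
  wf <- generate_waveform(15.3, 1, 8)
  wp <- build_wall_program(mesh, wf)
  mov <- mesh$tris[mesh$labels == "moving_wall", , drop = FALSE]
  for (t in c(0.1, 0.27, 0.62)) {
    w <- wp$alpha_fun(t) * wp$W
    flux <- csfmix:::facet_flux(mesh, mov, w)
    q <- waveform_fun(wf)(t)
    expect_lt(abs(flux + q), 1e-10 * max(abs(wf$q)))
  }
})

test_that("a zero waveform yields a zero wall program and zero flow", {
  mesh <- tube_fixture(0.5, 2, 4)
  wf <- generate_waveform(0, 1, 8)
  wp <- build_wall_program(mesh, wf)
  expect_equal(wp$alpha_fun(0.3), 0)
  fld <- solve_cycle(mesh, wf, cfg = solver_config(cycles = 1L,
                                                   store_phases = 4L,
                                                   min_steps = 20L))
  expect_equal(max(abs(fld$u)), 0)
  expect_equal(max(abs(fld$log$mass_residual)), 0)
})

test_that("wall displacement integrates to zero over one period", {
  wf <- generate_waveform(15.3, 1, 8)
  mesh <- ventricle_fixture()
  wp <- build_wall_program(mesh, wf)
  tt <- seq(0, 1, length.out = 4001)
  a <- wp$alpha_fun(tt)
  disp <- sum((head(a, -1) + tail(a, -1)) / 2 * diff(tt))
  expect_lt(abs(disp), 1e-6 * max(abs(a)))
})

test_that("meshes without a moving wall are rejected", {
  mesh <- box_mesh(1, 1, 1, 0.5)   # all rigid
  expect_error(build_wall_program(mesh, generate_waveform(1, 1, 8)),
               "moving-wall")
})

test_that("harmonic mesh motion reproduces rigid translation exactly", {
  mesh <- tube_fixture(0.5, 2, 4)
  bnodes <- unique(as.vector(mesh$tris))
  disp <- matrix(0, nrow(mesh$nodes), 3L)
  disp[bnodes, ] <- matrix(c(0.01, -0.02, 0.015), length(bnodes), 3L,
                           byrow = TRUE)
  res <- ale_mesh_motion(mesh, disp)
  expect_equal(res$disp,
               matrix(c(0.01, -0.02, 0.015), nrow(mesh$nodes), 3L,
                      byrow = TRUE),
               tolerance = 1e-8)
  expect_gt(res$min_volume, 0)
  # zero boundary displacement stays zero
  res0 <- ale_mesh_motion(mesh, disp * 0)
  expect_equal(max(abs(res0$disp)), 0)
})

test_that("mesh motion failure reports inverted elements", {
  mesh <- tube_fixture(0.5, 2, 4)
  bnodes <- unique(as.vector(mesh$tris))
  disp <- matrix(0, nrow(mesh$nodes), 3L)
  # crush one cap inward past the first interior layer
  cap <- bnodes[mesh$nodes[bnodes, 3L] < 1e-9]
  disp[cap, 3L] <- 2.5
  expect_error(ale_mesh_motion(mesh, disp), "inverted")
})

test_that("pulsatile ventricle run is periodic with bounded energy", {
  mesh <- ventricle_fixture()
  wf <- generate_waveform(15.3, 0.85, 8)
  fld <- solve_cycle(mesh, wf, cfg = solver_config(cycles = 2L, cfl = 0.5,
                                                   store_phases = 16L))
  expect_lt(fld$periodicity, 0.02)
  lg <- fld$log
  # kinetic energy stays bounded (no blow-up): final-cycle max below twice
  # the first-cycle max
  expect_lt(max(lg$ke[lg$cycle == 2]), 2 * max(lg$ke[lg$cycle == 1]))
  # the simulated aqueduct flow reproduces the driving waveform
  cs <- cross_section_flow(fld, mean(mesh$aqueduct_z))
  expect_equal(max(abs(cs$q)), max(abs(wf$q)), tolerance = 0.03)
})

test_that("solver rejects waveforms with net volume unless told otherwise", {
  mesh <- tube_fixture(0.5, 2, 4)
  wf <- flow_waveform(c(0, 0.25, 0.5, 0.75), rep(2, 4), 1, net_tol = Inf)
  expect_error(solve_cycle(mesh, wf), "net volume")
})

test_that("cross-section flow handles analytic fields exactly", {
  mesh <- tube_fixture(0.35, 2, 8)
  # uniform axial velocity: Q = u * pi r^2 at every phase
  fld <- synthetic_field(mesh, function(x, y, z) cbind(0 * x, 0 * x, 3 + 0 * x))
  cs <- cross_section_flow(fld, 4)
  expect_equal(cs$q, rep(3 * pi, 4L), tolerance = 0.02)
  # Poiseuille profile with centerline u0: Q = u0 * pi r^2 / 2
  fld2 <- synthetic_field(mesh, function(x, y, z) {
    cbind(0 * x, 0 * x, 10 * pmax(0, 1 - (x^2 + y^2)))
  })
  cs2 <- cross_section_flow(fld2, 4)
  expect_equal(cs2$q[1L], 10 * pi / 2, tolerance = 0.02 * 10 * pi / 2)
  # zero field
  fld0 <- synthetic_field(mesh, function(x, y, z) cbind(0 * x, 0 * x, 0 * x))
  expect_equal(max(abs(cross_section_flow(fld0, 4)$q)), 0)
  expect_error(cross_section_flow(fld0, 99), "plane")
})

test_that("sampling a nodal field at nodes returns the stored values", {
  mesh <- tube_fixture(0.5, 2, 4)
  fld <- synthetic_field(mesh, function(x, y, z) cbind(x, 2 * y, z - 1))
  idx <- c(5L, 40L, 100L)
  v <- sample_velocity(fld, mesh$nodes[idx, ], t = 0)
  expect_equal(v, cbind(mesh$nodes[idx, 1L], 2 * mesh$nodes[idx, 2L],
                        mesh$nodes[idx, 3L] - 1), tolerance = 1e-9)
  # linear fields are reproduced exactly anywhere inside (P1 exactness)
  pts <- cbind(c(0.1, -0.3), c(0.2, 0.1), c(1.7, 2.9))
  v2 <- sample_velocity(fld, pts, t = 0.4)
  expect_equal(v2, cbind(pts[, 1L], 2 * pts[, 2L], pts[, 3L] - 1),
               tolerance = 1e-9)
})
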