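test_that("the evaluation grid tiles the box exactly", {
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(grid$scales, c(2L, 4L, 6L, 8L, 10L))
  # scale 2: 8 subdomains of volume 1/8 each
  w <- (grid$hi - grid$lo) / 2
  expect_equal(prod(w), 1 / 8)
  # the 1000 subdomain centers at scale 10 hit every index exactly once
  ctr <- (as.matrix(expand.grid(0:9, 0:9, 0:9)) + 0.5) / 10
  idx <- csfmix:::cell_index(grid, ctr, 10L)
  expect_identical(sort(idx), 1:1000)
  set.seed(1)
  pts <- matrix(runif(3000), ncol = 3L)
  expect_true(all(csfmix:::cell_index(grid, pts, 10L) %in% 1:1000))
  expect_error(build_mix_grid(rbind(c(0, 0, 0), c(1, 0, 1))), "zero-volume")
})

test_that("interior face points land in exactly one subdomain", {
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  # x = 0.5 is the internal boundary at scale 2: half-open -> upper cell
  idx <- csfmix:::cell_index(grid, rbind(c(0.5, 0.25, 0.25)), 2L)
  expect_equal(idx, 2L)
  # top face is closed: x = 1 still belongs to the last cell
  idx2 <- csfmix:::cell_index(grid, rbind(c(1, 0.25, 0.25)), 2L)
  expect_equal(idx2, 2L)
  # outside points get NA
  expect_true(is.na(csfmix:::cell_index(grid, rbind(c(1.01, 0.5, 0.5)), 2L)))
})

test_that("exchange ratio counts final occupants by origin membership", {
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)), scales = 2L)
  # subdomain 1 is [0,0.5)^3; final occupants: 3 from inside, 2 from outside
  origin <- rbind(c(0.1, 0.1, 0.1), c(0.2, 0.3, 0.1), c(0.4, 0.4, 0.4),
                  c(0.9, 0.9, 0.9), c(0.7, 0.2, 0.2))
  final <- rbind(c(0.15, 0.1, 0.1), c(0.25, 0.3, 0.1), c(0.3, 0.2, 0.4),
                 c(0.1, 0.4, 0.3), c(0.2, 0.2, 0.2))
  pp <- manual_particles(origin, final)
  r <- exchange_ratio(pp, grid, 2L, 1L)
  expect_equal(r$n_in, 3L)
  expect_equal(r$n_out, 2L)
  expect_equal(r$c, 0.4)
  # no motion: every occupant originated inside
  pp0 <- manual_particles(origin, origin)
  expect_equal(exchange_ratio(pp0, grid, 2L, 1L)$c, 0)
  # all occupants from outside
  ppa <- manual_particles(rbind(c(0.9, 0.9, 0.9), c(0.8, 0.6, 0.9)),
                          rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2)))
  expect_equal(exchange_ratio(ppa, grid, 2L, 1L)$c, 1)
})

test_that("scale norms are true RMS values with the printed variant kept", {
  expect_equal(scale_norm(rep(0, 8)), 0)
  expect_equal(scale_norm(rep(0.5, 8)), 0.5)
  expect_equal(scale_norm(c(1, rep(0, 7))), sqrt(1 / 8), tolerance = 1e-12)
  expect_equal(scale_norm(rep(1, 27)), 1)
  expect_equal(scale_norm(c(1, rep(0, 7)), normalization = "printed"), 1)
  expect_error(scale_norm(rep(0.5, 7)), "i\\^3")
})

test_that("the aggregate mix-norm is the RMS over scales", {
  expect_equal(mix_norm_aggregate(rep(0, 5)), 0)
  expect_equal(mix_norm_aggregate(rep(1, 5)), 1)
  expect_equal(mix_norm_aggregate(rep(0.3, 5)), 0.3, tolerance = 1e-12)
  expect_error(mix_norm_aggregate(rep(0.3, 4)), "expected 5")
})

test_that("zero displacement gives mix-norm 0 exactly", {
  set.seed(11)
  pos <- cbind(runif(500), runif(500), runif(500))
  pp <- manual_particles(pos, pos)
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  mr <- mix_norm(pp, grid)
  expect_identical(mr$m, 0)
  expect_true(all(mr$m_scales == 0))
})

test_that("a uniform reshuffle over a much larger domain saturates the norm", {
  set.seed(42)
  n <- 1e5
  big <- 2  # mixing box is the unit cube inside a 2 x 2 x 2 domain, so the
            # finest subdomains still hold ~12 particles and empties (c = 0
            # by convention) stay rare
  origin <- cbind(runif(n, 0, big), runif(n, 0, big), runif(n, 0, big))
  final <- cbind(runif(n, 0, big), runif(n, 0, big), runif(n, 0, big))
  pp <- manual_particles(origin, final)
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  mr <- mix_norm(pp, grid)
  expect_gt(mr$m, 0.95)
  expect_true(all(abs(mr$m_scales - 1) < 0.05))
})

test_that("mix-norm stays within [0, 1] for arbitrary particle data", {
  set.seed(3)
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  for (rep in 1:20) {
    n <- sample(10:300, 1)
    origin <- cbind(runif(n, -1, 2), runif(n, -1, 2), runif(n, -1, 2))
    final <- origin + matrix(rnorm(3 * n, 0, 0.4), n)
    st <- as.integer(runif(n) < 0.1)
    mr <- mix_norm(manual_particles(origin, final, st), grid)
    expect_gte(mr$m, 0)
    expect_lte(mr$m, 1)
    expect_true(all(mr$m_scales >= 0 & mr$m_scales <= 1))
  }
})

test_that("optimized and brute-force mix-norms agree", {
  set.seed(7)
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)))
  for (rep in 1:5) {
    n <- 120
    origin <- cbind(runif(n, -0.2, 1.2), runif(n, -0.2, 1.2),
                    runif(n, -0.2, 1.2))
    final <- origin[sample(n), ]
    st <- as.integer(runif(n) < 0.15)
    pp <- manual_particles(origin, final, st)
    a <- mix_norm(pp, grid)
    b <- mix_norm_brute(pp, grid)
    expect_equal(a$m, b$m, tolerance = 1e-13)
    expect_equal(unname(a$m_scales), unname(b$m_scales), tolerance = 1e-13)
  }
  # all particles exited: every subdomain empty, m = 0 on both paths
  ppx <- manual_particles(cbind(0.5, 0.5, 0.5), cbind(0.5, 0.5, 0.5), 1L)
  expect_identical(mix_norm(ppx, grid)$m, 0)
  expect_identical(mix_norm_brute(ppx, grid)$m, 0)
})

test_that("empty-subdomain and printed-normalization options are honoured", {
  grid <- build_mix_grid(rbind(c(0, 0, 0), c(1, 1, 1)), scales = 2L)
  # one occupied subdomain with c = 1
  pp <- manual_particles(cbind(0.9, 0.9, 0.9), cbind(0.1, 0.1, 0.1))
  expect_equal(mix_norm(pp, grid, empty = "zero")$m_scales[[1]],
               sqrt(1 / 8), tolerance = 1e-12)
  expect_equal(mix_norm(pp, grid, empty = "drop")$m_scales[[1]], 1)
  expect_equal(mix_norm(pp, grid, normalization = "printed")$m_scales[[1]], 1)
})
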