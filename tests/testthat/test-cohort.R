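test_that("healthy defaults reproduce the cohort structure", {
  coh <- generate_cohort(cohort_params(), seed = 7)
  expect_equal(nrow(coh), 47L)
  expect_equal(sum(coh$sex == "male"), 19L)
  expect_equal(sum(coh$sex == "female"), 28L)
  expect_true(all(coh$d_mm > 0 & coh$u_mm_s > 0 & coh$sv_ul >= 0 &
                  coh$period_s > 0))
  # internal consistency: waveform peak matches U*A, SV matches waveform
  for (i in c(1L, 20L, 47L)) {
    wf <- coh$waveform[[i]]
    expect_equal(max(abs(wf$q)) / coh$a_mm2[i], coh$u_mm_s[i],
                 tolerance = 1e-9)
    expect_equal(coh$re[i], reynolds(coh$u_mm_s[i], coh$d_mm[i]),
                 tolerance = 1e-12)
  }
})

test_that("cohort generation is bit-identical under a fixed seed", {
  a <- generate_cohort(cohort_params(), seed = 42)
  b <- generate_cohort(cohort_params(), seed = 42)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_params(), seed = 43)
  expect_false(identical(a$d_mm, c2$d_mm))
})

test_that("zero-SD parameters collapse every subject onto the means", {
  p <- cohort_params(n_subjects = 6L, n_male = 3L, n_female = 3L,
                     age_sd = 0, weight_sd = 0, lv_sd = 0, v3_sd = 0,
                     v4_sd = 0, d_sd = 0, u_noise_sd = 0, period_sd = 0)
  coh <- generate_cohort(p, seed = 1)
  expect_true(all(coh$d_mm == 2.82))
  expect_true(all(coh$age == 52))
  expect_equal(coh$u_mm_s, rep(26.4 / 2.82, 6L), tolerance = 1e-12)
})

test_that("generated marginals recover their targets at large n", {
  p <- cohort_params(n_subjects = 10000L, n_male = 5000L, n_female = 5000L)
  coh <- generate_cohort(p, seed = 1)
  se <- 0.56 / sqrt(10000)
  expect_lt(abs(mean(coh$d_mm) - 2.82), 3 * se)
  expect_lt(abs(sd(coh$d_mm) - 0.56), 0.02)
  # inverse relation: U correlates positively with 1/D
  expect_gt(cor(coh$u_mm_s, 1 / coh$d_mm), 0.2)
  # and the Reynolds spread matches the design derivation
  expect_lt(abs(sd(coh$re) - 13.3), 1.5)
})

test_that("iNPH group matches its Reynolds marginal without inverse relation", {
  coh <- generate_cohort(inph_params(n_subjects = 4000L, n_male = 2000L,
                                     n_female = 2000L), seed = 3)
  expect_lt(abs(mean(coh$re) - 58.0) / 58.0, 0.06)   # truncation shifts slightly
  # no inverse-law coupling beyond the 1/D factor: regression of U on 1/D
  # recovers a coefficient near E[Re], far above the healthy 26.4
  ft <- fit_inverse(coh$d_mm, coh$u_mm_s)
  expect_gt(ft$a, 45)
})

test_that("parameter validation catches impossible settings", {
  expect_error(cohort_params(n_subjects = 0L, n_male = 0L, n_female = 0L),
               "positive")
  expect_error(cohort_params(n_male = 10L, n_female = 10L), "equal")
  expect_error(cohort_params(age_sd = -1), "SD")
  expect_error(cohort_params(n_phases = 3L), "n_phases")
  expect_error(cohort_params(d_mean = -10, d_sd = 1), "truncation")
})

test_that("cohort CSV round-trip preserves subjects and waveforms", {
  dir <- tempfile("cohdir")
  coh <- generate_cohort(cohort_params(n_subjects = 5L, n_male = 2L,
                                       n_female = 3L), seed = 9)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$d_mm, coh$d_mm, tolerance = 1e-9)
  expect_equal(back$waveform[[3L]]$q, coh$waveform[[3L]]$q, tolerance = 1e-9)
  expect_equal(back$waveform[[3L]]$period, coh$waveform[[3L]]$period,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
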