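#' Synthetic cohort parameters
#'
#' Parameter set for generating a synthetic subject cohort whose marginal
#' statistics emulate a published healthy (or iNPH contrast) population:
#' demographics, ventricle volumetrics, aqueduct diameter, and the
#' velocity-diameter coupling that makes the aqueductal Reynolds number a
#' similarity parameter in health.
#'
#' All `*_mean` / `*_sd` pairs parameterize independent Gaussians truncated
#' at 0 (physical lower bound). The healthy representative velocity is tied
#' to the diameter through the inverse relation `U = a/D + eps`,
#' `eps ~ N(0, u_noise_sd)`; the iNPH group instead draws the Reynolds number
#' directly (`Re ~ N(re_mean, re_sd)`, `U = Re/D`), so no inverse relation
#' holds there.
#'
#' @param group `"healthy"` or `"inph"`.
#' @param n_subjects number of subjects.
#' @param n_male,n_female sex split; must sum to `n_subjects`.
#' @param age_mean,age_sd years.
#' @param weight_mean,weight_sd kg.
#' @param lv_mean,lv_sd lateral-ventricle volume, ml.
#' @param v3_mean,v3_sd third-ventricle volume, ml.
#' @param v4_mean,v4_sd fourth-ventricle volume, ml.
#' @param d_mean,d_sd aqueduct diameter, mm.
#' @param a inverse-relation coefficient, mm^2/s (healthy only).
#' @param u_noise_sd SD of the velocity noise around `a/D`, mm/s (healthy
#'   only). The default reproduces the healthy Reynolds-number spread of
#'   about 13 via `sd(Re) ~ u_noise_sd * sqrt(E[D^2])`.
#' @param re_mean,re_sd Reynolds-number marginal (iNPH only).
#' @param period_mean,period_sd cardiac period, s.
#' @param aqueduct_length aqueduct length, mm (not reported by MRI
#'   volumetrics; anatomically plausible default).
#' @param n_phases waveform phases per cardiac cycle (>= 4).
#' @param waveform_shape passed to [generate_waveform()].
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(group = c("healthy", "inph"),
                          n_subjects = 47L, n_male = 19L, n_female = 28L,
                          age_mean = 52, age_sd = 18,
                          weight_mean = 60, weight_sd = 11,
                          lv_mean = 23.3, lv_sd = 11.8,
                          v3_mean = 1.1, v3_sd = 0.5,
                          v4_mean = 1.6, v4_sd = 0.3,
                          d_mean = 2.82, d_sd = 0.56,
                          a = 26.4, u_noise_sd = 4.6,
                          re_mean = 58.0, re_sd = 27.6,
                          period_mean = 0.85, period_sd = 0.12,
                          aqueduct_length = 12,
                          n_phases = 8L,
                          waveform_shape = "sinusoid") {
  group <- match.arg(group)
  p <- list(group = group, n_subjects = as.integer(n_subjects),
            n_male = as.integer(n_male), n_female = as.integer(n_female),
            age_mean = age_mean, age_sd = age_sd,
            weight_mean = weight_mean, weight_sd = weight_sd,
            lv_mean = lv_mean, lv_sd = lv_sd,
            v3_mean = v3_mean, v3_sd = v3_sd,
            v4_mean = v4_mean, v4_sd = v4_sd,
            d_mean = d_mean, d_sd = d_sd,
            a = a, u_noise_sd = u_noise_sd,
            re_mean = re_mean, re_sd = re_sd,
            period_mean = period_mean, period_sd = period_sd,
            aqueduct_length = aqueduct_length,
            n_phases = as.integer(n_phases),
            waveform_shape = waveform_shape)
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

#' Default iNPH contrast-group parameters
#'
#' Table-level iNPH marginals (n = 10, 6 male / 4 female, dilated ventricles,
#' hyperdynamic flow with Re ~ 58 +/- 28 and no inverse U-D relation). The
#' aqueduct diameter marginal is a synthetic assumption (mild dilation),
#' since only its distribution shape is shown in the source material.
#'
#' @param ... overrides passed to [cohort_params()].
#' @return object of class `cohort_params`.
#' @export
inph_params <- function(...) {
  defaults <- list(group = "inph", n_subjects = 10L, n_male = 6L, n_female = 4L,
                   age_mean = 75, age_sd = 7,
                   weight_mean = 56, weight_sd = 12,
                   lv_mean = 109.7, lv_sd = 32.2,
                   v3_mean = 4.5, v3_sd = 1.0,
                   v4_mean = 3.0, v4_sd = 1.0,
                   d_mean = 3.2, d_sd = 0.6)
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}

validate_cohort_params <- function(p) {
  sds <- c(p$age_sd, p$weight_sd, p$lv_sd, p$v3_sd, p$v4_sd, p$d_sd,
           p$u_noise_sd, p$re_sd, p$period_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (p$n_subjects <= 0L) stop("n_subjects must be positive")
  if (p$n_male + p$n_female != p$n_subjects) {
    stop("n_male + n_female must equal n_subjects")
  }
  if (p$n_phases < 4L) stop("n_phases must be >= 4")
  means <- c(p$age_mean, p$weight_mean, p$lv_mean, p$v3_mean, p$v4_mean,
             p$d_mean, p$period_mean)
  sdsm <- c(p$age_sd, p$weight_sd, p$lv_sd, p$v3_sd, p$v4_sd, p$d_sd,
            p$period_sd)
  bad <- sdsm > 0 & means / sdsm < -6
  if (any(bad)) stop("impossible truncation: a marginal mean lies many SDs below 0")
  invisible(TRUE)
}

# Gaussian truncated at `lower` by rejection; degenerate sd = 0 returns the mean.
rtrunc_gauss <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  if (stats::pnorm(lower, mean, sd) > 0.9999) {
    stop("impossible truncation: mean many SDs below the lower bound")
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Generate a synthetic subject cohort
#'
#' Draws `n_subjects` independent subjects from the marginals in `params`.
#' For the healthy group the representative velocity is functionally tied to
#' the aqueduct diameter (`U = a/D + eps`), so the inverse relation holds in
#' expectation and [fit_inverse()] recovers `a`; for the iNPH group `U` is
#' drawn through an independent Reynolds-number marginal. Each subject gets a
#' cardiac-gated waveform whose peak flow rate matches `U` exactly
#' (`Q0 = U * A`), which makes the stroke volume an emergent, internally
#' consistent quantity (`SV = U*A*T_c/pi` for the sinusoid shape).
#'
#' @param params a [cohort_params()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(params, seed)`.
#' @return A `data.frame` of class `csf_cohort`, one row per subject, with a
#'   list column `waveform` of [flow_waveform()] objects.
#' @examples
#' coh <- generate_cohort(cohort_params(), seed = 1)
#' table(coh$sex)  # 19 male, 28 female
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  validate_cohort_params(params)
  p <- params
  n <- p$n_subjects
  set.seed(as.integer(seed))
  sex <- sample(c(rep("male", p$n_male), rep("female", p$n_female)))
  age <- rtrunc_gauss(n, p$age_mean, p$age_sd)
  weight <- rtrunc_gauss(n, p$weight_mean, p$weight_sd)
  lv <- rtrunc_gauss(n, p$lv_mean, p$lv_sd)
  v3 <- rtrunc_gauss(n, p$v3_mean, p$v3_sd)
  v4 <- rtrunc_gauss(n, p$v4_mean, p$v4_sd)
  d <- rtrunc_gauss(n, p$d_mean, p$d_sd)
  period <- rtrunc_gauss(n, p$period_mean, p$period_sd)
  if (p$group == "healthy") {
    u <- p$a / d + stats::rnorm(n, 0, p$u_noise_sd)
    bad <- which(u <= 0)
    while (length(bad) > 0L) {  # redraw the noise, keep the diameter
      u[bad] <- p$a / d[bad] + stats::rnorm(length(bad), 0, p$u_noise_sd)
      bad <- bad[u[bad] <= 0]
    }
  } else {
    re_draw <- rtrunc_gauss(n, p$re_mean, p$re_sd)
    u <- re_draw / d
  }
  area <- pi * (d / 2)^2
  waveforms <- vector("list", n)
  sv <- numeric(n)
  for (i in seq_len(n)) {
    # peak flow matched to U so that representative_velocity(wf, A) == U
    q0 <- u[i] * area[i]
    sv_i <- switch(p$waveform_shape,
                   sinusoid = q0 * period[i] / pi,
                   biphasic = {
                     thd <- seq(0, 2 * pi, length.out = 20001L)
                     s <- sin(thd) + 0.35 * sin(2 * thd)
                     q0 / max(abs(s)) * (period[i] / 2) * mean(abs(s))
                   })
    waveforms[[i]] <- generate_waveform(sv_i, period[i], p$n_phases,
                                        p$waveform_shape)
    sv[i] <- sv_i
  }
  out <- data.frame(
    id = sprintf("%s%03d", if (p$group == "healthy") "H" else "N", seq_len(n)),
    group = p$group, sex = sex, age = age, weight_kg = weight,
    lv_ml = lv, v3_ml = v3, v4_ml = v4,
    d_mm = d, aqueduct_length_mm = p$aqueduct_length,
    period_s = period, a_mm2 = area,
    u_mm_s = u, sv_ul = sv, re = reynolds(u, d),
    stringsAsFactors = FALSE)
  out$waveform <- waveforms
  class(out) <- c("csf_cohort", "data.frame")
  out
}

#' Write a cohort to delimited tables
#'
#' Writes `cohort.csv` (one row per subject, scalar columns) and one
#' `waveform_<id>.csv` per subject with columns `time_s`, `Q_ul_per_s` and
#' the cardiac period recorded in a header comment.
#'
#' @param cohort a `csf_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scal <- cohort[, setdiff(names(cohort), "waveform")]
  utils::write.csv(scal, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    wf <- cohort$waveform[[i]]
    f <- file.path(dir, sprintf("waveform_%s.csv", cohort$id[i]))
    con <- file(f, "w")
    writeLines(sprintf("# period_s=%.10g", wf$period), con)
    utils::write.table(data.frame(time_s = wf$time, Q_ul_per_s = wf$q),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv` and waveform tables.
#' @param net_tol zero-net-volume tolerance for the waveforms (user-supplied
#'   measured waveforms may need a looser tolerance).
#' @return a `csf_cohort` data frame.
#' @export
read_cohort <- function(dir, net_tol = 1e-6) {
  scal <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  wfs <- vector("list", nrow(scal))
  for (i in seq_len(nrow(scal))) {
    f <- file.path(dir, sprintf("waveform_%s.csv", scal$id[i]))
    hdr <- readLines(f, n = 1L)
    period <- as.numeric(sub("# period_s=", "", hdr, fixed = TRUE))
    tab <- utils::read.csv(f, comment.char = "#")
    wfs[[i]] <- flow_waveform(tab$time_s, tab$Q_ul_per_s, period,
                              net_tol = net_tol)
  }
  scal$waveform <- wfs
  class(scal) <- c("csf_cohort", "data.frame")
  scal
}
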