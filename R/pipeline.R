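# End-to-end orchestration: cohort -> geometry -> CFD -> tracking -> mixing
# -> cohort statistics, with per-stage caching and crash isolation.

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations with output and caching options.
#' Serializes losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param cohort a [cohort_params()].
#' @param template a [geometry_template()].
#' @param base_size mesh base size in mm (scaled internally by D/2.82 per
#'   subject so narrow aqueducts stay resolved).
#' @param solver a [solver_config()].
#' @param tracking a [tracking_config()].
#' @param mix_scales mixing scale set.
#' @param out_dir output directory (`NULL`: no files written).
#' @param seed global seed controlling all randomness.
#' @param cache reuse per-subject results keyed by a content hash of the
#'   inputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(),
                       template = geometry_template(),
                       base_size = 0.7,
                       solver = solver_config(cfl = 0.5),
                       tracking = tracking_config(),
                       mix_scales = c(2L, 4L, 6L, 8L, 10L),
                       out_dir = NULL, seed = 1L, cache = TRUE) {
  structure(list(cohort = cohort, template = template, base_size = base_size,
                 solver = solver, tracking = tracking,
                 mix_scales = as.integer(mix_scales),
                 out_dir = out_dir, seed = as.integer(seed), cache = cache),
            class = "run_config")
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s cohort n=%d, base %.2f mm, %d tracking cycles, seed %d\n",
              x$cohort$group, x$cohort$n_subjects, x$base_size,
              x$tracking$n_cycles, x$seed))
  invisible(x)
}

#' Serialize / deserialize a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param file YAML path.
#' @return `file` invisibly (write) or the `run_config` (read).
#' @export
write_run_config <- function(cfg, file) {
  plain <- lapply(cfg, function(el) if (is.list(el)) unclass(el) else el)
  yaml::write_yaml(plain, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  run_config(cohort = do.call(cohort_params, y$cohort),
             template = do.call(geometry_template, y$template),
             base_size = y$base_size,
             solver = do.call(solver_config, y$solver),
             tracking = do.call(tracking_config, y$tracking),
             mix_scales = y$mix_scales,
             out_dir = y$out_dir, seed = y$seed, cache = y$cache)
}

# content hash (md5 of the serialized object) for cache keys
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

#' Run the full chain for one subject
#'
#' Geometry, mesh, one periodic CFD solution, 20-cycle particle tracking and
#' the mix-norm, plus the MRI-style flow metrics with the 4-section
#' consistency check (evaluation planes at 20/40/60/80% of the aqueduct
#' length). A failing stage returns a structured error record rather than
#' raising, so one subject cannot take down a cohort run.
#'
#' @param subject one-row `csf_cohort` data frame (or equivalent list with a
#'   `waveform` entry).
#' @param cfg a [run_config()].
#' @return list with `id`, `metrics` (a [flow_metrics()]), `mixing` (a
#'   [mix_norm()] result), `excluded`, `field` diagnostics, or an `error`
#'   record with the failing stage.
#' @export
run_subject <- function(subject, cfg = run_config()) {
  if (is.data.frame(subject)) {
    wf <- subject$waveform[[1L]]
    subject <- as.list(subject[1L, setdiff(names(subject), "waveform")])
    subject$waveform <- wf
  }
  key <- content_hash(list(subject = subject, template = cfg$template,
                           base_size = cfg$base_size, solver = cfg$solver,
                           tracking = cfg$tracking, scales = cfg$mix_scales))
  cache_file <- if (!is.null(cfg$out_dir) && cfg$cache) {
    file.path(cfg$out_dir, "cache", paste0(subject$id, "_", key, ".rds"))
  }
  if (!is.null(cache_file) && file.exists(cache_file)) {
    return(readRDS(cache_file))
  }
  stage <- "geometry"
  out <- tryCatch({
    geo <- build_geometry(subject, cfg$template)
    stage <- "meshing"
    mesh <- mesh_geometry(geo, cfg$base_size * subject$d_mm / 2.82)
    stage <- "cfd"
    fld <- solve_cycle(mesh, subject$waveform, cfg = cfg$solver)
    stage <- "flow_metrics"
    zpl <- geo$aqueduct_z[1L] + diff(geo$aqueduct_z) * c(0.2, 0.4, 0.6, 0.8)
    qs <- lapply(zpl, function(z) cross_section_flow(fld, z))
    areas <- vapply(qs, attr, numeric(1L), "area")
    qmat <- do.call(cbind, lapply(qs, function(w) w$q))
    met <- flow_metrics(qs[[2L]], area = areas[2L], areas = areas,
                        q_sections = qmat)
    stage <- "tracking"
    pts <- seed_particles(mesh, cfg$tracking$spacing)
    adv <- advect_particles(pts, fld, cfg$tracking)
    stage <- "mixing"
    grid <- build_mix_grid(mesh, cfg$mix_scales)
    mr <- mix_norm(adv, grid)
    list(id = subject$id, metrics = met, mixing = mr,
         excluded = met$excluded,
         field = list(periodicity = fld$periodicity,
                      mass_residual = max(abs(fld$log$mass_residual)) /
                                      max(abs(subject$waveform$q)),
                      nsteps = fld$nsteps, n_tets = nrow(mesh$tets)))
  }, error = function(e) {
    list(id = subject$id, error = conditionMessage(e), stage = stage)
  })
  if (!is.null(cache_file) && is.null(out$error)) {
    dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
    saveRDS(out, cache_file)
  }
  out
}

#' Run a full synthetic-cohort study
#'
#' Generates the cohort, runs every subject through [run_subject()], applies
#' the exclusion rule, and computes the statistics layer: group summaries,
#' sex and age comparisons, the inverse U-D regression, outlier flags, and
#' the mix-norm-versus-Reynolds-number regression.
#'
#' @param cfg a [run_config()].
#' @param cohort optionally a pre-generated `csf_cohort` (defaults to
#'   `generate_cohort(cfg$cohort, cfg$seed)`).
#' @return list of class `cohort_report`: `subjects` (per-subject results
#'   table), `excluded_ids`, `errors`, `comparisons`, `inverse_fit`,
#'   `mix_re_fit`, `outliers`.
#' @export
run_cohort <- function(cfg = run_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(cfg$cohort, cfg$seed)
  results <- lapply(seq_len(nrow(cohort)), function(i) {
    run_subject(cohort[i, ], cfg)
  })
  errs <- Filter(function(r) !is.null(r$error), results)
  ok <- Filter(function(r) is.null(r$error), results)
  tab <- do.call(rbind, lapply(ok, function(r) {
    data.frame(id = r$id, d_mm = r$metrics$d_mm, sv_ul = r$metrics$sv_ul,
               u_mm_s = r$metrics$u_mm_s, re = r$metrics$re,
               consistency_error = r$metrics$consistency_error,
               excluded = r$excluded, m = r$mixing$m,
               t(r$mixing$m_scales), stringsAsFactors = FALSE)
  }))
  excluded_ids <- tab$id[tab$excluded]
  use <- merge(cohort[, setdiff(names(cohort), "waveform")],
               tab[!tab$excluded, ], by = "id", suffixes = c("_gen", ""))
  comparisons <- list()
  outliers <- list()
  inverse <- NULL
  mix_re <- NULL
  if (nrow(use) >= 2L) {
    grp <- split_groups(use)
    for (v in c("d_mm", "sv_ul", "re", "m")) {
      if (length(grp$male) && length(grp$female)) {
        comparisons[[paste0(v, "_sex")]] <-
          mann_whitney(use[[v]][grp$male], use[[v]][grp$female])
      }
      if (length(grp$young) && length(grp$older)) {
        comparisons[[paste0(v, "_age")]] <-
          mann_whitney(use[[v]][grp$young], use[[v]][grp$older])
      }
    }
    inverse <- fit_inverse(use$d_mm, use$u_mm_s)
    if (stats::sd(use$re) > 0) mix_re <- linear_fit(use$re, use$m)
    if (nrow(use) >= 4L) {
      outliers <- lapply(stats::setNames(nm = c("sv_ul", "re", "m")),
                         function(v) use$id[flag_outliers(use[[v]])])
    }
  } else {
    message("fewer than 2 usable subjects: statistics skipped")
  }
  report <- structure(list(subjects = tab, usable = use,
                           excluded_ids = excluded_ids,
                           errors = errs, comparisons = comparisons,
                           inverse_fit = inverse, mix_re_fit = mix_re,
                           outliers = outliers, config = cfg),
                      class = "cohort_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(cfg$out_dir, "subjects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_json <- function(report) {
  cmp <- lapply(report$comparisons, function(gc) {
    list(n = gc$n, u = gc$u, p = gc$p, significant = gc$significant,
         method = gc$method)
  })
  list(n_subjects = nrow(report$subjects),
       n_excluded = length(report$excluded_ids),
       excluded_ids = report$excluded_ids,
       n_errors = length(report$errors),
       comparisons = cmp,
       inverse_fit = if (!is.null(report$inverse_fit)) {
         list(a = report$inverse_fit$a, r_squared = report$inverse_fit$r_squared)
       },
       mix_re_fit = report$mix_re_fit,
       outliers = report$outliers,
       multiple_testing_correction = "none")
}

#' @exportS3Method base::print
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects (%d excluded, %d failed)\n",
              nrow(x$subjects), length(x$excluded_ids), length(x$errors)))
  if (!is.null(x$inverse_fit)) {
    cat(sprintf("  U = a/D: a = %.2f (R^2 = %.3f)\n",
                x$inverse_fit$a, x$inverse_fit$r_squared))
  }
  if (!is.null(x$mix_re_fit)) {
    cat(sprintf("  m vs Re: slope %.4g, intercept %.3f, R^2 = %.3f\n",
                x$mix_re_fit$slope, x$mix_re_fit$intercept,
                x$mix_re_fit$r_squared))
  }
  invisible(x)
}
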