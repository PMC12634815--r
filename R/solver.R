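# Fractional-step incompressible Navier-Stokes solver on labeled meshes.
#
# Scheme per time step (P1/P1, linearized-ALE small-deformation form):
#   1. tentative velocity: explicit SUPG advection with the ALE advective
#      velocity (v - mesh velocity), Crank-Nicolson implicit diffusion;
#   2. pressure projection: Poisson equation with p = 0 on the outlets,
#      homogeneous Neumann on walls;
#   3. velocity correction with the lumped mass matrix, Dirichlet values
#      (moving-wall program / no-slip) re-imposed.
# Operators are assembled once on the reference mesh: at cohort conditions
# the wall displacement is far below the element size, so mesh motion enters
# only through the advective velocity and the stored phase coordinates.

#' Moving-wall boundary program
#'
#' Converts the driving flow waveform into a wall-velocity program
#' `w(x,t) = alpha(t) n(x)` on the `moving_wall` boundary, with the uniform
#' normal speed `alpha(t) = -Q(t)/A_eff` calibrated against the discrete
#' effective wall area so that the discrete wall flux equals `-Q(t)` to
#' machine precision (the wall volume change sources the aqueduct flow).
#'
#' @param mesh a `csf_mesh` with a non-empty `moving_wall` label.
#' @param waveform the driving [flow_waveform()].
#' @param interp waveform time interpolation, `"spline"` (periodic cubic) or
#'   `"linear"`.
#' @return object of class `wall_program`: unit wall field `W` (n x 3),
#'   `a_eff` (mm^2), `alpha_fun(t)` (mm/s), Dirichlet node sets.
#' @export
build_wall_program <- function(mesh, waveform, interp = "spline") {
  mov <- mesh$labels == "moving_wall"
  if (!any(mov)) stop("zero moving-wall area: mesh has no moving_wall facets")
  n <- nrow(mesh$nodes)
  fg <- facet_geometry(mesh$nodes, mesh$tris)
  mov_tris <- mesh$tris[mov, , drop = FALSE]
  mov_area <- fg$area[mov]
  mov_norm <- fg$normal[mov, , drop = FALSE]
  # area-weighted outward nodal normals on the moving wall
  W <- matrix(0, n, 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(mov_area * mov_norm[, d], mov_tris[, k])
      W[as.integer(rownames(acc)), d] <- W[as.integer(rownames(acc)), d] + acc
    }
  }
  nrm <- sqrt(rowSums(W^2))
  nz <- nrm > 0
  W[nz, ] <- W[nz, ] / nrm[nz]
  # nodes shared with rigid walls or outlets stay no-slip
  other_nodes <- unique(as.vector(mesh$tris[!mov, , drop = FALSE]))
  W[other_nodes, ] <- 0
  moving_nodes <- setdiff(unique(as.vector(mov_tris)), other_nodes)
  # discrete effective area: facet flux of the unit wall field
  wf1 <- (W[mov_tris[, 1L], ] + W[mov_tris[, 2L], ] + W[mov_tris[, 3L], ]) / 3
  a_eff <- sum(mov_area * rowSums(wf1 * mov_norm))
  if (a_eff <= 0) stop("zero moving-wall area: degenerate wall normals")
  qfun <- waveform_fun(waveform, method = if (interp == "spline") "spline" else "linear")
  rigid_nodes <- setdiff(unique(as.vector(mesh$tris[mesh$labels == "rigid_wall", ,
                                                    drop = FALSE])), moving_nodes)
  structure(list(W = W, a_eff = a_eff,
                 alpha_fun = function(t) -qfun(t) / a_eff,
                 waveform = waveform,
                 moving_nodes = moving_nodes,
                 rigid_nodes = rigid_nodes,
                 dirichlet_nodes = sort(c(moving_nodes, rigid_nodes))),
            class = "wall_program")
}

# discrete flux of a nodal vector field through a set of boundary facets
facet_flux <- function(mesh, tris_sel, field) {
  fg <- facet_geometry(mesh$nodes, tris_sel)
  fmean <- (field[tris_sel[, 1L], , drop = FALSE] +
            field[tris_sel[, 2L], , drop = FALSE] +
            field[tris_sel[, 3L], , drop = FALSE]) / 3
  sum(fg$area * rowSums(fmean * fg$normal))
}

#' Interior mesh motion by harmonic extension
#'
#' Solves a Laplacian smoothing problem for the interior node displacements
#' given prescribed boundary values; the mesh velocity is the displacement
#' rate. Elements must stay positively oriented after motion.
#'
#' @param mesh a `csf_mesh`.
#' @param boundary_disp n x 3 matrix, nonzero only on boundary nodes.
#' @return list with `disp` (n x 3, the harmonic extension) and
#'   `min_volume` after applying the displacement; an error identifies the
#'   inverted elements if the motion tangles the mesh.
#' @export
ale_mesh_motion <- function(mesh, boundary_disp) {
  fem <- fem_prepare(mesh)
  bnodes <- sort(unique(as.vector(mesh$tris)))
  free <- setdiff(seq_len(fem$n), bnodes)
  disp <- boundary_disp
  if (length(free)) {
    Kff <- fem$K[free, free, drop = FALSE]
    Kfb <- fem$K[free, bnodes, drop = FALSE]
    sol <- Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                         -Kfb %*% boundary_disp[bnodes, , drop = FALSE])
    disp[free, ] <- as.matrix(sol)
  }
  vol <- tet_volumes(mesh$nodes + disp, mesh$tets)
  if (any(vol <= 0)) {
    stop(sprintf("mesh motion inverted %d elements (first: %d)",
                 sum(vol <= 0), which(vol <= 0)[1L]))
  }
  list(disp = disp, min_volume = min(vol))
}

#' Solver configuration
#'
#' @param dt explicit time step in s; if `NULL` it is chosen from the
#'   advective CFL condition `cfl * h_min / U_est` (U_est twice the peak
#'   area-averaged aqueduct velocity), clamped to
#'   `[period/max_steps, period/min_steps]` and rounded so a whole number of
#'   steps fits between stored phases.
#' @param cfl target advective Courant number.
#' @param cycles cardiac cycles to run; the last is stored (spin-up to a
#'   periodic state).
#' @param store_phases stored phases per cycle.
#' @param min_steps,max_steps bounds on steps per cycle.
#' @param waveform_interp `"spline"` or `"linear"` time interpolation of the
#'   driving waveform.
#' @param check_net_volume refuse waveforms with nonzero net volume per
#'   cycle (disable for steady benchmark runs).
#' @param n_projection pressure-correction sweeps per step (each one Poisson
#'   solve); the default keeps the discrete mass-balance residual below 1%
#'   of the peak flow rate at the default resolution.
#' @param store_pressure keep nodal pressure per stored phase.
#' @param verbose print per-cycle progress.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = NULL, cfl = 0.8, cycles = 3L,
                          store_phases = 40L, min_steps = 60L,
                          max_steps = 2000L, waveform_interp = "spline",
                          check_net_volume = TRUE, n_projection = 4L,
                          store_pressure = FALSE, verbose = FALSE) {
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  structure(list(dt = dt, cfl = cfl, cycles = as.integer(cycles),
                 store_phases = as.integer(store_phases),
                 min_steps = as.integer(min_steps),
                 max_steps = as.integer(max_steps),
                 waveform_interp = waveform_interp,
                 check_net_volume = check_net_volume,
                 n_projection = as.integer(n_projection),
                 store_pressure = store_pressure,
                 verbose = verbose),
            class = "solver_config")
}

#' Solve one periodic cardiac cycle of ventricular CSF flow
#'
#' Runs the fractional-step scheme for `cfg$cycles` cardiac cycles on the
#' labeled mesh, driven by the moving-wall program derived from `waveform`
#' (no-slip on `rigid_wall`, 0 Pa on `outlet`), and returns the final cycle
#' as a phase-resolved periodic velocity field. Per-step mass-balance and
#' divergence residuals are logged.
#'
#' @param mesh a `csf_mesh`.
#' @param bc a [flow_waveform()] (a wall program is built internally) or a
#'   prebuilt [build_wall_program()] result.
#' @param props a [fluid_props()].
#' @param cfg a [solver_config()].
#' @return object of class `velocity_field`: `u` (n x 3 x P, mm/s),
#'   optional `p` (kinematic pressure * rho, Pa), `times` (s), `mesh`,
#'   `period`, wall/ALE data, and a per-step `log` data frame.
#' @export
solve_cycle <- function(mesh, bc, props = fluid_props(), cfg = solver_config()) {
  wf <- if (inherits(bc, "wall_program")) bc$waveform else bc
  wp <- if (inherits(bc, "wall_program")) bc
        else build_wall_program(mesh, wf, cfg$waveform_interp)
  if (cfg$check_net_volume) {
    tt <- c(wf$time, wf$period); qq <- c(wf$q, wf$q[1L])
    net <- sum(diff(tt) * (utils::head(qq, -1L) + utils::tail(qq, -1L)) / 2)
    tot <- sum(diff(tt) * abs(utils::head(qq, -1L) + utils::tail(qq, -1L)) / 2)
    if (tot > 0 && abs(net) > 1e-6 * tot) {
      stop("waveform has nonzero net volume per cycle; use check_net_volume = FALSE for steady benchmarks")
    }
  }
  nu <- props$viscosity / props$density * 1e6   # mm^2/s
  fem <- fem_prepare(mesh)
  n <- fem$n
  tc <- wf$period
  # ALE: harmonic extension of the unit wall-normal field
  bnodes <- sort(unique(as.vector(mesh$tris)))
  bd <- matrix(0, n, 3L)
  bd[wp$moving_nodes, ] <- wp$W[wp$moving_nodes, ]
  E <- {
    free <- setdiff(seq_len(n), bnodes)
    disp <- bd
    if (length(free)) {
      Kff <- fem$K[free, free, drop = FALSE]
      Kfb <- fem$K[free, bnodes, drop = FALSE]
      disp[free, ] <- as.matrix(
        Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                      -Kfb %*% bd[bnodes, , drop = FALSE]))
    }
    disp
  }
  # time step from the advective CFL
  a_aq <- pi * (mesh$d / 2)^2
  qmax <- max(abs(wf$q))
  u_est <- max(2 * qmax / a_aq, 1e-9)
  dt <- if (!is.null(cfg$dt)) cfg$dt else cfg$cfl * fem$hmin / u_est
  nsteps <- ceiling(tc / dt)
  nsteps <- min(max(nsteps, cfg$min_steps), cfg$max_steps)
  nsteps <- as.integer(ceiling(nsteps / cfg$store_phases) * cfg$store_phases)
  dt <- tc / nsteps
  stride <- nsteps %/% cfg$store_phases
  # operators with Dirichlet elimination
  cons <- wp$dirichlet_nodes
  free <- setdiff(seq_len(n), cons)
  A <- fem$M / dt + (nu / 2) * fem$K
  facA <- Matrix::Cholesky(Matrix::forceSymmetric(A[free, free, drop = FALSE]))
  Afc <- A[free, cons, drop = FALSE]
  # 0 Pa pressure on the outlets, imposed at the nodes strictly interior to
  # the outlet openings; the junction-ring nodes (shared with the no-slip
  # wall) keep their continuity rows tested, which keeps the global
  # wall+outlet flux balance tight
  out_tris <- mesh$tris[mesh$labels == "outlet", , drop = FALSE]
  if (nrow(out_tris) == 0L) stop("mesh has no outlet facets")
  pdir <- setdiff(sort(unique(as.vector(out_tris))), cons)
  if (!length(pdir)) pdir <- sort(unique(as.vector(out_tris)))[1L]
  pfree <- setdiff(seq_len(n), pdir)
  facP <- Matrix::Cholesky(Matrix::forceSymmetric(fem$K[pfree, pfree, drop = FALSE]))
  mov_tris <- mesh$tris[mesh$labels == "moving_wall", , drop = FALSE]

  u <- matrix(0, n, 3L)
  p <- numeric(n)
  P <- cfg$store_phases
  ustore <- array(0, c(n, 3L, P))
  pstore <- if (cfg$store_pressure) matrix(0, n, P) else NULL
  times <- numeric(P)
  alphas <- numeric(P)
  log_rows <- vector("list", cfg$cycles * nsteps)
  u_cycle_start <- NULL
  step_id <- 0L
  for (cyc in seq_len(cfg$cycles)) {
    if (cyc == cfg$cycles) u_cycle_start <- u
    for (s in seq_len(nsteps)) {
      step_id <- step_id + 1L
      t0 <- (s - 1L) * dt
      t1 <- s * dt
      a0 <- wp$alpha_fun(t0)
      a1 <- wp$alpha_fun(t1)
      util <- u - a0 * E
      adv <- advection_term(fem, u, util, dt, nu)
      # incremental pressure-correction: the lagged pressure gradient enters
      # the momentum step, the Poisson solve then corrects its increment
      rhs <- as.matrix(fem$M %*% (u / dt) - (nu / 2) * (fem$K %*% u)) - adv -
             cbind(as.numeric(fem$D[[1L]] %*% p),
                   as.numeric(fem$D[[2L]] %*% p),
                   as.numeric(fem$D[[3L]] %*% p))
      uc <- a1 * wp$W[cons, , drop = FALSE]   # rigid rows of W are zero
      ustar <- matrix(0, n, 3L)
      ustar[free, ] <- as.matrix(Matrix::solve(facA,
        rhs[free, , drop = FALSE] - as.matrix(Afc %*% uc)))
      ustar[cons, ] <- uc
      # pressure projection, iterated because the lumped-mass correction
      # only approximately annihilates the P1 divergence
      u <- ustar
      for (it in seq_len(cfg$n_projection)) {
        divu <- as.numeric(fem$D[[1L]] %*% u[, 1L] +
                           fem$D[[2L]] %*% u[, 2L] +
                           fem$D[[3L]] %*% u[, 3L])
        dp <- numeric(n)
        dp[pfree] <- as.numeric(Matrix::solve(facP, -divu[pfree] / dt))
        u <- u - dt * cbind(as.numeric(fem$D[[1L]] %*% dp) / fem$ml,
                            as.numeric(fem$D[[2L]] %*% dp) / fem$ml,
                            as.numeric(fem$D[[3L]] %*% dp) / fem$ml)
        u[cons, ] <- uc
        p <- p + dp
      }
      umax <- sqrt(max(rowSums(u^2)))
      if (umax * dt / fem$hmin > 4 * cfg$cfl) {
        stop(sprintf(paste("CFL violation at step %d (Courant %.2f):",
                           "reduce dt or raise max_steps"),
                     step_id, umax * dt / fem$hmin))
      }
      wall_flux <- facet_flux(mesh, mov_tris, u)
      out_flux <- facet_flux(mesh, out_tris, u)
      divres <- as.numeric(fem$D[[1L]] %*% u[, 1L] + fem$D[[2L]] %*% u[, 2L] +
                           fem$D[[3L]] %*% u[, 3L])
      log_rows[[step_id]] <- c(cycle = cyc, time = t1, umax = umax,
                               q = -a1 * wp$a_eff,
                               wall_flux = wall_flux, outlet_flux = out_flux,
                               mass_residual = wall_flux + out_flux,
                               div_l2 = sqrt(sum(divres^2)),
                               ke = 0.5 * sum(fem$ml * rowSums(u^2)))
      if (cyc == cfg$cycles && s %% stride == 0L) {
        ph <- s %/% stride
        ustore[, , ph] <- u
        if (cfg$store_pressure) pstore[, ph] <- p * props$density * 1e-6
        times[ph] <- t1
        alphas[ph] <- a1
      }
    }
    if (cfg$verbose) {
      message(sprintf("cycle %d/%d: max|u| = %.3f mm/s", cyc, cfg$cycles,
                      max(sqrt(rowSums(u^2)))))
    }
  }
  # phase 0 = end of cycle (periodic); roll so times start near 0
  times <- times %% tc
  ord <- order(times)
  ustore <- ustore[, , ord, drop = FALSE]
  times <- times[ord]
  alphas <- alphas[ord]
  if (cfg$store_pressure) pstore <- pstore[, ord, drop = FALSE]
  per <- sqrt(sum((u - u_cycle_start)^2)) /
         max(sqrt(max(rowSums(u^2))) * sqrt(n), 1e-30)
  lg <- as.data.frame(do.call(rbind, log_rows))
  # periodic integral of alpha for the stored mesh displacement amplitude
  tdense <- seq(0, tc, length.out = 2001L)
  adense <- wp$alpha_fun(tdense)
  aint <- cumsum(c(0, diff(tdense) * (utils::head(adense, -1L) +
                                      utils::tail(adense, -1L)) / 2))
  structure(list(mesh = mesh, u = ustore, p = pstore, times = times,
                 period = tc, alpha = alphas, wall = wp, ale_mode = E,
                 alpha_int = stats::approxfun(tdense, aint, rule = 2),
                 dt = dt, nsteps = nsteps,
                 periodicity = per, log = lg),
            class = "velocity_field")
}

#' @exportS3Method base::print
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d nodes, %d phases, T = %.3f s, max|u| = %.2f mm/s\n",
              dim(x$u)[1L], dim(x$u)[3L], x$period,
              sqrt(max(apply(x$u, 3L, function(m) max(rowSums(m^2)))))))
  cat(sprintf("  periodicity residual %.3g, peak |mass residual| %.3g ul/s\n",
              x$periodicity, max(abs(x$log$mass_residual))))
  invisible(x)
}

#' Mesh-independency protocol
#'
#' Runs the same driven cycle on a coarse/medium/fine mesh hierarchy
#' (base sizes scaled by D/2.82 so narrow aqueducts stay resolved) and
#' reports the relative difference of the peak area-averaged aqueduct
#' velocity between each pair, the finer run serving as reference.
#'
#' @param geom a `csf_geometry`.
#' @param waveform driving [flow_waveform()].
#' @param sizes three strictly decreasing base mesh sizes (mm).
#' @param props,cfg forwarded to [solve_cycle()].
#' @return data frame with one row per mesh (base size, elements, peak
#'   velocity) and attribute `pairs`: the pairwise relative errors.
#' @export
mesh_convergence <- function(geom, waveform,
                             sizes = c(1.4, 0.7, 0.35) * geom$d / 2.82,
                             props = fluid_props(), cfg = solver_config(cycles = 2L)) {
  if (length(sizes) != 3L || any(diff(sizes) >= 0)) {
    stop("sizes must be three strictly decreasing base mesh sizes")
  }
  zmid <- mean(geom$aqueduct_z)
  upk <- rep(NA_real_, 3L)
  nel <- rep(NA_integer_, 3L)
  for (i in 1:3) {
    res <- try({
      mesh <- mesh_geometry(geom, sizes[i])
      fld <- solve_cycle(mesh, waveform, props, cfg)
      qs <- cross_section_flow(fld, zmid)
      nel[i] <- nrow(mesh$tets)
      upk[i] <- max(abs(qs$q)) / attr(qs, "area")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("run at base size %.3g failed: %s", sizes[i],
                      attr(res, "condition")$message))
    }
  }
  out <- data.frame(base_size = sizes, n_tets = nel, u_peak = upk)
  rel <- function(a, b) abs(upk[a] - upk[b]) / upk[b]
  attr(out, "pairs") <- data.frame(
    pair = c("coarse_vs_medium", "medium_vs_fine", "coarse_vs_fine"),
    rel_error = c(rel(1L, 2L), rel(2L, 3L), rel(1L, 3L)))
  out
}
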