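# Sampling a stored velocity field and MRI-style cross-section flow series.

get_locator <- function(mesh) {
  loc <- mesh$cache$locator
  if (is.null(loc) || !cm_locator_valid(loc)) {
    lab <- match(mesh$labels, c("moving_wall", "rigid_wall", "outlet"))
    loc <- cm_locator_build(mesh$nodes, mesh$tets, mesh$tris,
                            as.integer(lab))
    mesh$cache$locator <- loc
  }
  loc
}

#' Locate points and interpolate the velocity field
#'
#' Barycentric (P1) interpolation within the containing tetrahedron with
#' periodic time interpolation between stored phases. Points outside the
#' fluid domain get `NA` rows (an "exited" signal, not an error).
#'
#' @param field a `velocity_field` from [solve_cycle()].
#' @param pts m x 3 matrix of positions (mm).
#' @param t time in seconds (extended periodically).
#' @param interp `"linear"` or `"periodic-cubic"` time interpolation.
#' @return m x 3 matrix of velocities (mm/s).
#' @export
sample_velocity <- function(field, pts, t = 0,
                            interp = c("linear", "periodic-cubic")) {
  interp <- match.arg(interp)
  pts <- matrix(as.numeric(pts), ncol = 3L)
  loc <- get_locator(field$mesh)
  lr <- cm_locate(loc, pts, integer(0))
  P <- dim(field$u)[3L]
  s <- t %% field$period
  # blend the two bracketing phases
  tt <- c(field$times, field$times[1L] + field$period)
  p1 <- findInterval(s, tt, rightmost.closed = FALSE)
  p1 <- max(1L, min(p1, P))
  t1 <- tt[p1]; t2 <- tt[p1 + 1L]
  w <- if (t2 > t1) (s - t1) / (t2 - t1) else 0
  p2 <- if (p1 == P) 1L else p1 + 1L
  if (interp == "linear") {
    ub <- (1 - w) * field$u[, , p1] + w * field$u[, , p2]
  } else {
    pm <- if (p1 == 1L) P else p1 - 1L
    pp <- if (p2 == P) 1L else p2 + 1L
    ub <- catmull_rom(field$u[, , pm], field$u[, , p1],
                      field$u[, , p2], field$u[, , pp], w)
  }
  out <- matrix(NA_real_, nrow(pts), 3L)
  inside <- lr$tet > 0L
  if (any(inside)) {
    tets <- field$mesh$tets[lr$tet[inside], , drop = FALSE]
    bar <- lr$bary[inside, , drop = FALSE]
    for (d in 1:3) {
      out[inside, d] <- rowSums(bar * matrix(ub[tets, d], ncol = 4L))
    }
  }
  out
}

catmull_rom <- function(um, u0, u1, up, w) {
  w2 <- w * w; w3 <- w2 * w
  (-0.5 * w3 + w2 - 0.5 * w) * um + (1.5 * w3 - 2.5 * w2 + 1) * u0 +
    (-1.5 * w3 + 2 * w2 + 0.5 * w) * u1 + (0.5 * w3 - 0.5 * w2) * up
}

#' Cross-sectional flow rate series
#'
#' Integrates the axial velocity over an oriented cross-section plane
#' (normal +z, the craniocaudal direction) at every stored phase. The disk
#' is sampled with an equal-area annular quadrature; sample points that fall
#' outside the polygonal mesh boundary (a thin near-wall sliver) contribute
#' zero velocity, consistent with no-slip.
#'
#' @param x a `velocity_field` (or a [flow_waveform()], returned unchanged:
#'   with rigid walls distal of the moving boundary the flow rate is
#'   plane-independent).
#' @param z axial plane position (mm), which must cut the geometry.
#' @param radius plane radius (defaults to the aqueduct radius).
#' @param n_r,n_theta annular quadrature resolution.
#' @param ... unused.
#' @return a [flow_waveform()]-like object with the per-phase flow rates
#'   (ul/s) and attribute `area` (mm^2).
#' @export
cross_section_flow <- function(x, ...) UseMethod("cross_section_flow")

#' @rdname cross_section_flow
#' @export
cross_section_flow.flow_waveform <- function(x, ...) x

#' @rdname cross_section_flow
#' @export
cross_section_flow.velocity_field <- function(x, z, radius = x$mesh$d / 2,
                                              n_r = 12L, n_theta = 16L, ...) {
  mesh <- x$mesh
  zr <- range(mesh$nodes[, 3L])
  if (z <= zr[1L] || z >= zr[2L]) stop("geometry error: plane misses the mesh")
  rr <- radius * sqrt((seq_len(n_r) - 0.5) / n_r)
  th <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  pts <- cbind(rep(rr, each = n_theta) * cos(th),
               rep(rr, each = n_theta) * sin(th),
               z)
  area <- pi * radius^2
  wq <- area / (n_r * n_theta)
  P <- dim(x$u)[3L]
  loc <- get_locator(mesh)
  lr <- cm_locate(loc, pts, integer(0))
  inside <- lr$tet > 0L
  q <- numeric(P)
  if (any(inside)) {
    tets <- mesh$tets[lr$tet[inside], , drop = FALSE]
    bar <- lr$bary[inside, , drop = FALSE]
    for (p in seq_len(P)) {
      uz <- rowSums(bar * matrix(x$u[, 3L, p][tets], ncol = 4L))
      q[p] <- wq * sum(uz)
    }
  }
  out <- structure(list(time = x$times, q = q, period = x$period),
                   class = "flow_waveform")
  attr(out, "area") <- area
  out
}
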