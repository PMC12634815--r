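#' CSF fluid properties
#'
#' CSF is modeled as a Newtonian fluid with water-like properties.
#'
#' @param density rho in kg/m^3.
#' @param viscosity dynamic viscosity mu in Pa s.
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1e3, viscosity = 1e-3) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(viscosity) || viscosity <= 0) stop("viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity), class = "fluid_props")
}

#' Reynolds number of aqueductal CSF flow
#'
#' `Re = rho * U * D / mu` with `U` the representative (peak area-averaged)
#' velocity and `D` the aqueduct diameter. Inputs are in the package's
#' mm-based interface units and converted to SI internally; with water-like
#' CSF properties the kinematic viscosity is 1 mm^2/s, so Re equals the
#' numeric product `U[mm/s] * D[mm]`.
#'
#' @param u representative velocity in mm/s (>= 0).
#' @param d aqueduct diameter in mm (> 0).
#' @param props a [fluid_props()].
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds(10.14, 2.82)  # ~28.6, a typical healthy aqueduct
#' @export
reynolds <- function(u, d, props = fluid_props()) {
  if (any(!is.finite(u)) || any(u < 0)) stop("u must be >= 0 (use |Q| upstream)")
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be > 0")
  props$density * (u * 1e-3) * (d * 1e-3) / props$viscosity
}

#' Representative velocity from a flow waveform
#'
#' Peak-over-cycle area-averaged velocity `U = max_t |Q(t)| / A`, the
#' normalization used to report the maximum Reynolds number in a cardiac
#' cycle.
#'
#' @param wf a [flow_waveform()].
#' @param area cross-sectional area in mm^2 (> 0).
#' @return U in mm/s.
#' @export
representative_velocity <- function(wf, area) {
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  max(abs(wf$q)) / area
}

#' Equivalent diameter from cross-sectional areas
#'
#' Mean over sections of the circle-equivalent diameter `2*sqrt(A/pi)`.
#'
#' @param areas numeric vector of section areas in mm^2, all > 0.
#' @return diameter in mm.
#' @export
equivalent_diameter <- function(areas) {
  if (length(areas) == 0L) stop("need at least one section area")
  if (any(!is.finite(areas)) || any(areas <= 0)) stop("areas must be > 0")
  mean(2 * sqrt(areas / pi))
}

#' Cross-section consistency error and exclusion flag
#'
#' MRI-style plausibility check: flow rates measured at several aqueduct
#' cross-sections must agree (incompressibility). The error is
#' `max_t max_j |Q_j(t) - Qbar(t)| / max_t |Qbar(t)|` with `Qbar` the
#' across-section mean; normalizing by the peak of the mean series avoids
#' division by near-zero flow at flow-reversal phases. Cases with error
#' strictly above 25% are flagged for exclusion.
#'
#' @param q_sections matrix (phases x sections) of flow rates on a common
#'   phase grid, or a list of equal-length numeric vectors.
#' @param threshold exclusion threshold (strict inequality).
#' @return list with `error` (fraction) and `excluded` (logical).
#' @export
consistency_error <- function(q_sections, threshold = 0.25) {
  if (is.list(q_sections)) q_sections <- do.call(cbind, q_sections)
  q_sections <- as.matrix(q_sections)
  if (ncol(q_sections) < 2L) stop("need at least 2 sections")
  qbar <- rowMeans(q_sections)
  denom <- max(abs(qbar))
  err <- if (denom == 0) 0 else max(abs(q_sections - qbar)) / denom
  list(error = err, excluded = err > threshold)
}

#' MRI-style flow metrics for one subject
#'
#' Combines the flow descriptors into one record: equivalent diameter,
#' cross-sectional area, stroke volume, representative velocity, and the
#' maximum Reynolds number, plus the 4-section consistency flag when
#' section series are supplied.
#'
#' @param wf a [flow_waveform()] (aqueductal flow rate).
#' @param area aqueduct cross-sectional area in mm^2; alternatively give
#'   `areas` per section.
#' @param areas optional numeric vector of per-section areas (mm^2) used for
#'   the equivalent diameter; defaults to `area`.
#' @param q_sections optional phases x sections matrix for the consistency
#'   check.
#' @param props a [fluid_props()].
#' @return list of class `flow_metrics` with fields `d_mm`, `a_mm2`, `sv_ul`,
#'   `u_mm_s`, `re`, `consistency_error`, `excluded`.
#' @export
flow_metrics <- function(wf, area, areas = area, q_sections = NULL,
                         props = fluid_props()) {
  d <- equivalent_diameter(areas)
  sv <- stroke_volume(wf)
  u <- representative_velocity(wf, area)
  ce <- if (is.null(q_sections)) list(error = 0, excluded = FALSE)
        else consistency_error(q_sections)
  structure(list(d_mm = d, a_mm2 = area, sv_ul = sv, u_mm_s = u,
                 re = reynolds(u, d, props),
                 consistency_error = ce$error, excluded = ce$excluded),
            class = "flow_metrics")
}

#' @exportS3Method base::print
print.flow_metrics <- function(x, ...) {
  cat(sprintf("<flow_metrics> D = %.2f mm, A = %.3f mm^2, SV = %.2f ul, U = %.2f mm/s, Re = %.1f%s\n",
              x$d_mm, x$a_mm2, x$sv_ul, x$u_mm_s, x$re,
              if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}
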