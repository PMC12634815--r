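# Idealized ventricle-aqueduct geometries.
#
# Patient-specific segmentations are replaced by a parametric idealization:
# a smooth body of revolution about the craniocaudal z axis with three
# volume-matched chamber bulges (lateral and third ventricle proximally,
# fourth ventricle distally) connected by a straight circular aqueduct.
# The moving-wall forcing lives on the lateral-ventricle portion of the
# boundary; two outlet disks on the distal end cap stand in for the foramina
# of Luschka and Magendie.

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Geometry template parameters
#'
#' Tunable parameters of the idealized ventricle-aqueduct geometry. Chamber
#' volumes are the subject's MRI volumetrics scaled by `chamber_scale`
#' (desk-scale default 0.1: chambers reduced ~10x while the aqueduct stays at
#' true scale, preserving aqueduct Reynolds number and dynamics at a fraction
#' of the mesh size). Lengths are anatomically plausible defaults; none are
#' available from the summary volumetrics.
#'
#' @param chamber_scale multiplier applied to chamber volumes.
#' @param lv_length,v3_length,v4_length axial extents (mm) of the lateral,
#'   third and fourth ventricle segments. The fourth-ventricle segment is
#'   deliberately elongated so that the outlet disks sit farther from the
#'   aqueduct than the largest per-cycle tracer excursion (~10 mm at
#'   Re ~ 90); with a shorter distal chamber the freeze-at-exit rule censors
#'   exactly the fast-core trajectories that carry the Lagrangian drift, and
#'   the measured mixing is biased down at high stroke volumes.
#' @param outlet_radius_frac outlet-disk radius as a fraction of the distal
#'   cap radius.
#' @param outlet_offset_frac outlet-disk center offset from the axis as a
#'   fraction of the distal cap radius.
#' @return a named list.
#' @export
geometry_template <- function(chamber_scale = 0.1,
                              lv_length = 12, v3_length = 6, v4_length = 14,
                              outlet_radius_frac = 0.48,
                              outlet_offset_frac = 0.5) {
  list(chamber_scale = chamber_scale,
       lv_length = lv_length, v3_length = v3_length, v4_length = v4_length,
       outlet_radius_frac = outlet_radius_frac,
       outlet_offset_frac = outlet_offset_frac)
}

# integral of pi*R(z)^2 over [z0,z1] by composite Simpson
revolved_volume <- function(profile, z0, z1, n = 800L) {
  n <- if (n %% 2L == 1L) n + 1L else n
  z <- seq(z0, z1, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * pi * profile(z)^2) * (z1 - z0) / (3 * n)
}

# solve the bulge peak radius so the segment volume matches `target`
match_bulge_radius <- function(ra, len, bump, target) {
  seg_vol <- function(rk) {
    f <- function(z) ra + (rk - ra) * bump(z / len)
    revolved_volume(f, 0, len)
  }
  vmin <- seg_vol(ra)
  if (target <= vmin * (1 + 1e-9)) {
    stop(sprintf(paste("geometry error: chamber target volume %.1f mm^3 is not",
                       "larger than the aqueduct-radius baseline %.1f mm^3",
                       "(aqueduct as wide as the chamber)"), target, vmin))
  }
  upper <- ra + 1
  while (seg_vol(upper) < target && upper < 1e3) upper <- upper * 2
  stats::uniroot(function(rk) seg_vol(rk) - target,
                 c(ra, upper), tol = 1e-10)$root
}

#' Build an idealized ventricle-aqueduct geometry
#'
#' Constructs the parametric body-of-revolution geometry for one subject:
#' lateral-ventricle bulge (moving wall), third-ventricle bulge, straight
#' circular aqueduct of the subject's diameter, fourth-ventricle bulge with
#' two outlet disks on its distal cap. Each chamber's revolved volume is
#' matched to the (scaled) subject volumetrics to better than 0.1%.
#' Deterministic in its inputs.
#'
#' @param subject a list or one-row data frame with `d_mm`,
#'   `aqueduct_length_mm`, `lv_ml`, `v3_ml`, `v4_ml` (as produced by
#'   [generate_cohort()]); lateral and third ventricle volumes are combined
#'   with the template scale. Alternatively pass the fields directly.
#' @param template a [geometry_template()].
#' @return object of class `csf_geometry` with the radius profile `R(z)`,
#'   segment table, aqueduct extent, moving-wall extent and outlet-disk
#'   specification.
#' @examples
#' geo <- build_geometry(list(d_mm = 2.82, aqueduct_length_mm = 12,
#'                            lv_ml = 23.3, v3_ml = 1.1, v4_ml = 1.6))
#' pi * (geo$d / 2)^2  # aqueduct cross-section area, 6.246 mm^2
#' @export
build_geometry <- function(subject, template = geometry_template()) {
  if (is.data.frame(subject)) subject <- as.list(subject[1L, ])
  d <- subject$d_mm
  la <- if (!is.null(subject$aqueduct_length_mm)) subject$aqueduct_length_mm else 12
  if (!is.finite(d) || d <= 0) stop("geometry error: aqueduct diameter must be > 0")
  if (!is.finite(la) || la <= 0) stop("geometry error: aqueduct length must be > 0")
  ra <- d / 2
  sc <- template$chamber_scale * 1000  # ml -> mm^3, then desk scale
  targets <- c(lv = subject$lv_ml * sc, v3 = subject$v3_ml * sc,
               v4 = subject$v4_ml * sc)
  if (any(!is.finite(targets)) || any(targets <= 0)) {
    stop("geometry error: chamber volumes must be > 0")
  }
  lens <- c(lv = template$lv_length, v3 = template$v3_length,
            v4 = template$v4_length)
  bumps <- list(
    lv = function(u) smoothstep((1 - u) / 0.4),             # plateau, tapers to aqueduct
    v3 = function(u) smoothstep(u / 0.35) * smoothstep((1 - u) / 0.35),
    v4 = function(u) smoothstep(u / 0.45))                  # rises, plateau to end cap
  rpk <- vapply(c("lv", "v3", "v4"), function(k) {
    match_bulge_radius(ra, lens[[k]], bumps[[k]], targets[[k]])
  }, numeric(1))
  z0 <- c(lv = 0, v3 = lens[["lv"]], v4 = lens[["lv"]] + lens[["v3"]] + la)
  total_l <- lens[["lv"]] + lens[["v3"]] + la + lens[["v4"]]
  segs <- data.frame(name = c("lv", "v3", "aqueduct", "v4"),
                     z0 = c(z0[["lv"]], z0[["v3"]], z0[["v3"]] + lens[["v3"]],
                            z0[["v4"]]),
                     z1 = c(z0[["v3"]], z0[["v3"]] + lens[["v3"]], z0[["v4"]],
                            total_l),
                     r_peak = c(rpk[["lv"]], rpk[["v3"]], ra, rpk[["v4"]]),
                     stringsAsFactors = FALSE)
  profile <- function(z) {
    r <- rep(ra, length(z))
    for (k in c("lv", "v3", "v4")) {
      i <- which(z >= z0[[k]] - 1e-12 & z <= z0[[k]] + lens[[k]] + 1e-12)
      if (length(i)) {
        u <- (z[i] - z0[[k]]) / lens[[k]]
        r[i] <- r[i] + (rpk[[k]] - ra) * bumps[[k]](u)
      }
    }
    r
  }
  r_end <- profile(total_l)
  structure(list(kind = "ventricle", d = d, length = total_l,
                 profile = profile, segments = segs,
                 aqueduct_z = c(segs$z0[3L], segs$z1[3L]),
                 moving_z_max = lens[["lv"]],
                 outlet = list(type = "disks",
                               radius = template$outlet_radius_frac * r_end,
                               centers = rbind(
                                 c(template$outlet_offset_frac * r_end, 0),
                                 c(-template$outlet_offset_frac * r_end, 0))),
                 chamber_targets = targets),
            class = "csf_geometry")
}

#' Straight circular tube geometry (validation benchmark domain)
#'
#' A straight tube with a piston cap: the cap at `z = 0` carries the
#' moving-wall label (uniform normal-speed piston sourcing the flow), the
#' lateral surface is a rigid no-slip wall and the far cap is the pressure
#' outlet. Used for the Poiseuille and Womersley solver oracles.
#'
#' @param diameter tube diameter, mm.
#' @param length tube length, mm.
#' @return object of class `csf_geometry`.
#' @export
tube_geometry <- function(diameter = 2, length = 10) {
  if (!is.finite(diameter) || diameter <= 0) stop("geometry error: diameter must be > 0")
  ra <- diameter / 2
  structure(list(kind = "tube", d = diameter, length = length,
                 profile = function(z) rep(ra, length(z)),
                 segments = data.frame(name = "tube", z0 = 0, z1 = length,
                                       r_peak = ra, stringsAsFactors = FALSE),
                 aqueduct_z = c(0.2 * length, 0.8 * length),
                 moving_z_max = 0,
                 outlet = list(type = "full_cap")),
            class = "csf_geometry")
}

#' Analytic volume of a geometry between two axial stations
#'
#' @param geom a `csf_geometry`.
#' @param z0,z1 axial bounds (defaults: whole geometry).
#' @return volume in mm^3.
#' @export
geometry_volume <- function(geom, z0 = 0, z1 = geom$length) {
  revolved_volume(geom$profile, z0, z1, n = 4000L)
}

#' @exportS3Method base::print
print.csf_geometry <- function(x, ...) {
  cat(sprintf("<csf_geometry:%s> D = %.2f mm, L = %.1f mm, volume = %.1f mm^3\n",
              x$kind, x$d, x$length, geometry_volume(x)))
  invisible(x)
}
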