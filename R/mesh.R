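# Structured tetrahedral meshing of body-of-revolution geometries.
#
# Cross-sections are triangulated disks (concentric rings, 6k nodes on ring
# k) scaled by the local profile radius R(z) and extruded along z; each
# triangular prism is split into three tetrahedra with the minimum-vertex
# diagonal rule, which guarantees a conforming mesh. Resolution is tied to
# the aqueduct: the ring count guarantees at least 8 elements across the
# aqueduct diameter, refined further as base_size decreases.

# triangulated unit disk: rings at radii `radii` (increasing, last = 1),
# ring k carries 6k equally spaced nodes
disk_mesh <- function(radii) {
  nr <- length(radii)
  xs <- 0; ys <- 0
  ring_start <- integer(nr)  # index of first node of ring k (1-based)
  idx <- 1L
  for (k in seq_len(nr)) {
    m <- 6L * k
    th <- 2 * pi * (seq_len(m) - 1L) / m
    ring_start[k] <- idx + 1L
    xs <- c(xs, radii[k] * cos(th))
    ys <- c(ys, radii[k] * sin(th))
    idx <- idx + m
  }
  ring_ids <- function(k) if (k == 0L) 1L else ring_start[k] + 0:(6L * k - 1L)
  tris <- matrix(0L, 0L, 3L)
  # center fan
  r1 <- ring_ids(1L)
  tris <- rbind(tris, cbind(1L, r1, r1[c(2:6, 1)]))
  # annular zips
  for (k in seq_len(nr - 1L)) {
    inner <- ring_ids(k); outer <- ring_ids(k + 1L)
    m <- length(inner); M <- length(outer)
    tt <- matrix(0L, m + M, 3L)
    i <- 0L; j <- 0L; t <- 0L
    while (t < m + M) {
      t <- t + 1L
      adv_inner <- if (i >= m) FALSE
        else if (j >= M) TRUE
        else (i + 1) / m < (j + 1) / M - 1e-12
      if (adv_inner) {
        tt[t, ] <- c(inner[i %% m + 1L], inner[(i + 1L) %% m + 1L],
                     outer[j %% M + 1L])
        i <- i + 1L
      } else {
        tt[t, ] <- c(outer[j %% M + 1L], outer[(j + 1L) %% M + 1L],
                     inner[i %% m + 1L])
        j <- j + 1L
      }
    }
    tris <- rbind(tris, tt)
  }
  # enforce counterclockwise orientation
  ax <- xs[tris[, 2L]] - xs[tris[, 1L]]; ay <- ys[tris[, 2L]] - ys[tris[, 1L]]
  bx <- xs[tris[, 3L]] - xs[tris[, 1L]]; by <- ys[tris[, 3L]] - ys[tris[, 1L]]
  flip <- (ax * by - ay * bx) < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2]
  list(x = xs, y = ys, tris = tris)
}

# split wedge stack into tets with the minimum-vertex diagonal rule
# (diagonal of every quad face drawn from its smallest global node id,
# which makes adjacent wedges agree)
wedges_to_tets <- function(wedges) {
  a <- wedges[, 1L]; b <- wedges[, 2L]; c3 <- wedges[, 3L]
  rot1 <- b <= a & b <= c3       # min at position 2 -> rotate (b,c,a)
  rot2 <- c3 <= a & c3 <= b & !rot1
  v0 <- ifelse(rot1, b, ifelse(rot2, c3, a))
  v1 <- ifelse(rot1, c3, ifelse(rot2, a, b))
  v2 <- ifelse(rot1, a, ifelse(rot2, b, c3))
  off <- wedges[, 4L] - wedges[, 1L]  # constant per-layer node offset
  v3 <- v0 + off; v4 <- v1 + off; v5 <- v2 + off
  caseA <- v1 < v2
  t1 <- cbind(v0, v1, v2, ifelse(caseA, v5, v4))
  t2 <- cbind(v0, ifelse(caseA, v1, v4), ifelse(caseA, v5, v2),
              ifelse(caseA, v4, v5))
  t3 <- cbind(v0, v4, v5, v3)
  rbind(t1, t2, t3)
}

tet_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  (e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
   e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
   e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])) / 6
}

# boundary faces (occurring once over all tets) with their outward order
boundary_faces <- function(nodes, tets) {
  n <- nrow(nodes)
  faceloc <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  faces <- do.call(rbind, lapply(1:4, function(k) tets[, faceloc[k, ]]))
  s1 <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  s3 <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  s2 <- faces[, 1L] + faces[, 2L] + faces[, 3L] - s1 - s3
  key <- (as.numeric(s1) * (n + 1) + s2) * (n + 1) + s3
  idx <- match(key, unique(key))
  cnt <- tabulate(idx)
  faces[cnt[idx] == 1L, , drop = FALSE]
}

facet_geometry <- function(nodes, tris) {
  p1 <- nodes[tris[, 1L], , drop = FALSE]
  e1 <- nodes[tris[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tris[, 3L], , drop = FALSE] - p1
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  area2 <- sqrt(nx^2 + ny^2 + nz^2)
  centroid <- (p1 + nodes[tris[, 2L], , drop = FALSE] +
               nodes[tris[, 3L], , drop = FALSE]) / 3
  list(area = area2 / 2,
       normal = cbind(nx, ny, nz) / area2,
       centroid = centroid)
}

#' Mesh an idealized geometry with labeled first-order tetrahedra
#'
#' Structured extrusion of a triangulated disk along the geometry axis; node
#' rings are scaled by the local profile radius so the mesh conforms exactly
#' to the body of revolution. Boundary triangles are each labeled exactly one
#' of `moving_wall`, `rigid_wall`, `outlet`. The ring count guarantees at
#' least 8 elements across the aqueduct diameter and increases as
#' `base_size` shrinks, so the mesh-independency protocol (1.4 / 0.7 /
#' 0.35 mm base sizes) refines both radially and axially.
#'
#' @param geom a `csf_geometry` from [build_geometry()] or [tube_geometry()].
#' @param base_size target element size in mm (> 0); axial spacing equals
#'   `base_size` and the aqueduct radial spacing is about `base_size`
#'   (capped at D/4).
#' @param n_layers optional count of graded near-wall rings (boundary-layer
#'   analogue of prism layers; default 0 at desk scale, near-wall resolution
#'   being enforced through `base_size` instead).
#' @return object of class `csf_mesh`: `nodes` (n x 3, mm), `tets`
#'   (ne x 4), `tris` (boundary triangles), `labels` (per-triangle), plus
#'   geometry metadata.
#' @export
mesh_geometry <- function(geom, base_size = 0.7, n_layers = 0L) {
  stopifnot(inherits(geom, "csf_geometry"))
  if (!is.finite(base_size) || base_size <= 0) stop("base_size must be > 0")
  ra <- geom$d / 2
  n_r <- max(2L, as.integer(ceiling(ra / min(base_size, geom$d / 4))) + 2L)
  radii <- seq_len(n_r) / n_r
  if (n_layers > 0L) {
    # subdivide the outermost interval into geometrically shrinking rings
    # (near-wall refinement analogous to prism boundary layers)
    w <- 0.6^(0:(n_layers))
    incr <- w / sum(w) / n_r
    radii <- c(utils::head(radii, -1L), (n_r - 1L) / n_r + cumsum(incr))
    radii[length(radii)] <- 1
  }
  disk <- disk_mesh(radii)
  npl <- length(disk$x)                      # nodes per layer
  nz <- max(4L, as.integer(ceiling(geom$length / base_size)))
  zs <- seq(0, geom$length, length.out = nz + 1L)
  if (geom$kind == "ventricle") {
    # halve the axial spacing over the distal cap region: the outflow jets
    # through the foramina carry the steepest gradients in the domain
    dz <- zs[2L] - zs[1L]
    zref <- zs[zs > geom$length - 2 * dz - 1e-9]
    extra <- utils::head(zref, -1L) + dz / 2
    zs <- sort(unique(c(zs, extra)))
  }
  nz <- length(zs) - 1L
  rz <- geom$profile(zs)
  nodes <- cbind(rep(disk$x, nz + 1L) * rep(rz, each = npl),
                 rep(disk$y, nz + 1L) * rep(rz, each = npl),
                 rep(zs, each = npl))
  ntri <- nrow(disk$tris)
  wedges <- do.call(rbind, lapply(seq_len(nz), function(l) {
    lower <- disk$tris + (l - 1L) * npl
    cbind(lower, lower + npl)
  }))
  tets <- wedges_to_tets(wedges)
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {
    tets[neg, 3:4] <- tets[neg, c(4L, 3L)]
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0)) stop("meshing error: degenerate elements produced")
  tris <- boundary_faces(nodes, tets)
  fg <- facet_geometry(nodes, tris)
  labels <- label_boundary(geom, fg$centroid, eps = min(diff(zs)) / 10)
  m <- structure(list(nodes = nodes, tets = tets, tris = tris,
                      labels = labels, base_size = base_size,
                      d = geom$d, aqueduct_z = geom$aqueduct_z,
                      length = geom$length, kind = geom$kind,
                      cache = new.env(parent = emptyenv())),
                 class = "csf_mesh")
  m
}

label_boundary <- function(geom, centroid, eps) {
  z <- centroid[, 3L]
  lab <- rep("rigid_wall", length(z))
  if (geom$kind == "tube") {
    lab[z < eps] <- "moving_wall"
    lab[z > geom$length - eps] <- "outlet"
    return(lab)
  }
  lab[z < geom$moving_z_max - eps] <- "moving_wall"   # LV cap + lateral wall
  on_cap <- z > geom$length - eps
  if (geom$outlet$type == "full_cap") {
    lab[on_cap] <- "outlet"
  } else {
    for (k in seq_len(nrow(geom$outlet$centers))) {
      ctr <- geom$outlet$centers[k, ]
      inside <- on_cap & sqrt((centroid[, 1L] - ctr[1L])^2 +
                              (centroid[, 2L] - ctr[2L])^2) < geom$outlet$radius
      if (!any(inside)) {
        # guarantee at least one outlet facet per foramen disk
        dd <- ifelse(on_cap, (centroid[, 1L] - ctr[1L])^2 +
                             (centroid[, 2L] - ctr[2L])^2, Inf)
        inside <- seq_along(z) == which.min(dd)
      }
      lab[inside] <- "outlet"
    }
  }
  lab
}

#' Mesh quality report
#'
#' Element volumes, aspect ratios (longest edge over `2*sqrt(6)` times the
#' inradius, 1 for a regular tetrahedron), inverted-element count, and
#' boundary label areas.
#'
#' @param mesh a `csf_mesh`.
#' @return list with `volume` (min/mean/total), `aspect` (summary vector),
#'   `n_inverted`, `label_areas` (mm^2), `n_nodes`, `n_tets`.
#' @export
mesh_quality <- function(mesh) {
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  p <- lapply(1:4, function(k) mesh$nodes[mesh$tets[, k], , drop = FALSE])
  pairs <- utils::combn(4L, 2L)
  elen <- vapply(seq_len(ncol(pairs)), function(j) {
    d <- p[[pairs[1L, j]]] - p[[pairs[2L, j]]]
    sqrt(rowSums(d * d))
  }, numeric(nrow(mesh$tets)))
  lmax <- apply(matrix(elen, nrow = nrow(mesh$tets)), 1L, max)
  # total face area per tet for the inradius r = 3V / sum(A_f)
  faceloc <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  atot <- 0
  for (k in 1:4) {
    f <- mesh$tets[, faceloc[k, ], drop = FALSE]
    atot <- atot + facet_geometry(mesh$nodes, f)$area
  }
  rin <- 3 * abs(vol) / atot
  aspect <- lmax / (2 * sqrt(6) * rin)
  fg <- facet_geometry(mesh$nodes, mesh$tris)
  la <- tapply(fg$area, mesh$labels, sum)
  list(volume = c(min = min(vol), mean = mean(vol), total = sum(vol)),
       aspect = summary(aspect),
       n_inverted = sum(vol <= 0),
       label_areas = la,
       boundary_area = sum(fg$area),
       n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets))
}

#' @exportS3Method base::print
print.csf_mesh <- function(x, ...) {
  cat(sprintf("<csf_mesh:%s> %d nodes, %d tets, %d boundary tris (base %.2f mm)\n",
              x$kind, nrow(x$nodes), nrow(x$tets), nrow(x$tris), x$base_size))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

#' Structured tetrahedral mesh of an axis-aligned box
#'
#' Kuhn subdivision (six tetrahedra per cube cell), conforming across cells.
#' Useful as a simple reference domain for tracking and mixing checks. All
#' boundary facets are labeled `rigid_wall` except, optionally, the
#' `x = lx` face as `outlet` and the `x = 0` face as `moving_wall`.
#'
#' @param lx,ly,lz box edge lengths (mm).
#' @param h target cell size (mm).
#' @param labeled if `TRUE`, label the two x faces moving_wall/outlet.
#' @return a `csf_mesh`.
#' @export
box_mesh <- function(lx = 1, ly = 1, lz = 1, h = 0.25, labeled = FALSE) {
  nx <- max(1L, round(lx / h)); ny <- max(1L, round(ly / h))
  nzc <- max(1L, round(lz / h))
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nzc + 1L)
  nid <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nzc - 1L))
  # Kuhn: six tets along the main diagonal, one per permutation of steps
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  steps <- diag(3L)
  tets <- do.call(rbind, lapply(perms, function(pm) {
    p0 <- cbind(cells$i, cells$j, cells$k)
    p1 <- p0 + matrix(steps[pm[1L], ], nrow(p0), 3L, byrow = TRUE)
    p2 <- p1 + matrix(steps[pm[2L], ], nrow(p0), 3L, byrow = TRUE)
    p3 <- p2 + matrix(steps[pm[3L], ], nrow(p0), 3L, byrow = TRUE)
    cbind(nid(p0[, 1L], p0[, 2L], p0[, 3L]), nid(p1[, 1L], p1[, 2L], p1[, 3L]),
          nid(p2[, 1L], p2[, 2L], p2[, 3L]), nid(p3[, 1L], p3[, 2L], p3[, 3L]))
  }))
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, 3:4] <- tets[neg, c(4L, 3L)]
  tris <- boundary_faces(nodes, tets)
  fg <- facet_geometry(nodes, tris)
  labels <- rep("rigid_wall", nrow(tris))
  if (labeled) {
    eps <- min(lx, ly, lz) * 1e-9
    labels[fg$centroid[, 1L] > lx - eps] <- "outlet"
    labels[fg$centroid[, 1L] < eps] <- "moving_wall"
  }
  structure(list(nodes = nodes, tets = tets, tris = tris, labels = labels,
                 base_size = h, d = min(ly, lz),
                 aqueduct_z = c(0, lz), length = lz, kind = "box",
                 cache = new.env(parent = emptyenv())),
            class = "csf_mesh")
}
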