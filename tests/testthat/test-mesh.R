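test_that("meshes are valid and labels partition the boundary", {
  mesh <- ventricle_fixture()
  q <- mesh_quality(mesh)
  expect_gt(q$volume[["min"]], 0)
  expect_equal(q$n_inverted, 0L)
  expect_setequal(unique(mesh$labels), c("moving_wall", "rigid_wall", "outlet"))
  expect_equal(sum(q$label_areas), q$boundary_area, tolerance = 1e-9)
  expect_gt(q$label_areas[["moving_wall"]], 0)
})

test_that("there are exactly two outlet openings", {
  mesh <- ventricle_fixture()
  out <- mesh$tris[mesh$labels == "outlet", , drop = FALSE]
  # connected components over shared nodes
  comp <- seq_len(nrow(out))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(out))) {
      nb <- which(apply(out, 1L, function(f) length(intersect(f, out[i, ])) >= 2L))
      newc <- min(comp[nb], comp[i])
      if (any(comp[c(i, nb)] != newc)) {
        comp[c(i, nb)] <- newc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(length(unique(comp)), 2L)
})

test_that("coarser base size gives strictly fewer elements", {
  geo <- build_geometry(default_subject())
  n14 <- nrow(mesh_geometry(geo, 1.4)$tets)
  n07 <- nrow(mesh_geometry(geo, 0.7)$tets)
  expect_lt(n14, n07)
})

test_that("meshed volume converges monotonically to the analytic volume", {
  geo <- build_geometry(default_subject())
  va <- geometry_volume(geo)
  errs <- sapply(c(1.4, 0.9, 0.6), function(b) {
    m <- mesh_geometry(geo, b)
    abs(sum(csfmix:::tet_volumes(m$nodes, m$tets)) - va) / va
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("outlet flow area of a meshed unit cylinder approaches pi/4", {
  mesh <- mesh_geometry(tube_geometry(diameter = 1, length = 1), 0.25)
  q <- mesh_quality(mesh)
  expect_lt(abs(q$label_areas[["outlet"]] - pi / 4) / (pi / 4), 0.05)
})

test_that("at least 8 elements span the aqueduct diameter", {
  mesh <- ventricle_fixture()
  zmid <- mean(mesh$aqueduct_z)
  sl <- abs(mesh$nodes[, 3L] - zmid) < 1.0
  xs <- mesh$nodes[sl & abs(mesh$nodes[, 2L]) < 1e-9, 1L]
  expect_gte(length(unique(round(xs, 6))), 9L)  # >= 9 nodes across
})

test_that("mesh quality flags inverted elements", {
  mesh <- ventricle_fixture()
  bad <- mesh
  bad$tets <- mesh$tets
  bad$tets[1L, c(3L, 4L)] <- bad$tets[1L, c(4L, 3L)]
  q <- mesh_quality(bad)
  expect_gte(q$n_inverted, 1L)
})

test_that("the aspect-ratio metric is 1 for a regular tetrahedron", {
  s <- 1 / sqrt(2)
  nodes <- rbind(c(1, 0, -s), c(-1, 0, -s), c(0, 1, s), c(0, -1, s))
  m <- structure(list(nodes = nodes, tets = matrix(1:4, 1L),
                      tris = csfmix:::boundary_faces(nodes, matrix(1:4, 1L)),
                      labels = rep("rigid_wall", 4L),
                      cache = new.env(parent = emptyenv())),
                 class = "csf_mesh")
  q <- mesh_quality(m)
  expect_equal(unname(q$aspect[["Min."]]), 1, tolerance = 1e-9)
})

test_that("optional near-wall layers refine the outer rings", {
  geo <- tube_geometry(2, 4)
  m0 <- mesh_geometry(geo, 0.4)
  m3 <- mesh_geometry(geo, 0.4, n_layers = 3L)
  expect_gt(nrow(m3$nodes), nrow(m0$nodes))
  # outermost radial spacing shrinks
  rr0 <- sort(unique(round(sqrt(m0$nodes[, 1]^2 + m0$nodes[, 2]^2), 8)))
  rr3 <- sort(unique(round(sqrt(m3$nodes[, 1]^2 + m3$nodes[, 2]^2), 8)))
  expect_lt(diff(rev(rr3))[1] * -1, diff(rev(rr0))[1] * -1)
})

test_that("MSH round-trip preserves nodes, elements and labels", {
  mesh <- tube_fixture(0.5, 2, 4)
  f <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, f)
  back <- read_mesh_msh(f)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-9)
  expect_equal(nrow(back$tets), nrow(mesh$tets))
  expect_equal(sort(table(back$labels)), sort(table(mesh$labels)))
  unlink(f)
})

test_that("VTU export writes a well-formed XML file", {
  mesh <- tube_fixture(0.5, 2, 4)
  f <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f, point_data = list(z = mesh$nodes[, 3L]))
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  unlink(f)
})
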