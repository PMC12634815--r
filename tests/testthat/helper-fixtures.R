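# Shared fixtures, built once per test run.

default_subject <- function() {
  list(d_mm = 2.82, aqueduct_length_mm = 12,
       lv_ml = 23.3, v3_ml = 1.1, v4_ml = 1.6)
}

# small tube mesh reused by solver tests
fixture_env <- new.env()

tube_fixture <- function(base = 0.35, diameter = 2, length = 8) {
  key <- sprintf("tube_%g_%g_%g", base, diameter, length)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- mesh_geometry(tube_geometry(diameter, length), base)
  }
  fixture_env[[key]]
}

ventricle_fixture <- function(base = 0.9) {
  key <- sprintf("vent_%g", base)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- mesh_geometry(build_geometry(default_subject()), base)
  }
  fixture_env[[key]]
}

# a synthetic periodic velocity field from nodal values: ufun(x, y, z) -> n x 3
synthetic_field <- function(mesh, ufun, period = 1, phases = 4L) {
  n <- nrow(mesh$nodes)
  u1 <- ufun(mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L])
  u <- array(0, c(n, 3L, phases))
  for (p in seq_len(phases)) u[, , p] <- u1
  structure(list(mesh = mesh, u = u,
                 times = period * (seq_len(phases) - 1L) / phases,
                 period = period),
            class = "velocity_field")
}

# particle set with hand-chosen origins/finals (for mixing arithmetic)
manual_particles <- function(origin, pos, status = integer(nrow(pos))) {
  structure(list(pos = pos, origin = origin, status = status,
                 hint = integer(nrow(pos)), spacing = NA_real_),
            class = "particle_set")
}
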