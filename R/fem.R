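# P1 tetrahedral finite-element operators, assembled once per mesh.
#
# All solver algebra runs in mm / s units with kinematic pressure
# (p/rho, mm^2/s^2); with water-like CSF properties the kinematic viscosity
# is 1 mm^2/s, which keeps the numbers well scaled.

fem_prepare <- function(mesh) {
  if (!is.null(mesh$cache$fem)) return(mesh$cache$fem)
  nodes <- mesh$nodes
  tets <- mesh$tets
  n <- nrow(nodes)
  ne <- nrow(tets)
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  c23 <- cr(e2, e3)
  det <- rowSums(e1 * c23)             # 6V, positive by construction
  vol <- det / 6
  grads <- vector("list", 4L)          # gradient of basis k, ne x 3
  grads[[2L]] <- c23 / det
  grads[[3L]] <- cr(e3, e1) / det
  grads[[4L]] <- cr(e1, e2) / det
  grads[[1L]] <- -(grads[[2L]] + grads[[3L]] + grads[[4L]])
  # sparse operators
  ii <- jj <- integer(16L * ne)
  kx <- mx <- numeric(16L * ne)
  dx <- matrix(0, 16L * ne, 3L)
  pos <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- pos + seq_len(ne)
    ii[idx] <- tets[, i]
    jj[idx] <- tets[, j]
    kx[idx] <- vol * rowSums(grads[[i]] * grads[[j]])
    mx[idx] <- vol / (if (i == j) 10 else 20)
    dx[idx, ] <- (vol / 4) * grads[[j]]   # int phi_i d(phi_j)/dx_d
    pos <- pos + ne
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kx, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mx, dims = c(n, n))
  D <- lapply(1:3, function(d) {
    Matrix::sparseMatrix(i = ii, j = jj, x = dx[, d], dims = c(n, n))
  })
  ml <- as.numeric(M %*% rep(1, n))     # lumped mass
  # scatter plan: per-local-node accumulation into global nodes
  idx_all <- as.vector(tets)            # 4*ne
  ord <- order(idx_all)
  sorted <- idx_all[ord]
  ends <- which(diff(c(sorted, n + 1L)) > 0L)
  target <- sorted[ends]
  # element sizes
  hmin_edges <- pmin(
    sqrt(rowSums(e1^2)), sqrt(rowSums(e2^2)), sqrt(rowSums(e3^2)),
    sqrt(rowSums((e1 - e2)^2)), sqrt(rowSums((e1 - e3)^2)),
    sqrt(rowSums((e2 - e3)^2)))
  h_supg <- (6 * sqrt(2) * vol)^(1 / 3)  # regular-tet equivalent edge
  fem <- list(n = n, ne = ne, tets = tets, vol = vol, grads = grads,
              K = K, M = M, D = D, ml = ml,
              scatter = list(ord = ord, ends = ends, target = target),
              hmin = min(hmin_edges), h_supg = h_supg)
  mesh$cache$fem <- fem
  fem
}

# scatter-add: vals has one value per (element, local node) in tets order
scatter_add <- function(fem, vals) {
  out <- numeric(fem$n)
  cs <- cumsum(vals[fem$scatter$ord])
  out[fem$scatter$target] <- diff(c(0, cs[fem$scatter$ends]))
  out
}

# Explicit SUPG-stabilized advection residual: for each velocity component d
#   r_i,d = int phi_i (util . grad u_d) + tau int (util . grad phi_i)(util . grad u_d)
advection_term <- function(fem, u, util, dt, nu) {
  tets <- fem$tets
  ne <- fem$ne
  ut <- lapply(1:4, function(k) util[tets[, k], , drop = FALSE])
  gu <- lapply(1:3, function(d) {
    g <- fem$grads[[1L]] * u[tets[, 1L], d]
    for (k in 2:4) g <- g + fem$grads[[k]] * u[tets[, k], d]
    g   # ne x 3, gradient of component d (constant per element)
  })
  # c[k][d]: util.grad(u_d) evaluated at local node k
  cc <- lapply(1:4, function(k) {
    sapply(1:3, function(d) rowSums(ut[[k]] * gu[[d]])) # ne x 3
  })
  csum <- cc[[1L]] + cc[[2L]] + cc[[3L]] + cc[[4L]]
  # a[i][k]: util.grad(phi_i) at local node k
  aa <- lapply(1:4, function(i) {
    lapply(1:4, function(k) rowSums(ut[[k]] * fem$grads[[i]]))
  })
  ubar <- (ut[[1L]] + ut[[2L]] + ut[[3L]] + ut[[4L]]) / 4
  umag <- sqrt(rowSums(ubar^2))
  h <- fem$h_supg
  tau <- 1 / sqrt((2 / dt)^2 + (2 * umag / h)^2 + (12 * nu / h^2)^2)
  w <- fem$vol / 20
  vals <- matrix(0, 4L * ne, 3L)
  for (i in 1:4) {
    ai_sum <- aa[[i]][[1L]] + aa[[i]][[2L]] + aa[[i]][[3L]] + aa[[i]][[4L]]
    supg <- aa[[i]][[1L]] * cc[[1L]] + aa[[i]][[2L]] * cc[[2L]] +
            aa[[i]][[3L]] * cc[[3L]] + aa[[i]][[4L]] * cc[[4L]]
    vals[(i - 1L) * ne + seq_len(ne), ] <-
      w * (csum + cc[[i]]) + (tau * w) * (ai_sum * csum + supg)
  }
  cbind(scatter_add(fem, vals[, 1L]),
        scatter_add(fem, vals[, 2L]),
        scatter_add(fem, vals[, 3L]))
}
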