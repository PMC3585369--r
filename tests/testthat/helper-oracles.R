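# Independent finite-volume Laplace solver on an axisymmetric spherical
# grid, used as the numerical oracle for the analytic series solvers.
#
# Solves div(sigma grad phi) = 0 in spherical coordinates (r, theta) with
# azimuthal symmetry, with point current sources either on the outer
# boundary (scalp stimulation) or in interior cells (dipole as a +/- pair),
# and an insulating exterior. Cell-centred finite volumes; conductances use
# harmonic averaging across shell interfaces. Returns cell centres and the
# potential (zero-mean over the grid).
fv_laplace_axisym <- function(radii, sigmas, n_r = 60, n_th = 96,
                              boundary_sources = NULL,
                              interior_sources = NULL) {
  R <- radii[length(radii)]
  re <- seq(0, R, length.out = n_r + 1)       # radial cell edges
  te <- seq(0, pi, length.out = n_th + 1)     # polar cell edges
  rc <- (re[-1] + re[-(n_r + 1)]) / 2
  tc <- (te[-1] + te[-(n_th + 1)]) / 2
  sig_of <- function(r) sigmas[findInterval(r, radii, left.open = TRUE) + 1]
  idx <- function(i, j) (j - 1L) * n_r + i
  n <- n_r * n_th
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n)
  add <- function(a, b, g) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, g)
  }
  # radial faces between (i, j) and (i+1, j)
  for (i in seq_len(n_r - 1)) {
    rf <- re[i + 1]
    # harmonic mean of sigma along the two half-links
    d1 <- rf - rc[i]; d2 <- rc[i + 1] - rf
    s1 <- sig_of(rc[i]); s2 <- sig_of(rc[i + 1])
    for (j in seq_len(n_th)) {
      area <- 2 * pi * rf^2 * (cos(te[j]) - cos(te[j + 1]))
      g <- area / (d1 / s1 + d2 / s2)
      a <- idx(i, j); b <- idx(i + 1, j)
      add(a, b, g); add(b, a, g)
      diag_acc[a] <- diag_acc[a] + g
      diag_acc[b] <- diag_acc[b] + g
    }
  }
  # polar faces between (i, j) and (i, j+1)
  for (j in seq_len(n_th - 1)) {
    tf <- te[j + 1]
    for (i in seq_len(n_r)) {
      dr <- re[i + 1] - re[i]
      area <- 2 * pi * rc[i] * sin(tf) * dr
      arc <- rc[i] * (tc[j + 1] - tc[j])
      g <- sig_of(rc[i]) * area / arc
      a <- idx(i, j); b <- idx(i, j + 1)
      add(a, b, g); add(b, a, g)
      diag_acc[a] <- diag_acc[a] + g
      diag_acc[b] <- diag_acc[b] + g
    }
  }
  rhs <- numeric(n)
  # boundary sources: data.frame(theta, I) injected through the outer face
  if (!is.null(boundary_sources)) {
    for (k in seq_len(nrow(boundary_sources))) {
      j <- findInterval(boundary_sources$theta[k], te,
                        rightmost.closed = TRUE)
      j <- min(max(j, 1L), n_th)
      rhs[idx(n_r, j)] <- rhs[idx(n_r, j)] + boundary_sources$I[k]
    }
  }
  # interior sources: data.frame(r, theta, I) placed in the containing cell
  if (!is.null(interior_sources)) {
    for (k in seq_len(nrow(interior_sources))) {
      i <- min(max(findInterval(interior_sources$r[k], re), 1L), n_r)
      j <- min(max(findInterval(interior_sources$theta[k], te), 1L), n_th)
      rhs[idx(i, j)] <- rhs[idx(i, j)] + interior_sources$I[k]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(-vv, diag_acc), dims = c(n, n))
  # pin one cell to fix the additive constant
  A[1, ] <- 0; A[1, 1] <- 1; rhs[1] <- 0
  phi <- as.numeric(Matrix::solve(A, rhs))
  phi <- phi - mean(phi)
  list(r = rc, theta = tc, phi = matrix(phi, n_r, n_th),
       lookup = function(r, theta) {
    i <- min(max(findInterval(r, re), 1L), n_r)
    j <- min(max(findInterval(theta, te), 1L), n_th)
    matrix(phi, n_r, n_th)[i, j]
  })
}

# shared small geometry fixtures, built once per test run
fixture_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cortical_mesh(3, 0.079, 0, seed = 1)
    cache
  }
})

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
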