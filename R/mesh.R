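#' Triangulated cortical source surface
#'
#' A `cortical_mesh` is a closed triangulated surface standing in for the
#' white/grey-matter interface: `vertices` (V x 3, metres), `triangles`
#' (F x 3, 1-based vertex indices with outward winding), plus per-triangle
#' `barycenters`, unit outward `normals` and `areas`. EEG sources and
#' stimulation-field samples live at the barycenters.
#'
#' @name cortical_mesh
NULL

new_cortical_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  bary <- (v1 + v2 + v3) / 3
  cr <- cross3(v2 - v1, v3 - v1)
  a2 <- sqrt(rowSums(cr^2))
  if (any(a2 <= 0)) stop("invalid geometry: degenerate triangle (zero area)")
  normals <- cr / a2
  # consistent outward winding is required; star-shaped meshes built here
  # always satisfy it, imported meshes are checked by the caller
  structure(list(vertices = vertices, triangles = triangles,
                 barycenters = bary, normals = normals, areas = a2 / 2),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %d vertices, %d triangles, area %.5f m^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Unit icosahedron with outward-wound faces.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  edge_key <- function(i, j) ifelse(i < j, i * (nv + 1L) + j, j * (nv + 1L) + i)
  e1 <- edge_key(faces[, 1], faces[, 2])
  e2 <- edge_key(faces[, 2], faces[, 3])
  e3 <- edge_key(faces[, 3], faces[, 1])
  keys <- c(e1, e2, e3)
  ukeys <- unique(keys)
  mid_idx <- nv + match(keys, ukeys)
  # midpoint coordinates for unique edges
  first <- match(ukeys, keys)
  ia <- c(faces[, 1], faces[, 2], faces[, 3])[first]
  ib <- c(faces[, 2], faces[, 3], faces[, 1])[first]
  mids <- (vertices[ia, , drop = FALSE] + vertices[ib, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  vnew <- rbind(vertices, mids)
  nf <- nrow(faces)
  m1 <- mid_idx[seq_len(nf)]
  m2 <- mid_idx[nf + seq_len(nf)]
  m3 <- mid_idx[2L * nf + seq_len(nf)]
  fnew <- rbind(cbind(faces[, 1], m1, m3),
                cbind(faces[, 2], m2, m1),
                cbind(faces[, 3], m3, m2),
                cbind(m1, m2, m3))
  list(vertices = vnew, faces = fnew)
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Smooth random radial bump field on the unit sphere, max |value| = 1.
bump_field <- function(dirs, seed, n_bumps = 12L, width = 0.6) {
  rs <- with_seed(seed, {
    centers <- matrix(stats::rnorm(n_bumps * 3L), ncol = 3L)
    centers <- centers / sqrt(rowSums(centers^2))
    list(centers = centers, w = stats::rnorm(n_bumps))
  })
  g <- numeric(nrow(dirs))
  for (k in seq_len(nrow(rs$centers))) {
    ang <- acos(pmin(1, pmax(-1, dirs %*% rs$centers[k, ])))
    g <- g + rs$w[k] * exp(-(ang / width)^2)
  }
  m <- max(abs(g))
  if (m > 0) g <- g / m
  g
}

#' Generate a spherical cortical source mesh
#'
#' Builds a closed triangulated sphere by recursive subdivision of an
#' icosahedron (`20 * 4^subdivision_level` triangles), optionally radially
#' perturbed by a smooth seeded bump field so that triangle normals are not
#' all exactly radial — a stand-in for the folded cortical surface.
#'
#' @param subdivision_level integer >= 1, number of 1-to-4 subdivision steps.
#' @param cortical_radius sphere radius in metres (default 0.079).
#' @param perturbation_amplitude maximal radial displacement in metres;
#'   must satisfy `0 <= perturbation_amplitude < 0.2 * cortical_radius`.
#' @param seed integer seed for the bump field (ignored when the amplitude
#'   is zero).
#' @return A [cortical_mesh].
#' @examples
#' m <- generate_cortical_mesh(2, 0.079, 0, seed = 1)
#' nrow(m$triangles)  # 320
#' @export
generate_cortical_mesh <- function(subdivision_level, cortical_radius = 0.079,
                                   perturbation_amplitude = 0, seed = 1L) {
  if (!is.finite(cortical_radius) || cortical_radius <= 0) {
    stop("invalid geometry: cortical_radius must be positive")
  }
  subdivision_level <- as.integer(subdivision_level)
  if (subdivision_level < 1L) stop("subdivision_level must be >= 1")
  if (perturbation_amplitude < 0 ||
      perturbation_amplitude >= 0.2 * cortical_radius) {
    stop("perturbation_amplitude must be in [0, 0.2 * cortical_radius)")
  }
  ico <- icosahedron()
  for (i in seq_len(subdivision_level)) {
    ico <- subdivide_once(ico$vertices, ico$faces)
  }
  dirs <- ico$vertices
  r <- rep(cortical_radius, nrow(dirs))
  if (perturbation_amplitude > 0) {
    r <- r + perturbation_amplitude * bump_field(dirs, seed)
  }
  new_cortical_mesh(dirs * r, ico$faces)
}

mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Closed-surface checks
#'
#' `mesh_is_closed()` verifies that every edge is shared by exactly two
#' triangles; `mesh_euler_characteristic()` returns V - E + F (2 for a
#' closed genus-0 surface); `mesh_signed_volume()` returns the signed
#' enclosed volume (positive for outward winding).
#'
#' @param mesh a [cortical_mesh].
#' @return Logical, integer and numeric scalar respectively.
#' @export
mesh_is_closed <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname mesh_is_closed
#' @export
mesh_euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  n_e <- length(unique(paste(e[, 1], e[, 2])))
  nrow(mesh$vertices) - n_e + nrow(mesh$triangles)
}

#' @rdname mesh_is_closed
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(v1 * cross3(v2, v3))) / 6
}

# Triangle adjacency over shared edges, as a list of integer neighbour sets.
triangle_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  tri <- rep(seq_len(nrow(mesh$triangles)), 3L)
  sp <- split(tri, key)
  adj <- vector("list", nrow(mesh$triangles))
  for (p in sp) {
    if (length(p) == 2L) {
      adj[[p[1]]] <- c(adj[[p[1]]], p[2])
      adj[[p[2]]] <- c(adj[[p[2]]], p[1])
    }
  }
  adj
}
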