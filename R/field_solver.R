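#' Stimulation configuration
#'
#' Describes a two-pad transcranial stimulation montage: anode and cathode
#' electrode labels (pad centers), injected current, pad footprint and the
#' number of point sources used to discretize each pad on the scalp sphere.
#'
#' @param anode,cathode electrode labels (must differ).
#' @param current injected current in amperes (default 1.12 mA).
#' @param pad_width,pad_height pad footprint in metres (default 7 x 5 cm).
#' @param sources_per_pad number of point sources per pad (default 35,
#'   a 7 x 5 grid).
#' @return An object of class `stimulation_config`.
#' @export
stimulation_config <- function(anode = "PO9", cathode = "PO10",
                               current = 1.12e-3, pad_width = 0.07,
                               pad_height = 0.05, sources_per_pad = 35L) {
  if (!is.finite(current) || current <= 0) stop("current must be positive")
  if (pad_width <= 0 || pad_height <= 0) stop("pad dimensions must be positive")
  if (identical(anode, cathode)) stop("anode and cathode must differ")
  sources_per_pad <- as.integer(sources_per_pad)
  if (sources_per_pad < 1L) stop("sources_per_pad must be >= 1")
  structure(list(anode = anode, cathode = cathode, current = current,
                 pad_width = pad_width, pad_height = pad_height,
                 sources_per_pad = sources_per_pad),
            class = "stimulation_config")
}

#' Discretize stimulation pads into scalp point sources
#'
#' Each rectangular pad is represented by a grid of point current sources
#' covering its footprint, laid out in the tangent plane at the pad-center
#' electrode and projected radially onto the scalp sphere. Anode points carry
#' `+current/sources_per_pad` each, cathode points the negative, so the total
#' injected current is conserved exactly.
#'
#' @param config a [stimulation_config].
#' @param layout an `electrode_layout` containing the anode/cathode labels.
#' @param scalp_radius scalp sphere radius in metres.
#' @return An object of class `point_source_set`: `positions` (n x 3, on the
#'   scalp sphere) and `currents` (A, summing to zero).
#' @export
pad_sources <- function(config, layout, scalp_radius = 0.092) {
  pad_one <- function(label, total_current) {
    i <- match(label, layout$names)
    if (is.na(i)) stop("unknown electrode label: ", label)
    center <- layout$positions[i, ]
    center <- center / sqrt(sum(center^2))
    # tangent frame at the pad center; pad width axis = local "horizontal"
    up <- c(0, 0, 1)
    if (abs(sum(center * up)) > 0.99) up <- c(0, 1, 0)
    e1 <- cross3(matrix(up, 1), matrix(center, 1))[1, ]
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(matrix(center, 1), matrix(e1, 1))[1, ]
    n <- config$sources_per_pad
    # near-square grid covering the footprint (7x5 when n = 35)
    nw <- max(1L, round(sqrt(n * config$pad_width / config$pad_height)))
    nh <- max(1L, ceiling(n / nw))
    g <- expand.grid(u = seq_len(nw), v = seq_len(nh))
    g <- g[seq_len(min(n, nrow(g))), , drop = FALSE]
    du <- if (nw > 1) {
      (g$u - (nw + 1) / 2) / (nw - 1) * config$pad_width
    } else {
      rep(0, nrow(g))
    }
    dv <- if (nh > 1) {
      (g$v - (nh + 1) / 2) / (nh - 1) * config$pad_height
    } else {
      rep(0, nrow(g))
    }
    pts <- outer(rep(1, nrow(g)), center) + outer(du, e1) + outer(dv, e2)
    pts <- pts / sqrt(rowSums(pts^2)) * scalp_radius
    list(positions = pts,
         currents = rep(total_current / nrow(g), nrow(g)))
  }
  a <- pad_one(config$anode, config$current)
  c_ <- pad_one(config$cathode, -config$current)
  structure(list(positions = rbind(a$positions, c_$positions),
                 currents = c(a$currents, c_$currents)),
            class = "point_source_set")
}

# ---- multi-shell Legendre series --------------------------------------------

# Interface propagation of radial coefficients (A, B) for harmonic degree n:
# phi = A s^n + B s^-(n+1) within a shell (s = r / R_outer). Returns the
# 2x2 matrix taking shell-j coefficients to shell-(j+1) coefficients across
# the interface at scaled radius s between conductivities sig1 -> sig2.
interface_matrix <- function(n, s, sig1, sig2) {
  # closed-form solve of the continuity conditions (potential and sigma *
  # d(phi)/dr); stable at high degree where a naive 2x2 solve is singular
  q <- sig1 / sig2
  m11 <- ((n + 1) + n * q) / (2 * n + 1)
  m12 <- s^(-(2 * n + 1)) * (n + 1) * (1 - q) / (2 * n + 1)
  m21 <- s^(2 * n + 1) * n * (1 - q) / (2 * n + 1)
  m22 <- (n + (n + 1) * q) / (2 * n + 1)
  matrix(c(m11, m21, m12, m22), 2, 2)
}

# For each degree n, propagate the two basis coefficient pairs (1,0), (0,1)
# from the innermost shell to all shells. Returns a list (per n) of a
# n_shell x 2 x 2 array M where coefficients in shell j are M[j,,] %*% c(A1,B1).
propagate_shells <- function(shells, n_terms) {
  R <- shells$radii[length(shells$radii)]
  s <- shells$radii / R
  sig <- shells$conductivities
  ns <- length(s)
  out <- vector("list", n_terms)
  for (n in seq_len(n_terms)) {
    M <- array(0, dim = c(ns, 2, 2))
    M[1, , ] <- diag(2)
    if (ns > 1) {
      for (j in seq_len(ns - 1)) {
        Tm <- interface_matrix(n, s[j], sig[j], sig[j + 1])
        M[j + 1, , ] <- Tm %*% M[j, , ]
      }
    }
    out[[n]] <- M
  }
  out
}

# Per-degree scalp-source solution coefficients for a unit point current
# source on the scalp surface of the multi-shell head (insulating exterior).
# Returns an n_terms x n_shells x 2 array of (A, B) coefficients such that
# phi(r in shell j) = I * sum_n [A[n,j] s^n + B[n,j] s^-(n+1)] P_n(cos gamma).
monopole_coefficients <- function(shells, n_terms) {
  R <- shells$radii[length(shells$radii)]
  sigN <- shells$conductivities[length(shells$conductivities)]
  prop <- propagate_shells(shells, n_terms)
  ns <- length(shells$radii)
  co <- array(0, dim = c(n_terms, ns, 2))
  for (n in seq_len(n_terms)) {
    M <- prop[[n]]
    # innermost shell regular at the origin: (A1, B1) = alpha * (1, 0)
    uN <- M[ns, 1, 1]; vN <- M[ns, 2, 1]
    # outer boundary: sigma_N dphi/dr (r=R) equals the source surface
    # current density harmonic I (2n+1) / (4 pi R^2)
    deriv1 <- n * uN - (n + 1) * vN   # d/ds of (u s^n + v s^-(n+1)) at s=1
    alpha <- (2 * n + 1) / (4 * pi * R * sigN * deriv1)
    co[n, , 1] <- alpha * M[, 1, 1]
    co[n, , 2] <- alpha * M[, 2, 1]
  }
  co
}

shell_index <- function(shells, r) {
  idx <- findInterval(r, shells$radii, left.open = TRUE) + 1L
  idx
}

legendre_p <- function(n_max, u) {
  # returns list of matrices P[[n]] and dP[[n]] evaluated by recurrence;
  # here vectorized: P is (n_max+1) x length(u) with rows n = 0..n_max
  P <- matrix(0, n_max + 1, length(u))
  dP <- matrix(0, n_max + 1, length(u))
  P[1, ] <- 1
  if (n_max >= 1) {
    P[2, ] <- u
    dP[2, ] <- 1
  }
  if (n_max >= 2) {
    for (n in 2:n_max) {
      P[n + 1, ] <- ((2 * n - 1) * u * P[n, ] - (n - 1) * P[n - 1, ]) / n
      dP[n + 1, ] <- dP[n - 1, ] + (2 * n - 1) * P[n, ]
    }
  }
  list(P = P, dP = dP)
}

#' Electrostatic potential in a multi-shell spherical head
#'
#' Evaluates the quasi-static potential generated inside a concentric
#' multi-shell head by point current sources on the scalp surface, using the
#' truncated Legendre-series solution of Laplace's equation (per-shell radial
#' coefficients propagated across interfaces, insulating exterior boundary),
#' superposed over all sources. The potential is defined up to an additive
#' constant, fixed here by zero mean over the evaluation points.
#'
#' @param shells a [shell_model].
#' @param sources a `point_source_set` from [pad_sources()] (positions on the
#'   scalp surface, currents summing to zero).
#' @param points n x 3 matrix of evaluation positions strictly inside the
#'   outer shell.
#' @param n_terms series truncation order (default 120).
#' @param tail_tol warn when the last term's contribution exceeds this
#'   fraction of the accumulated potential scale (default 1e-8).
#' @param demean subtract the mean over evaluation points (default TRUE);
#'   set to FALSE to obtain the raw series value (e.g. for point-wise
#'   derivative checks).
#' @return Numeric vector of potentials in volts.
#' @export
potential_multishell <- function(shells, sources, points, n_terms = 120L,
                                 tail_tol = 1e-8, demean = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("points must be an n x 3 matrix")
  R <- shells$radii[length(shells$radii)]
  r <- sqrt(rowSums(pts^2))
  if (any(r >= R * (1 - 1e-12))) {
    stop("point outside head: all evaluation points must lie strictly inside",
         " the outer shell")
  }
  co <- monopole_coefficients(shells, n_terms)
  sh <- shell_index(shells, r)
  s <- r / R
  nn <- seq_len(n_terms)
  SP <- outer(s, nn, "^")
  SM <- outer(s, -(nn + 1), "^")
  SM[s < 1e-300, ] <- 0
  Amat <- t(co[, , 1, drop = TRUE])[sh, , drop = FALSE]
  Bmat <- t(co[, , 2, drop = TRUE])[sh, , drop = FALSE]
  RF <- Amat * SP + Bmat * SM
  pdir <- pts / pmax(r, 1e-300)
  pdir[r < 1e-12, ] <- 0
  phi <- numeric(nrow(pts))
  last_term <- numeric(nrow(pts))
  src_dir <- sources$positions / sqrt(rowSums(sources$positions^2))
  for (k in seq_along(sources$currents)) {
    Ik <- sources$currents[k]
    if (Ik == 0) next
    u <- as.numeric(pmin(1, pmax(-1, pdir %*% src_dir[k, ])))
    leg <- legendre_p(n_terms, u)
    terms <- RF * t(leg$P[-1, , drop = FALSE])
    phi <- phi + Ik * rowSums(terms)
    last_term <- last_term + abs(Ik * terms[, n_terms])
  }
  scale <- max(abs(phi), 1e-300)
  if (max(last_term) / scale > tail_tol) {
    warning(sprintf(paste0("series may not have converged: tail term ratio ",
                           "%.2e exceeds %.1e; increase n_terms"),
                    max(last_term) / scale, tail_tol))
  }
  if (demean) phi - mean(phi) else phi
}

#' Electric field in a multi-shell spherical head
#'
#' Evaluates E = -grad(phi) for the configuration of [potential_multishell()]
#' by analytic differentiation of the Legendre series (radial derivative of
#' the shell radial factors and angular derivative of the Legendre
#' polynomials).
#'
#' @inheritParams potential_multishell
#' @return An object of class `field_map`: list with `E` (n x 3 matrix, V/m).
#' @export
efield_at <- function(shells, sources, points, n_terms = 120L,
                      tail_tol = 1e-8) {
  pts <- as.matrix(points)
  R <- shells$radii[length(shells$radii)]
  r <- sqrt(rowSums(pts^2))
  if (any(r >= R * (1 - 1e-12))) {
    stop("point outside head: all evaluation points must lie strictly inside",
         " the outer shell")
  }
  if (any(r < 1e-9)) stop("evaluation points at the origin are not supported")
  co <- monopole_coefficients(shells, n_terms)
  sh <- shell_index(shells, r)
  s <- r / R
  nn <- seq_len(n_terms)
  SP <- outer(s, nn, "^")
  SM <- outer(s, -(nn + 1), "^")
  Amat <- t(co[, , 1, drop = TRUE])[sh, , drop = FALSE]
  Bmat <- t(co[, , 2, drop = TRUE])[sh, , drop = FALSE]
  Nm <- matrix(nn, nrow(pts), n_terms, byrow = TRUE)
  RF <- Amat * SP + Bmat * SM
  DRF <- (Amat * Nm * SP / s - Bmat * (Nm + 1) * SM / s) / R
  rhat <- pts / r
  src_dir <- sources$positions / sqrt(rowSums(sources$positions^2))
  grad <- matrix(0, nrow(pts), 3)
  last_term <- 0
  for (k in seq_along(sources$currents)) {
    Ik <- sources$currents[k]
    if (Ik == 0) next
    u <- as.numeric(pmin(1, pmax(-1, rhat %*% src_dir[k, ])))
    leg <- legendre_p(n_terms, u)
    # radial part: sum_n dfr P_n ; angular part: sum_n fr P'_n, along grad u
    radial <- rowSums(DRF * t(leg$P[-1, , drop = FALSE]))
    angular <- rowSums(RF * t(leg$dP[-1, , drop = FALSE]))
    gu <- (matrix(src_dir[k, ], nrow(pts), 3, byrow = TRUE) - u * rhat) / r
    grad <- grad + Ik * (radial * rhat + angular * gu)
    last_term <- last_term +
      max(abs(Ik * DRF[, n_terms] * t(leg$P)[, n_terms + 1]),
          abs(Ik * RF[, n_terms] * t(leg$dP)[, n_terms + 1] / r))
  }
  gscale <- max(abs(grad), 1e-300)
  if (last_term / gscale > tail_tol * 10) {
    warning("field series may not have converged; increase n_terms")
  }
  structure(list(E = -grad), class = "field_map")
}

#' Normal component of a cortical field map
#'
#' Projects the per-triangle electric field onto the unit outward normal of
#' each mesh triangle (the component parallel to the pyramidal-cell
#' somato-dendritic axis). Positive values point outwards.
#'
#' @param field a `field_map` with one row per mesh triangle.
#' @param mesh the [cortical_mesh] the field was sampled on.
#' @return Numeric vector of signed normal components E_n in V/m.
#' @export
normal_field <- function(field, mesh) {
  if (nrow(field$E) != nrow(mesh$normals)) {
    stop("field and mesh have different triangle counts")
  }
  rowSums(field$E * mesh$normals)
}

#' Per-region mean normal field and membrane-potential offsets
#'
#' Averages the per-triangle normal field over each parcellation region
#' (unweighted arithmetic mean) and scales by the calibration constant
#' lambda to obtain the membrane-potential offset applied to the pyramidal
#' subpopulation of each region's neural mass.
#'
#' @param E_n per-triangle signed normal field (V/m).
#' @param parcellation a [parcellate] result covering the same triangles.
#' @param lambda calibration constant in mV per V/m; `lambda = 0` is the
#'   no-stimulation condition.
#' @return An object of class `region_field_coefficients`: list with
#'   `mean_normal_field` (V/m), `lambda`, and `offsets` (mV), all of length
#'   `n_regions`.
#' @export
region_mean_field <- function(E_n, parcellation, lambda) {
  if (length(E_n) != length(parcellation$labels)) {
    stop("E_n length must match the parcellation")
  }
  counts <- tabulate(parcellation$labels, parcellation$n_regions)
  if (any(counts == 0L)) stop("empty region in parcellation")
  sums <- as.numeric(rowsum(E_n, parcellation$labels))
  means <- sums / counts
  structure(list(mean_normal_field = means, lambda = lambda,
                 offsets = lambda * means),
            class = "region_field_coefficients")
}

#' Field map and region-coefficient text I/O
#'
#' Field maps are stored as tab-separated text with columns
#' `triangle_index` (0-based, contiguous), `Ex`, `Ey`, `Ez` (V/m). Region
#' coefficients are stored with columns `region_index`, `mean_normal_field`,
#' `offset_mV`.
#'
#' @param field a `field_map`.
#' @param path file path.
#' @export
write_field_map <- function(field, path) {
  df <- data.frame(triangle_index = seq_len(nrow(field$E)) - 1L,
                   Ex = field$E[, 1], Ey = field$E[, 2], Ez = field$E[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_map
#' @export
load_field_map <- function(path) {
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t"),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  need <- c("triangle_index", "Ex", "Ey", "Ez")
  if (!all(need %in% names(df)) || nrow(df) == 0L) {
    stop("format error: field map needs columns ",
         paste(need, collapse = ", "))
  }
  df <- df[order(df$triangle_index), ]
  if (anyDuplicated(df$triangle_index) ||
      !identical(as.integer(df$triangle_index), seq_len(nrow(df)) - 1L)) {
    stop("format error: triangle indices must be 0-based, contiguous and",
         " unique")
  }
  E <- as.matrix(df[, c("Ex", "Ey", "Ez")])
  if (any(!is.finite(E))) stop("format error: non-finite field values")
  dimnames(E) <- NULL
  structure(list(E = E), class = "field_map")
}

#' @rdname write_field_map
#' @param coeff a `region_field_coefficients` object.
#' @export
write_region_coefficients <- function(coeff, path) {
  df <- data.frame(region_index = seq_along(coeff$offsets) - 1L,
                   mean_normal_field = coeff$mean_normal_field,
                   offset_mV = coeff$offsets)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
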