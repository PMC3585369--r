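#' Analytic EEG leadfield for a 3-shell spherical head
#'
#' Computes the scalp potential of each unit dipole of a cortical dipole
#' layer in a concentric 3-shell (brain/skull/scalp) head, using the
#' truncated Legendre-series solution for a current dipole inside a layered
#' sphere with an insulating exterior. For each harmonic degree the primary
#' (infinite-medium) dipole expansion in the innermost shell is matched
#' across the shell interfaces with the same transfer matrices as the
#' stimulation field solver. Rows are electrodes, columns dipoles; the
#' matrix maps dipole moments (A·m) to potentials (V). Columns are
#' average-referenced by default.
#'
#' @param shells3 a [shell_model] with exactly 3 shells.
#' @param layout an `electrode_layout` on the outer shell.
#' @param dipoles a [dipole_layer] strictly inside the innermost shell.
#' @param n_terms series truncation (default 60).
#' @param reference `"average"` (default) or `"none"` (potential against the
#'   series' natural zero at infinity-free constant).
#' @return An object of class `leadfield_matrix`: list with `values`
#'   (electrodes x dipoles, V per A·m for a unit-moment dipole), i.e. the
#'   potential of dipole j at electrode i is `values[i, j] * moment_j` once
#'   scaled by [project_eeg()]; `electrode_names`; `reference`.
#' @export
leadfield_3shell <- function(shells3, layout, dipoles, n_terms = 60L,
                             reference = c("average", "none")) {
  reference <- match.arg(reference)
  if (length(shells3$radii) != 3L) {
    stop("the EEG head model must have exactly 3 shells")
  }
  lf <- leadfield_multishell(shells3, layout, dipoles, n_terms)
  if (reference == "average") {
    lf <- sweep(lf, 2, colMeans(lf))
  }
  structure(list(values = lf, electrode_names = layout$names,
                 reference = reference),
            class = "leadfield_matrix")
}

# Series leadfield for any number of shells; dipoles inside the innermost.
leadfield_multishell <- function(shells, layout, dipoles, n_terms) {
  R <- shells$radii[length(shells$radii)]
  r1 <- shells$radii[1]
  sig1 <- shells$conductivities[1]
  pos <- dipoles$positions
  b <- sqrt(rowSums(pos^2))
  if (any(b >= r1 * (1 - 1e-9))) {
    stop("dipole outside inner shell")
  }
  ed <- layout$positions / sqrt(rowSums(layout$positions^2))
  if (any(abs(sqrt(rowSums(layout$positions^2)) - R) > 1e-6 * R)) {
    stop("electrodes must lie on the scalp shell")
  }
  # per-degree scalp factor g_n for a unit inner-shell singular coefficient
  g <- dipole_scalp_factors(shells, n_terms)
  n_el <- nrow(ed)
  n_dip <- nrow(pos)
  bhat <- pos / pmax(b, 1e-300)
  bhat[b < 1e-12, ] <- rep(c(0, 0, 1), each = sum(b < 1e-12))
  mom <- dipoles$orientations  # unit moment along the orientation
  q_r <- rowSums(mom * bhat)
  q_tan <- mom - q_r * bhat    # tangential moment vector
  sb <- b / R
  nn <- seq_len(n_terms)
  # b^(n-1) / R^(n+1) expressed in scaled radius: sb^(n-1) / R^2
  BP <- outer(sb, nn - 1, "^") / R^2          # n_dip x n_terms
  BP <- sweep(BP, 2, g, "*") / (4 * pi * sig1)
  out <- matrix(0, n_el, n_dip)
  for (e in seq_len(n_el)) {
    u <- as.numeric(pmin(1, pmax(-1, bhat %*% ed[e, ])))
    leg <- legendre_p(n_terms, u)
    P <- t(leg$P[-1, , drop = FALSE])    # n_dip x n_terms, P_n
    dP <- t(leg$dP[-1, , drop = FALSE])  # P'_n
    # tangential unit vector at the dipole pointing towards the electrode
    tvec <- matrix(ed[e, ], n_dip, 3, byrow = TRUE) - u * bhat
    tn <- sqrt(rowSums(tvec^2))
    ok <- tn > 1e-12
    tvec[ok, ] <- tvec[ok, ] / tn[ok]
    tvec[!ok, ] <- 0
    q_t <- rowSums(q_tan * tvec)
    sing <- sqrt(pmax(0, 1 - u^2))
    radial_part <- rowSums(BP * sweep(P, 2, nn, "*")) * q_r
    tangential_part <- rowSums(BP * dP) * sing * q_t
    out[e, ] <- radial_part + tangential_part
  }
  out
}

# Scalp value per degree for a dipole whose singular expansion in the inner
# shell has unit coefficient: propagate (A1 unknown, B1 = 1) outwards and
# apply the insulating outer boundary d(phi)/dr = 0 at r = R.
dipole_scalp_factors <- function(shells, n_terms) {
  prop <- propagate_shells(shells, n_terms)
  ns <- length(shells$radii)
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    M <- prop[[n]]
    u1 <- M[ns, 1, 1]; v1 <- M[ns, 2, 1]  # image of (1, 0)
    u2 <- M[ns, 1, 2]; v2 <- M[ns, 2, 2]  # image of (0, 1)
    alpha <- -(n * u2 - (n + 1) * v2) / (n * u1 - (n + 1) * v1)
    g[n] <- alpha * (u1 + v1) + (u2 + v2)
  }
  g
}

#' Project region time courses to scalp EEG
#'
#' Expands the per-region source matrix to the full dipole layer (every
#' triangle of a region carries its region's time course scaled by the
#' triangle's dipole moment) and applies the leadfield: X = A * S.
#' Simulated source activity is in millivolt LFP units; the projection
#' treats the moment-scaled source value as the dipole moment time course.
#'
#' @param A a `leadfield_matrix`.
#' @param parcellation a [parcellate] result with one label per dipole.
#' @param dipoles the [dipole_layer] the leadfield was built on.
#' @param sim a `simulation_result` from [simulate_network()] whose region
#'   count equals `parcellation$n_regions`.
#' @return An object of class `eeg_record`: `X` (electrodes x samples, V),
#'   `fs`, `electrode_names`, `reference`.
#' @export
project_eeg <- function(A, parcellation, dipoles, sim) {
  n_dip <- ncol(A$values)
  if (length(parcellation$labels) != n_dip ||
      length(dipoles$moments) != n_dip) {
    stop("leadfield, parcellation and dipole layer sizes do not match")
  }
  if (nrow(sim$S) != parcellation$n_regions) {
    stop("simulation region count does not match the parcellation")
  }
  # electrodes x regions: moment-weighted sum of each region's columns
  W <- matrix(0, n_dip, parcellation$n_regions)
  W[cbind(seq_len(n_dip), parcellation$labels)] <- dipoles$moments
  A_region <- A$values %*% W
  X <- A_region %*% (sim$S * 1e-3)  # source LFP mV -> V
  structure(list(X = X, fs = sim$fs, electrode_names = A$electrode_names,
                 reference = A$reference),
            class = "eeg_record")
}

#' Re-reference an EEG record
#'
#' Subtracts either the instantaneous channel mean (`"average"`) or a named
#' electrode's signal from every channel. Average referencing is idempotent;
#' re-referencing never changes inter-electrode differences.
#'
#' @param eeg an `eeg_record`.
#' @param scheme `"average"` or an electrode label present in the record.
#' @return The re-referenced `eeg_record`.
#' @export
rereference <- function(eeg, scheme = "average") {
  if (identical(scheme, "average")) {
    ref <- colMeans(eeg$X)
    eeg$X <- sweep(eeg$X, 2, ref)
    eeg$reference <- "average"
  } else {
    i <- match(scheme, eeg$electrode_names)
    if (is.na(i)) stop("unknown electrode label: ", scheme)
    eeg$X <- sweep(eeg$X, 2, eeg$X[i, ])
    eeg$reference <- scheme
  }
  eeg
}

#' Leadfield and EEG text I/O
#'
#' The leadfield file is a tab-separated matrix whose header row holds the
#' electrode names; each subsequent column block is one dipole (rows =
#' electrodes after transposition on read). EEG records are written as
#' tab-separated text, one row per sample, one column per electrode, with a
#' header of channel labels and a YAML sidecar (`<path>.meta.yaml`) holding
#' the sampling rate and reference.
#'
#' @param A a `leadfield_matrix`.
#' @param path file path.
#' @export
write_leadfield <- function(A, path) {
  m <- t(A$values)
  colnames(m) <- A$electrode_names
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  values <- t(m)
  electrode_names <- colnames(m)
  dimnames(values) <- NULL
  structure(list(values = values, electrode_names = electrode_names,
                 reference = "unknown"),
            class = "leadfield_matrix")
}

#' @rdname write_leadfield
#' @param eeg an `eeg_record`.
#' @export
write_eeg_text <- function(eeg, path) {
  m <- t(eeg$X)
  colnames(m) <- eeg$electrode_names
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = eeg$fs, reference = eeg$reference,
                        units = "V", channels = eeg$electrode_names),
                   paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_eeg_text <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  X <- t(m)
  electrode_names <- colnames(m)
  dimnames(X) <- NULL
  structure(list(X = X, fs = meta$fs, electrode_names = electrode_names,
                 reference = meta$reference),
            class = "eeg_record")
}
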