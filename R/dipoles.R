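#' Dipole layer over a cortical mesh
#'
#' Associates one elementary current dipole with every mesh triangle, placed
#' at the triangle barycenter, oriented along the unit outward normal (the
#' mean somato-dendritic axis of the pyramidal cells in that patch), with
#' moment magnitude proportional to the triangle area.
#'
#' @param mesh a [cortical_mesh].
#' @param moment_density dipole moment per unit area, A·m per m^2; must be
#'   positive.
#' @return An object of class `dipole_layer`: list with `positions` (n x 3,
#'   m), `orientations` (n x 3, unit), `moments` (A·m).
#' @export
dipole_layer <- function(mesh, moment_density = 1e-3) {
  if (!is.finite(moment_density) || moment_density <= 0) {
    stop("moment_density must be positive")
  }
  structure(list(positions = mesh$barycenters,
                 orientations = mesh$normals,
                 moments = moment_density * mesh$areas),
            class = "dipole_layer")
}

#' @export
print.dipole_layer <- function(x, ...) {
  cat(sprintf("<dipole_layer> %d dipoles, total moment %.3e A.m\n",
              length(x$moments), sum(x$moments)))
  invisible(x)
}
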