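#' Concentric-shell head model
#'
#' A `shell_model` describes a head as concentric spherical shells, each with
#' an outer radius and an isotropic conductivity. Shells are ordered from the
#' innermost outwards; the outer radius of the last shell is the scalp
#' surface. The same container is used by the stimulation field solver
#' (typically 5 tissues: white matter, grey matter, CSF, skull, scalp) and by
#' the EEG forward model (3 tissues: brain, skull, scalp).
#'
#' @param radii numeric vector of shell outer radii in metres, strictly
#'   increasing, innermost first.
#' @param conductivities numeric vector of per-shell isotropic conductivities
#'   in S/m, same length as `radii`, all positive.
#' @return An object of class `shell_model` with elements `radii` and
#'   `conductivities`.
#' @examples
#' shell_model(c(0.082, 0.087, 0.092), c(0.33, 0.008, 0.33))
#' @export
shell_model <- function(radii, conductivities) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != length(conductivities)) {
    stop("`radii` and `conductivities` must have the same length")
  }
  if (length(radii) < 1L) stop("at least one shell is required")
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("invalid geometry: shell radii must be positive and finite")
  }
  if (any(diff(radii) <= 0)) {
    stop("invalid geometry: shell radii must be strictly increasing")
  }
  if (any(!is.finite(conductivities)) || any(conductivities <= 0)) {
    stop("all conductivities must be positive and finite")
  }
  structure(list(radii = radii, conductivities = conductivities),
            class = "shell_model")
}

#' @export
print.shell_model <- function(x, ...) {
  cat("<shell_model> ", length(x$radii), " shells\n", sep = "")
  for (i in seq_along(x$radii)) {
    cat(sprintf("  shell %d: r = %.4f m, sigma = %.3f S/m\n",
                i, x$radii[i], x$conductivities[i]))
  }
  invisible(x)
}

#' Default shell models
#'
#' `default_field_shells()` returns the 5-shell head used by the stimulation
#' field solver: white-matter core, grey matter, CSF, skull and scalp with
#' conductivities 0.15, 0.33, 1.79, 0.008 and 0.33 S/m. `default_eeg_shells()`
#' returns the 3-shell (brain/skull/scalp) model used for the EEG forward
#' problem, with conductivities 0.33, 0.008 and 0.33 S/m.
#'
#' Default radii follow the common spherical-head convention: cortical surface
#' at 0.079 m, inner skull at 0.082 m (a thin CSF shell between cortex and
#' skull in the field model), outer skull at 0.087 m and scalp at 0.092 m.
#' The white-matter core radius is 0.065 m.
#'
#' @param scalp_radius scalp (outermost) radius in metres; all other radii
#'   are scaled proportionally.
#' @return A [shell_model].
#' @export
default_field_shells <- function(scalp_radius = 0.092) {
  s <- scalp_radius / 0.092
  shell_model(radii = s * c(0.065, 0.079, 0.082, 0.087, 0.092),
              conductivities = c(0.15, 0.33, 1.79, 0.008, 0.33))
}

#' @rdname default_field_shells
#' @export
default_eeg_shells <- function(scalp_radius = 0.092) {
  s <- scalp_radius / 0.092
  shell_model(radii = s * c(0.082, 0.087, 0.092),
              conductivities = c(0.33, 0.008, 0.33))
}
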