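#' Standard electrode positions on a spherical scalp
#'
#' Returns scalp electrode positions for the international 10-20 system
#' (19 electrodes) or an extended 10-10 layout (43 electrodes, including the
#' low occipital positions PO9/PO10 used for stimulation pads). Positions are
#' constructed geodesically on the sphere with the conventional arcs:
#' the sagittal nasion-inion arc (Fpz..Oz at 10% steps), the coronal
#' ear-to-ear arc (T3..T4), the 10% circumferential ring, a lower ring 10%
#' below it (PO9/PO10), and great-circle midpoints for intermediate
#' electrodes (F3/F4, P3/P4, ...).
#'
#' Coordinates are right-handed with +x towards the right ear, +y towards the
#' nasion and +z towards the vertex (Cz).
#'
#' @param montage `"10-20"` or `"10-10"`.
#' @param scalp_radius scalp sphere radius in metres.
#' @return An object of class `electrode_layout`: list with `names`
#'   (character) and `positions` (n x 3 matrix, metres, all at
#'   `|r| = scalp_radius`).
#' @examples
#' lay <- standard_electrode_positions("10-20", 0.092)
#' lay$names
#' @export
standard_electrode_positions <- function(montage = c("10-20", "10-10"),
                                         scalp_radius = 0.092) {
  montage <- match.arg(montage)
  if (!is.finite(scalp_radius) || scalp_radius <= 0) {
    stop("scalp_radius must be positive")
  }
  tab <- electrode_table()
  if (montage == "10-20") {
    keep <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
              "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
    tab <- tab[match(keep, tab$name), ]
  }
  pos <- as.matrix(tab[, c("x", "y", "z")]) * scalp_radius
  dimnames(pos) <- NULL
  structure(list(names = tab$name, positions = pos, montage = montage),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %s, %d electrodes\n",
              x$montage %||% "custom", length(x$names)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit-sphere directions for the supported labels.
electrode_table <- function() {
  deg <- pi / 180
  rows <- list()
  add <- function(name, x, y, z) rows[[length(rows) + 1L]] <<- list(
    name = name, x = x, y = y, z = z)
  # sagittal midline arc: angle psi from nasion over the vertex
  mid <- c(Fpz = 18, AFz = 36, Fz = 54, FCz = 72, Cz = 90, CPz = 108,
           Pz = 126, POz = 144, Oz = 162)
  for (nm in names(mid)) {
    psi <- mid[[nm]] * deg
    add(nm, 0, cos(psi), sin(psi))
  }
  # 10% circumferential ring at elevation 18 deg; azimuth theta from the
  # nasion, left (-x) side then mirrored
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T3 = 90, TP7 = 108,
            T5 = 126, PO7 = 144, O1 = 162)
  el <- 18 * deg
  for (nm in names(ring)) {
    th <- ring[[nm]] * deg
    add(nm, -sin(th) * cos(el), cos(th) * cos(el), sin(el))
  }
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T3 = "T4",
              TP7 = "TP8", T5 = "T6", PO7 = "PO8", O1 = "O2")
  for (nm in names(ring)) {
    th <- ring[[nm]] * deg
    add(mirror[[nm]], sin(th) * cos(el), cos(th) * cos(el), sin(el))
  }
  # lower ring 10% (18 deg) below the circumferential ring: low occipital
  add("PO9", -sin(144 * deg), cos(144 * deg), 0)
  add("PO10", sin(144 * deg), cos(144 * deg), 0)
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  # coronal-arc electrodes C3/C4 (30% up from each ear) coincide with the
  # slerp construction below applied to (Cz, T3); intermediates by
  # great-circle midpoints
  slerp_mid <- function(a, b) {
    p <- (a + b) / sqrt(sum((a + b)^2))
    p
  }
  getp <- function(nm) unlist(tab[tab$name == nm, c("x", "y", "z")])
  inter <- list(
    C3 = c("Cz", "T3"), C4 = c("Cz", "T4"),
    F3 = c("Fz", "F7"), F4 = c("Fz", "F8"),
    P3 = c("Pz", "T5"), P4 = c("Pz", "T6"),
    AF3 = c("AFz", "AF7"), AF4 = c("AFz", "AF8"),
    FC3 = c("FCz", "FT7"), FC4 = c("FCz", "FT8"),
    CP3 = c("CPz", "TP7"), CP4 = c("CPz", "TP8"),
    PO3 = c("POz", "PO7"), PO4 = c("POz", "PO8"))
  for (nm in names(inter)) {
    p <- slerp_mid(getp(inter[[nm]][1]), getp(inter[[nm]][2]))
    tab <- rbind(tab, data.frame(name = nm, x = p[1], y = p[2], z = p[3]))
  }
  tab$name <- as.character(tab$name)
  stopifnot(!anyDuplicated(tab$name))
  tab
}

#' Write / read an electrode layout as delimited text
#'
#' Format: tab-separated columns `label`, `x`, `y`, `z` (metres).
#'
#' @param layout an `electrode_layout`.
#' @param path file path.
#' @export
write_electrode_layout <- function(layout, path) {
  df <- data.frame(label = layout$names, x = layout$positions[, 1],
                   y = layout$positions[, 2], z = layout$positions[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_electrode_layout
#' @export
read_electrode_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$label)) stop("format error: duplicate electrode labels")
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  structure(list(names = df$label, positions = pos, montage = "custom"),
            class = "electrode_layout")
}
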