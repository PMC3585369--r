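#' Mesh input/output in ASCII OFF and PLY formats
#'
#' `write_mesh_off()`/`read_mesh_off()` use the Object File Format;
#' `write_mesh_ply()`/`read_mesh_ply()` use ASCII PLY. Both store vertices in
#' metres and 0-based triangle indices on disk; in memory triangles are
#' 1-based. Imported meshes are validated (closed surface, outward winding).
#'
#' @param mesh a [cortical_mesh].
#' @param path file path.
#' @return Readers return a [cortical_mesh]; writers return `path` invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop("format error: not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("format error: only triangle faces supported")
  validate_imported_mesh(verts, fl[, 2:4] + 1L)
}

#' @rdname write_mesh_off
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("format error: not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("format error: missing end_header")
  hdr <- lines[1:hdr_end]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", hdr, value = TRUE)))
  verts <- matrix(scan(text = lines[hdr_end + (1:nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[hdr_end + nv + (1:nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("format error: only triangle faces supported")
  validate_imported_mesh(verts, fl[, 2:4] + 1L)
}

validate_imported_mesh <- function(vertices, triangles) {
  mesh <- new_cortical_mesh(vertices, triangles)
  if (!mesh_is_closed(mesh)) stop("invalid geometry: mesh is not closed")
  if (mesh_signed_volume(mesh) <= 0) {
    stop("invalid geometry: mesh winding is not outward")
  }
  mesh
}
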