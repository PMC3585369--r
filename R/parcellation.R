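#' Parcellate a cortical mesh into contiguous regions
#'
#' Groups mesh triangles into `n_regions` spatially contiguous regions, one
#' neuronal population per region. Clustering is seeded spherical k-means on
#' triangle barycenter directions, followed by a contiguity repair step that
#' reassigns disconnected fragments to a neighbouring region. With
#' `symmetric = TRUE` (the default) regions are split equally between the
#' x > 0 and x < 0 hemispheres (e.g. 66 regions = 33 per hemisphere): the
#' right hemisphere is clustered and the left hemisphere labelled by
#' mirror-image centroids.
#'
#' @param mesh a [cortical_mesh].
#' @param n_regions number of regions (default 66); must be even when
#'   `symmetric = TRUE` and cannot exceed the triangle count.
#' @param seed integer seed making the clustering deterministic.
#' @param symmetric logical; enforce the hemisphere split.
#' @return An object of class `parcellation`: list with `labels` (per-triangle
#'   region index in 1..n_regions) and `n_regions`.
#' @export
parcellate <- function(mesh, n_regions = 66L, seed = 1L, symmetric = TRUE) {
  n_tri <- nrow(mesh$triangles)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (n_regions > n_tri) stop("n_regions exceeds the number of triangles")
  if (symmetric && n_regions %% 2L != 0L && n_regions > 1L) {
    stop("n_regions must be even when hemisphere symmetry is requested")
  }
  if (n_regions == 1L) {
    return(structure(list(labels = rep(1L, n_tri), n_regions = 1L),
                     class = "parcellation"))
  }
  dirs <- mesh$barycenters / sqrt(rowSums(mesh$barycenters^2))
  labels <- integer(n_tri)
  if (symmetric) {
    k <- n_regions %/% 2L
    right <- dirs[, 1] > 0
    km <- with_seed(seed, stats::kmeans(dirs[right, , drop = FALSE],
                                        centers = k, nstart = 8L,
                                        iter.max = 50L))
    labels[right] <- km$cluster
    # mirror the right-hemisphere centroids for the left hemisphere
    cl <- km$centers
    cl[, 1] <- -cl[, 1]
    d <- dirs[!right, , drop = FALSE] %*% t(cl)
    labels[!right] <- k + max.col(d)
    hemi <- ifelse(right, 1L, 2L)
  } else {
    km <- with_seed(seed, stats::kmeans(dirs, centers = n_regions,
                                        nstart = 8L, iter.max = 50L))
    labels <- km$cluster
    hemi <- rep(1L, n_tri)
  }
  labels <- repair_contiguity(mesh, labels, hemi)
  if (length(unique(labels)) != n_regions) {
    stop("parcellation failed to produce the requested number of regions")
  }
  structure(list(labels = labels, n_regions = n_regions),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d triangles into %d regions (sizes %d-%d)\n",
              length(x$labels), x$n_regions, min(table(x$labels)),
              max(table(x$labels))))
  invisible(x)
}

# Reassign every connected component of a label that is not its largest
# component to the most frequent neighbouring label in the same hemisphere.
repair_contiguity <- function(mesh, labels, hemi) {
  adj <- triangle_adjacency(mesh)
  for (iter in 1:20) {
    comp <- label_components(labels, adj)
    moved <- FALSE
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      comps <- split(idx, comp[idx])
      if (length(comps) <= 1L) next
      sizes <- lengths(comps)
      keep <- which.max(sizes)
      for (ci in seq_along(comps)) {
        if (ci == keep) next
        frag <- comps[[ci]]
        nb <- unlist(adj[frag])
        nb_lab <- labels[nb]
        ok <- nb_lab != lab & hemi[nb] == hemi[frag[1]]
        if (!any(ok)) next
        tgt <- as.integer(names(which.max(table(nb_lab[ok]))))
        labels[frag] <- tgt
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

# Connected components of the triangle graph restricted to equal labels.
label_components <- function(labels, adj) {
  n <- length(labels)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      t <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- adj[[t]]
      nb <- nb[comp[nb] == 0L & labels[nb] == labels[t]]
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Read and write parcellations as delimited text
#'
#' The on-disk format is two tab-separated columns, `triangle_index` and
#' `region_index`, both 0-based, one row per triangle in triangle order.
#'
#' @param parcellation a [parcellate] result.
#' @param path file path.
#' @return `read_parcellation()` returns a `parcellation`;
#'   `write_parcellation()` returns `path` invisibly.
#' @export
write_parcellation <- function(parcellation, path) {
  df <- data.frame(triangle_index = seq_along(parcellation$labels) - 1L,
                   region_index = parcellation$labels - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("triangle_index", "region_index") %in% names(df))) {
    stop("parcellation file must have triangle_index and region_index columns")
  }
  df <- df[order(df$triangle_index), ]
  if (!identical(as.integer(df$triangle_index),
                 seq_len(nrow(df)) - 1L)) {
    stop("format error: triangle indices must be 0-based and contiguous")
  }
  labels <- as.integer(df$region_index) + 1L
  structure(list(labels = labels, n_regions = length(unique(labels))),
            class = "parcellation")
}
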