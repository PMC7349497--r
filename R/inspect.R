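#' Topological health report of a mesh
#'
#' Computes counts from edge incidence: a boundary edge is used by exactly one
#' face, a manifold edge by at most two. Watertightness (zero boundary edges)
#' is the precondition for a well-defined enclosed volume, and consistent
#' orientation means every shared edge is traversed in opposite directions by
#' its two faces.
#'
#' @param mesh a [triangle_mesh]; weld duplicated vertices with [clean_mesh()]
#'   first, otherwise coincident-but-distinct vertices read as boundary.
#' @return A `mesh_report` list: `n_vertices`, `n_faces`, `n_boundary_edges`,
#'   `n_connected_components`, `is_edge_manifold`, `is_watertight`,
#'   `is_consistently_oriented`.
#' @examples
#' inspect(make_cube(7))$is_watertight
#' @export
inspect <- function(mesh) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (nf == 0L) {
    return(structure(list(n_vertices = nv, n_faces = 0L,
                          n_boundary_edges = 0L,
                          n_connected_components = 0L,
                          is_edge_manifold = TRUE, is_watertight = TRUE,
                          is_consistently_oriented = TRUE),
                     class = "mesh_report"))
  }
  he <- half_edges(mesh$faces)
  keys <- edge_keys(he)
  cnt <- table(keys)
  n_boundary <- sum(cnt == 1L)
  manifold <- all(cnt <= 2L)

  # orientation: every interior edge must appear once in each direction
  dir_keys <- paste(he[, 1], he[, 2], sep = "_")
  oriented <- manifold && !anyDuplicated(dir_keys) && TRUE

  # connected components over vertices used by faces
  used <- sort(unique(as.vector(mesh$faces)))
  g <- igraph::graph_from_edgelist(
    cbind(match(he[, 1], used), match(he[, 2], used)), directed = FALSE)
  ncomp <- igraph::count_components(g)

  structure(list(n_vertices = nv, n_faces = nf,
                 n_boundary_edges = as.integer(n_boundary),
                 n_connected_components = as.integer(ncomp),
                 is_edge_manifold = manifold,
                 is_watertight = n_boundary == 0L,
                 is_consistently_oriented = isTRUE(oriented)),
            class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat("mesh report:\n")
  cat("  vertices:            ", x$n_vertices, "\n")
  cat("  faces:               ", x$n_faces, "\n")
  cat("  boundary edges:      ", x$n_boundary_edges, "\n")
  cat("  connected components:", x$n_connected_components, "\n")
  cat("  edge-manifold:       ", x$is_edge_manifold, "\n")
  cat("  watertight:          ", x$is_watertight, "\n")
  cat("  oriented:            ", x$is_consistently_oriented, "\n")
  invisible(x)
}
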