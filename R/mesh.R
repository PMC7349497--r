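#' Triangular surface mesh
#'
#' The container every geometric operation in mealvol works on: an indexed
#' triangle soup with vertex coordinates in centimeters and faces wound
#' counter-clockwise when viewed from outside the surface.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (cm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param label optional character label carried through the pipeline.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces` and `label`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1L, 2L, 3L)))
#' n_faces(m)
#' @export
triangle_mesh <- function(vertices, faces, label = NULL) {
  vertices <- as.matrix(vertices)
  if (length(vertices) == 0L) {
    vertices <- matrix(numeric(0), ncol = 3)
  }
  if (ncol(vertices) != 3L) {
    stop("vertices must have 3 columns (x, y, z)")
  }
  storage.mode(vertices) <- "double"
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("vertices contain non-finite coordinates")
  }
  faces <- as.matrix(faces)
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), ncol = 3)
  }
  if (ncol(faces) != 3L) {
    stop("faces must have 3 columns")
  }
  storage.mode(faces) <- "integer"
  nv <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nv) {
      stop("face index out of range [1, ", nv, "]")
    }
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(dup)) {
      stop("face ", which(dup)[1], " references the same vertex twice")
    }
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Weld duplicate vertices and drop degenerate faces
#'
#' Scanner exports routinely duplicate vertices at triangle corners; boundary
#' detection needs welded topology. Vertices closer than `weld_tol` are merged
#' (snapped to a grid of that pitch), faces that collapse to fewer than three
#' distinct vertices or whose area falls below `area_tol` are removed, and
#' unreferenced vertices are dropped.
#'
#' @param mesh a `triangle_mesh`.
#' @param weld_tol merge tolerance in cm.
#' @param area_tol faces with area (cm^2) at or below this are dropped.
#' @return A cleaned `triangle_mesh`.
#' @export
clean_mesh <- function(mesh, weld_tol = 1e-6, area_tol = 1e-10) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L) return(mesh)
  key <- apply(round(v / weld_tol), 1, paste, collapse = ",")
  first <- match(key, key)               # representative per duplicate group
  keep <- sort(unique(first))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  v2 <- v[keep, , drop = FALSE]
  if (nrow(f) > 0L) {
    f2 <- matrix(remap[first[f]], ncol = 3)
    distinct <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
    f2 <- f2[distinct, , drop = FALSE]
    if (nrow(f2) > 0L) {
      areas <- face_areas(v2, f2)
      f2 <- f2[areas > area_tol, , drop = FALSE]
    }
  } else {
    f2 <- f
  }
  # drop vertices no face references
  if (nrow(f2) > 0L) {
    used <- sort(unique(as.vector(f2)))
    remap2 <- integer(nrow(v2))
    remap2[used] <- seq_along(used)
    v2 <- v2[used, , drop = FALSE]
    f2 <- matrix(remap2[f2], ncol = 3)
  }
  triangle_mesh(v2, f2, label = mesh$label)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr * cr))
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  len <- sqrt(rowSums(cr * cr))
  len[len == 0] <- 1
  cr / len
}

face_centroids <- function(vertices, faces) {
  (vertices[faces[, 1], , drop = FALSE] +
   vertices[faces[, 2], , drop = FALSE] +
   vertices[faces[, 3], , drop = FALSE]) / 3
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps) return(c(0, 0, 0))
  v / n
}

# directed edges as they appear in faces: one row per half-edge (from, to)
half_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

# undirected edge keys "lo_hi" per half-edge
edge_keys <- function(he) {
  lo <- pmin(he[, 1], he[, 2])
  hi <- pmax(he[, 1], he[, 2])
  paste(lo, hi, sep = "_")
}
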