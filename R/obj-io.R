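#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records of an ASCII OBJ file into a [triangle_mesh].
#' Polygonal faces are fan-triangulated from their first vertex. Normal,
#' texture and material records are ignored: the pipeline is geometry-only.
#' Coordinates are interpreted as centimeters. Negative (relative) face
#' indices are resolved against the vertices read so far, and `i/t/n` index
#' triplets are stripped to the vertex index.
#'
#' @param path path to an OBJ file.
#' @return A [triangle_mesh]. Vertices are not welded on read; call
#'   [clean_mesh()] before topological analysis.
#' @seealso [write_obj()]
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) {
    stop("OBJ file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  faces <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    rec <- tok[1]
    if (rec == "v") {
      if (length(tok) < 4L) {
        stop("line ", ln, ": vertex record has fewer than 3 coordinates")
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) {
        stop("line ", ln, ": non-numeric vertex coordinate")
      }
      verts[[length(verts) + 1L]] <- xyz
    } else if (rec == "f") {
      if (length(tok) < 4L) {
        stop("line ", ln, ": face record has fewer than 3 vertices")
      }
      idx <- vapply(tok[-1], function(t) {
        i <- suppressWarnings(as.integer(strsplit(t, "/", fixed = TRUE)[[1]][1]))
        if (is.na(i)) stop("line ", ln, ": non-integer face index '", t, "'")
        i
      }, integer(1), USE.NAMES = FALSE)
      idx[idx < 0L] <- length(verts) + 1L + idx[idx < 0L]
      if (any(idx < 1L) || any(idx > length(verts))) {
        stop("line ", ln, ": face index out of range (", length(verts),
             " vertices read so far)")
      }
      # fan triangulation of polygons from the first vertex
      for (k in seq_len(length(idx) - 2L)) {
        faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
      }
    }
    # vn/vt/usemtl/o/g/s records ignored
  }
  v <- if (length(verts)) do.call(rbind, verts) else matrix(numeric(0), ncol = 3)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), ncol = 3)
  triangle_mesh(v, f)
}

#' Write a mesh as Wavefront OBJ
#'
#' Writes `v` records at full double precision (15 significant digits) and
#' 1-based triangular `f` records. An empty mesh produces a header comment
#' only.
#'
#' @param mesh a [triangle_mesh].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_obj <- function(mesh, path) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines("# mealvol triangular mesh (units: cm)", con)
  if (nrow(mesh$vertices) > 0L) {
    writeLines(sprintf("v %.15g %.15g %.15g",
                       mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3]), con)
  }
  if (nrow(mesh$faces) > 0L) {
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  }
  invisible(path)
}
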