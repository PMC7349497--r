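#' Detect hole boundary loops
#'
#' A boundary edge is incident to exactly one face; chained boundary edges
#' form closed loops delimiting holes. Loops are traversed in the direction
#' the adjacent faces' half-edges impose, so the existing surface lies to a
#' consistent side. Each loop carries the interior front angle `theta`
#' (degrees) at every boundary vertex: the angle between the two boundary
#' edges at that vertex, opened toward the hole, disambiguated for reflex
#' vertices against the loop's Newell (area-vector) normal.
#'
#' @param mesh an edge-manifold [triangle_mesh] (weld first with
#'   [clean_mesh()]).
#' @return A list of `boundary_loop` objects, each a list with `vertices`
#'   (ordered vertex indices, closed implicitly) and `theta` (degrees, in
#'   `(0, 360)`).
#' @examples
#' holes <- find_holes(puncture(make_cube(7), c(3.5, 3.5, 7), 1e-3))
#' length(holes)
#' @export
find_holes <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(list())
  he <- half_edges(mesh$faces)
  keys <- edge_keys(he)
  cnt <- table(keys)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1]
    stop("non-manifold edge (used by >2 faces): vertices ",
         gsub("_", "-", bad))
  }
  on_boundary <- cnt[keys] == 1L
  bhe <- he[on_boundary, , drop = FALSE]
  if (nrow(bhe) == 0L) return(list())

  loops <- list()
  # outgoing boundary half-edges per tail vertex (handles bowtie vertices)
  used <- rep(FALSE, nrow(bhe))
  out_of <- split(seq_len(nrow(bhe)), bhe[, 1])
  repeat {
    start <- which(!used)[1]
    if (is.na(start)) break
    loop <- integer(0)
    i <- start
    repeat {
      used[i] <- TRUE
      loop <- c(loop, bhe[i, 1])
      nxt_candidates <- out_of[[as.character(bhe[i, 2])]]
      nxt_candidates <- nxt_candidates[!used[nxt_candidates]]
      if (length(nxt_candidates) == 0L) break
      i <- nxt_candidates[1]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  lapply(loops, function(idx) {
    structure(list(vertices = idx,
                   theta = interior_angles(mesh$vertices[idx, , drop = FALSE])),
              class = "boundary_loop")
  })
}

# Newell area-vector normal of an ordered 3D polygon (rows of P)
newell_normal <- function(P) {
  nxt <- c(2:nrow(P), 1)
  n <- colSums(cross3(P, P[nxt, , drop = FALSE]))
  normalize3(n)
}

# interior angles (degrees) of an ordered 3D polygon; reflex vertices
# resolved against the Newell normal so values lie in (0, 360)
interior_angles <- function(P) {
  k <- nrow(P)
  if (k < 3L) return(rep(NA_real_, k))
  n <- newell_normal(P)
  prv <- c(k, seq_len(k - 1))
  nxt <- c(2:k, 1)
  u <- P[prv, , drop = FALSE] - P
  w <- P[nxt, , drop = FALSE] - P
  lu <- sqrt(rowSums(u * u)); lw <- sqrt(rowSums(w * w))
  cosang <- pmin(1, pmax(-1, rowSums(u * w) / (lu * lw)))
  raw <- acos(cosang)
  s <- rowSums(cross3(w, u) * matrix(n, k, 3, byrow = TRUE))
  ang <- ifelse(s >= 0, raw, 2 * pi - raw)
  ang * 180 / pi
}

#' Plate segmentation configuration
#'
#' @param plane_tolerance inliers lie within this distance (cm) of the fitted
#'   plane; also the face classification band.
#' @param min_inlier_fraction minimum fraction of mesh vertices the plane must
#'   explain, else no plate is found.
#' @param ransac_iters number of random 3-point plane hypotheses.
#' @param seed RNG seed for the RANSAC draws (reproducibility).
#' @return A `plate_config` list.
#' @export
plate_config <- function(plane_tolerance = 0.3, min_inlier_fraction = 0.2,
                         ransac_iters = 500L, seed = 1L) {
  stopifnot(plane_tolerance > 0, min_inlier_fraction > 0,
            min_inlier_fraction <= 1, ransac_iters >= 1)
  structure(list(plane_tolerance = plane_tolerance,
                 min_inlier_fraction = min_inlier_fraction,
                 ransac_iters = as.integer(ransac_iters),
                 seed = as.integer(seed)),
            class = "plate_config")
}

#' Segment the support plate from a scan
#'
#' Replaces the manual plate-removal step of interactive mesh tools with a
#' deterministic RANSAC plane fit: random vertex triples propose planes, the
#' plane with most inliers (within `plane_tolerance`) wins and is refined by
#' a least-squares fit to its inliers. Faces whose three vertices all lie in
#' the tolerance band are the plate; the remaining faces are split into
#' connected components, one food item candidate each. Removing the plate
#' opens boundary loops on the items, to be closed by [fill_all_holes()].
#'
#' @param mesh a [triangle_mesh] containing a dominant near-planar surface.
#' @param cfg a [plate_config()].
#' @return A `segmentation_result`: list with `plate` (mesh), `items` (list of
#'   meshes), `plane` (list `point`, `normal`).
#' @export
segment_plate <- function(mesh, cfg = plate_config()) {
  v <- mesh$vertices
  nv <- nrow(v)
  if (nv < 3L) stop("no plate found: mesh too small")
  rng <- local_rng(cfg$seed)
  best <- NULL
  best_n <- -1L
  for (it in seq_len(cfg$ransac_iters)) {
    idx <- sample_int(rng, nv, 3L)
    p <- v[idx, , drop = FALSE]
    n <- normalize3(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])[1, ])
    if (all(n == 0)) next
    d <- abs((v - matrix(p[1, ], nv, 3, byrow = TRUE)) %*% n)
    n_in <- sum(d <= cfg$plane_tolerance)
    if (n_in > best_n) {
      best_n <- n_in
      best <- list(point = p[1, ], normal = n)
    }
  }
  if (is.null(best) || best_n < cfg$min_inlier_fraction * nv) {
    stop("no plate found: best plane explains ", max(best_n, 0), "/", nv,
         " vertices (need ", ceiling(cfg$min_inlier_fraction * nv), ")")
  }
  # least-squares refinement on inliers
  d <- abs((v - matrix(best$point, nv, 3, byrow = TRUE)) %*% best$normal)
  inl <- v[d <= cfg$plane_tolerance, , drop = FALSE]
  ctr <- colMeans(inl)
  sv <- svd(sweep(inl, 2, ctr))
  normal <- sv$v[, 3]
  # orient the normal toward the food side (majority of off-plane vertices)
  off <- (v - matrix(ctr, nv, 3, byrow = TRUE)) %*% normal
  if (sum(off > cfg$plane_tolerance) < sum(off < -cfg$plane_tolerance)) {
    normal <- -normal
  }
  dist <- abs((v - matrix(ctr, nv, 3, byrow = TRUE)) %*% normal)
  vert_on_plane <- dist <= cfg$plane_tolerance
  f <- mesh$faces
  face_on_plane <- vert_on_plane[f[, 1]] & vert_on_plane[f[, 2]] &
    vert_on_plane[f[, 3]]
  plate <- submesh(mesh, which(face_on_plane), label = "plate")
  food_faces <- which(!face_on_plane)
  items <- list()
  if (length(food_faces) > 0L) {
    food <- submesh(mesh, food_faces)
    comp <- face_components(food)
    items <- lapply(seq_len(max(comp)), function(k) {
      submesh(food, which(comp == k), label = paste0("item_", k))
    })
  }
  structure(list(plate = plate, items = items,
                 plane = list(point = ctr, normal = as.numeric(normal))),
            class = "segmentation_result")
}

#' Split a food mesh into items from seed points
#'
#' One 3D seed point per item replaces interactive item selection. Faces are
#' assigned to the nearest seed by a geodesic flood fill over the face
#' adjacency graph (edge cost = centroid distance), with flood boundaries at
#' concave creases whose dihedral exceeds `crease_angle` — the valley where
#' two touching items meet. Faces a flood cannot reach get the Euclidean
#' nearest seed.
#'
#' @param mesh a [triangle_mesh].
#' @param seeds numeric matrix, one row per item, columns x/y/z (cm).
#' @param crease_angle dihedral angle (degrees) above which a concave crease
#'   blocks the flood.
#' @return A list of [triangle_mesh] objects, one per seed; their faces
#'   partition the input faces.
#' @export
split_items <- function(mesh, seeds, crease_angle = 50) {
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L) stop("seeds must be x,y,z triplets")
  if (nrow(seeds) < 1L) stop("at least one seed required")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  nf <- nrow(mesh$faces)
  if (nf == 0L) stop("mesh has no faces")
  ctr <- face_centroids(mesh$vertices, mesh$faces)
  if (nrow(seeds) == 1L) {
    return(list(submesh(mesh, seq_len(nf), label = "item_1")))
  }
  adj <- face_adjacency(mesh)
  nrm <- face_normals(mesh$vertices, mesh$faces)
  f1 <- adj[, 1]; f2 <- adj[, 2]
  dihedral <- acos(pmin(1, pmax(-1, rowSums(nrm[f1, , drop = FALSE] *
                                            nrm[f2, , drop = FALSE])))) * 180 / pi
  step <- ctr[f2, , drop = FALSE] - ctr[f1, , drop = FALSE]
  concave <- rowSums(nrm[f1, , drop = FALSE] * step) > 0
  keep <- !(concave & dihedral > crease_angle)
  w <- sqrt(rowSums(step * step))
  g <- igraph::graph_from_edgelist(adj[keep, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  seed_faces <- apply(seeds, 1, function(s) {
    which.min(rowSums(sweep(ctr, 2, s)^2))
  })
  d <- igraph::distances(g, v = seed_faces, weights = w[keep])
  assign <- apply(d, 2, which.min)
  unreachable <- apply(d, 2, function(col) all(!is.finite(col)))
  if (any(unreachable)) {
    for (i in which(unreachable)) {
      assign[i] <- which.min(rowSums(sweep(seeds, 2, ctr[i, ])^2))
    }
  }
  lapply(seq_len(nrow(seeds)), function(k) {
    submesh(mesh, which(assign == k), label = paste0("item_", k))
  })
}

# faces of a sub-selection, with unreferenced vertices dropped
submesh <- function(mesh, face_ids, label = NULL) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3), label = label)
}

# connected component id per face (edge-sharing adjacency)
face_components <- function(mesh) {
  nf <- nrow(mesh$faces)
  adj <- face_adjacency(mesh)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  igraph::components(g)$membership
}

# pairs of faces sharing an edge (m x 2 matrix)
face_adjacency <- function(mesh) {
  nf <- nrow(mesh$faces)
  he <- half_edges(mesh$faces)
  fid <- rep(seq_len(nf), 3L)
  keys <- edge_keys(he)
  ord <- order(keys)
  keys <- keys[ord]; fid <- fid[ord]
  same <- which(keys[-1] == keys[-length(keys)])
  cbind(fid[same], fid[same + 1L])
}

# --- small deterministic RNG helpers (no global RNG state touched) ---

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- as.double(seed %% 2147483647L)
  if (env$state == 0) env$state <- 1
  env
}

# Lehmer / Park-Miller uniform draws in (0,1)
runif_rng <- function(rng, n) {
  out <- numeric(n)
  st <- rng$state
  for (i in seq_len(n)) {
    st <- (st * 48271) %% 2147483647
    out[i] <- st / 2147483647
  }
  rng$state <- st
  out
}

sample_int <- function(rng, n, k) {
  # distinct draws by rejection; n >> k in practice
  picked <- integer(0)
  while (length(picked) < k) {
    cand <- floor(runif_rng(rng, k - length(picked)) * n) + 1
    picked <- unique(c(picked, as.integer(cand)))
  }
  picked
}

# standard normals via Box-Muller on the local RNG
rnorm_rng <- function(rng, n) {
  m <- ceiling(n / 2)
  u1 <- pmax(runif_rng(rng, m), 1e-12)
  u2 <- runif_rng(rng, m)
  r <- sqrt(-2 * log(u1))
  z <- c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))
  z[seq_len(n)]
}
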