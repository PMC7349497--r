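#' Hole-filling configuration
#'
#' @param epsilon_factor the vertex-merge radius epsilon for each hole is
#'   `epsilon_factor` times the mean boundary-edge length of that hole's loop.
#' @param max_iter_factor advancing-front iteration bound, as a multiple of
#'   the loop size; exceeded means the front failed to close.
#' @param cot_clamp cotangent weights are clamped to `[-cot_clamp, cot_clamp]`
#'   for robustness on skinny triangles.
#' @param planarity_tolerance distance (cm) within which refined patch
#'   vertices over a planar hole are expected to stay in its plane.
#' @return A `fill_config` list.
#' @export
fill_config <- function(epsilon_factor = 0.5, max_iter_factor = 10,
                        cot_clamp = 1e6, planarity_tolerance = 1e-8) {
  stopifnot(epsilon_factor >= 0, max_iter_factor >= 1, cot_clamp > 0)
  structure(list(epsilon_factor = epsilon_factor,
                 max_iter_factor = max_iter_factor,
                 cot_clamp = cot_clamp,
                 planarity_tolerance = planarity_tolerance),
            class = "fill_config")
}

#' Fill one hole with an advancing-front patch
#'
#' Grows triangles inward from the hole boundary (the "front"). Each
#' iteration picks the front vertex with the smallest interior angle theta
#' (ties broken by lowest vertex index) and applies one of three rules:
#' \describe{
#'   \item{theta <= 75 deg}{connect the two neighbouring front vertices
#'     directly into one triangle;}
#'   \item{75 < theta <= 135 deg}{add one vertex on the angle bisector, in
#'     the plane of the two boundary edges, at their average length;}
#'   \item{theta > 135 deg}{add two vertices on the angle trisectors, same
#'     plane, average edge length.}
#' }
#' A candidate vertex closer than `epsilon` to an existing front vertex is
#' replaced by that vertex (choosing, among several, the one whose triangle
#' is closest to equilateral); such merges can split the front, and each
#' sub-front is processed in turn. The front closes with a final triangle
#' when three vertices remain.
#'
#' @param mesh a [triangle_mesh].
#' @param loop a `boundary_loop` from [find_holes()].
#' @param epsilon merge radius (cm); `NULL` uses half the loop's mean
#'   boundary-edge length.
#' @param max_iter_factor iteration bound multiplier (see [fill_config()]).
#' @return A `patch_fill`: list with `new_vertices` (matrix of added points),
#'   `new_faces` (triangles indexing the mesh's vertices followed by the new
#'   ones), `free` (indices of added vertices in the combined numbering,
#'   movable by [harmonic_refine()]), and `boundary` (the loop's fixed
#'   vertices).
#' @export
afm_fill <- function(mesh, loop, epsilon = NULL, max_iter_factor = 10) {
  front0 <- loop$vertices
  k <- length(front0)
  if (k < 3L) stop("boundary loop has fewer than 3 vertices")
  V <- mesh$vertices
  nv0 <- nrow(V)
  P <- V[front0, , drop = FALSE]
  edge_len <- sqrt(rowSums((P - P[c(2:k, 1), , drop = FALSE])^2))
  if (is.null(epsilon)) epsilon <- 0.5 * mean(edge_len)
  if (epsilon < 0) stop("epsilon must be >= 0")
  fallback_n <- newell_normal(P)

  new_faces <- list()
  fronts <- list(front0)
  max_iter <- max(ceiling(max_iter_factor * k), 20L)
  iter <- 0L

  add_face <- function(a, b, c) {
    if (a == b || b == c || a == c) return(invisible(NULL))
    ar <- face_areas(V, matrix(c(a, b, c), 1))
    if (ar <= 1e-10) return(invisible(NULL))
    new_faces[[length(new_faces) + 1L]] <<- c(a, b, c)
    invisible(NULL)
  }

  # quality in (0,1], 1 for equilateral: 4*sqrt(3)*area / sum of squared edges
  tri_quality <- function(a, b, c) {
    e2 <- sum((V[a, ] - V[b, ])^2) + sum((V[b, ] - V[c, ])^2) +
      sum((V[c, ] - V[a, ])^2)
    if (e2 == 0) return(0)
    4 * sqrt(3) * face_areas(V, matrix(c(a, b, c), 1)) / e2
  }

  # merge a candidate position into an existing front vertex if one lies
  # within epsilon; returns a vertex id (possibly new) in combined numbering
  place_vertex <- function(pos, front, v_prev, v_i, v_next) {
    cand <- setdiff(front, v_i)
    if (length(cand) > 0L && epsilon > 0) {
      d <- sqrt(rowSums(sweep(V[cand, , drop = FALSE], 2, pos)^2))
      near <- cand[d < epsilon]
      if (length(near) > 0L) {
        if (length(near) > 1L) {
          q <- vapply(near, function(ve) {
            min(tri_quality(v_prev, v_i, ve), tri_quality(ve, v_i, v_next))
          }, numeric(1))
          near <- near[which.max(q)]
        }
        return(near[1])
      }
    }
    V <<- rbind(V, pos)
    nrow(V)
  }

  while (length(fronts) > 0L) {
    front <- fronts[[1]]
    fronts <- fronts[-1]
    repeat {
      if (length(front) < 3L) break          # healed seam, nothing to add
      if (length(front) == 3L) {
        add_face(front[3], front[2], front[1])
        break
      }
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("advancing front failed to close after ", max_iter,
             " iterations (epsilon too large for this hole?)")
      }
      m <- length(front)
      Pf <- V[front, , drop = FALSE]
      nrm <- newell_normal(Pf)
      if (all(nrm == 0)) nrm <- fallback_n
      theta <- interior_angles_n(Pf, nrm)
      pick <- order(theta, front)[1]
      i_prev <- if (pick == 1L) m else pick - 1L
      i_next <- if (pick == m) 1L else pick + 1L
      v_prev <- front[i_prev]; v_i <- front[pick]; v_next <- front[i_next]
      th <- theta[pick]
      u <- V[v_prev, ] - V[v_i, ]
      w <- V[v_next, ] - V[v_i, ]
      len_avg <- (sqrt(sum(u^2)) + sqrt(sum(w^2))) / 2

      if (th <= 75) {
        add_face(v_next, v_i, v_prev)
        repl <- integer(0)
      } else {
        # in-plane direction at angle phi (deg), rotating from the edge to
        # v_next counter-clockwise (around the front normal) into the hole
        dir_at <- function(phi) {
          b <- normalize3(w)
          p <- b - sum(b * nrm) * nrm
          if (sqrt(sum(p * p)) < 1e-12) {
            p <- cross3(nrm, normalize3(u))[1, ]   # near-collinear: stabilize
          }
          p <- normalize3(p)
          q <- cross3(nrm, p)[1, ]
          phi <- phi * pi / 180
          cos(phi) * p + sin(phi) * q
        }
        if (th <= 135) {
          pos <- V[v_i, ] + len_avg * dir_at(th / 2)
          vn <- place_vertex(pos, front, v_prev, v_i, v_next)
          add_face(vn, v_i, v_prev)
          add_face(v_next, v_i, vn)
          repl <- vn
        } else {
          # vn1 neighbours v_prev on the new front, vn2 neighbours v_next;
          # dir_at rotates from the v_next edge, so vn1 is at 2/3 theta
          pos1 <- V[v_i, ] + len_avg * dir_at(2 * th / 3)
          pos2 <- V[v_i, ] + len_avg * dir_at(th / 3)
          vn1 <- place_vertex(pos1, front, v_prev, v_i, v_next)
          vn2 <- place_vertex(pos2, front, v_prev, v_i, v_next)
          add_face(vn1, v_i, v_prev)
          add_face(vn2, v_i, vn1)
          add_face(v_next, v_i, vn2)
          repl <- unique(c(vn1, vn2))
        }
        repl <- repl[!(repl %in% c(v_prev, v_next))]
      }
      front <- append(front[-pick], repl, after = i_prev - (pick < i_prev))
      # a merge can make the front visit a vertex twice: split there
      pieces <- split_front(front)
      front <- pieces[[1]]
      if (length(pieces) > 1L) fronts <- c(fronts, pieces[-1])
    }
  }

  nf <- if (length(new_faces)) do.call(rbind, new_faces) else
    matrix(integer(0), ncol = 3)
  structure(list(
    new_vertices = V[seq_len(nrow(V)) > nv0, , drop = FALSE],
    new_faces = nf,
    free = seq_len(nrow(V))[seq_len(nrow(V)) > nv0],
    boundary = front0),
    class = "patch_fill")
}

# split a cyclic front at duplicated vertices into simple cycles
split_front <- function(front) {
  dup <- front[duplicated(front)]
  if (length(dup) == 0L) return(list(front))
  x <- dup[1]
  pos <- which(front == x)
  p <- pos[1]; q <- pos[2]
  a <- front[p:(q - 1L)]
  b <- front[c(q:length(front), seq_len(p - 1L))]
  c(split_front(a), split_front(b))
}

# interior_angles with an externally supplied normal (front may be degenerate)
interior_angles_n <- function(P, n) {
  k <- nrow(P)
  prv <- c(k, seq_len(k - 1))
  nxt <- c(2:k, 1)
  u <- P[prv, , drop = FALSE] - P
  w <- P[nxt, , drop = FALSE] - P
  lu <- sqrt(rowSums(u * u)); lw <- sqrt(rowSums(w * w))
  lu[lu == 0] <- 1; lw[lw == 0] <- 1
  cosang <- pmin(1, pmax(-1, rowSums(u * w) / (lu * lw)))
  raw <- acos(cosang)
  s <- rowSums(cross3(w, u) * matrix(n, k, 3, byrow = TRUE))
  ifelse(s >= 0, raw, 2 * pi - raw) * 180 / pi
}

#' Harmonically refine a patch
#'
#' Repositions the patch's interior (newly created) vertices by solving the
#' cotangent-Laplacian system `sum_j w_ij (f(v_j) - f(v_i)) = 0` per
#' coordinate, with `w_ij = cot(alpha_ij) + cot(beta_ij)` over the two
#' triangles incident to edge `(i, j)` and all original mesh and boundary
#' vertices held fixed. This minimises the discrete Dirichlet energy of the
#' patch: the fill relaxes to the membrane (harmonic) surface spanning the
#' hole. Topology is unchanged. Angles below 1e-4 rad are treated as 1e-4
#' and cotangents clamped for robustness on skinny triangles.
#'
#' @param mesh the [triangle_mesh] the patch was built on.
#' @param patch a `patch_fill` from [afm_fill()].
#' @param cot_clamp cotangent clamp (see [fill_config()]).
#' @return A [triangle_mesh] containing the original faces plus the refined
#'   patch. Vertices away from the patch are bit-identical to the input.
#' @export
harmonic_refine <- function(mesh, patch, cot_clamp = 1e6) {
  V <- rbind(mesh$vertices, patch$new_vertices)
  faces_all <- rbind(mesh$faces, patch$new_faces)
  free <- patch$free
  if (length(free) == 0L) {
    return(triangle_mesh(V, faces_all, label = mesh$label))
  }
  pf <- patch$new_faces
  # cotangent weights per undirected edge, accumulated over patch triangles
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (corner in 1:3) {
    a <- pf[, corner]
    b <- pf[, corner %% 3 + 1]
    cc <- pf[, (corner + 1) %% 3 + 1]
    # angle at a, opposite edge (b, cc)
    e1 <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    e2 <- V[cc, , drop = FALSE] - V[a, , drop = FALSE]
    l1 <- sqrt(rowSums(e1 * e1)); l2 <- sqrt(rowSums(e2 * e2))
    ang <- acos(pmin(1, pmax(-1, rowSums(e1 * e2) / (l1 * l2))))
    ang <- pmin(pmax(ang, 1e-4), pi - 1e-4)
    cotv <- pmin(pmax(1 / tan(ang), -cot_clamp), cot_clamp)
    ii <- c(ii, b); jj <- c(jj, cc); ww <- c(ww, cotv)
  }
  # symmetrize onto undirected edges
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  key <- paste(lo, hi, sep = "_")
  wsum <- tapply(ww, key, sum)
  ek <- strsplit(names(wsum), "_", fixed = TRUE)
  ei <- vapply(ek, function(x) as.integer(x[1]), integer(1))
  ej <- vapply(ek, function(x) as.integer(x[2]), integer(1))
  wv <- as.numeric(wsum)

  nfree <- length(free)
  row_of <- integer(nrow(V))
  row_of[free] <- seq_len(nfree)
  is_free <- row_of > 0

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  rhs <- matrix(0, nfree, 3)
  add_entry <- function(i, j, w) {
    # contribution of edge (i, j) with weight w to row of free vertex i
    ri <- row_of[i]
    ti <<- c(ti, ri); tj <<- c(tj, ri); tx <<- c(tx, w)   # diagonal
    if (is_free[j]) {
      ti <<- c(ti, ri); tj <<- c(tj, row_of[j]); tx <<- c(tx, -w)
    } else {
      rhs[ri, ] <<- rhs[ri, ] + w * V[j, ]
    }
  }
  for (e in seq_along(wv)) {
    if (is_free[ei[e]]) add_entry(ei[e], ej[e], wv[e])
    if (is_free[ej[e]]) add_entry(ej[e], ei[e], wv[e])
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nfree, nfree))
  diag_a <- Matrix::diag(A)
  if (any(diag_a == 0)) {
    bad <- free[which(diag_a == 0)[1]]
    stop("singular harmonic system: vertex ", bad,
         " has a degenerate 1-ring")
  }
  sol <- tryCatch(as.matrix(Matrix::solve(A, rhs)),
                  error = function(e) stop("singular harmonic system: ",
                                           conditionMessage(e)))
  V[free, ] <- sol
  triangle_mesh(V, faces_all, label = mesh$label)
}

#' Fill every hole in a mesh
#'
#' Detects boundary loops, fills each with [afm_fill()] (largest loop first,
#' for a deterministic order) and refines each patch with
#' [harmonic_refine()]. A closed mesh is returned unchanged.
#'
#' @param mesh an edge-manifold [triangle_mesh].
#' @param cfg a [fill_config()].
#' @return A watertight [triangle_mesh].
#' @examples
#' open_cube <- puncture(make_cube(7), c(3.5, 3.5, 7), 3)
#' filled <- fill_all_holes(open_cube)
#' inspect(filled)$n_boundary_edges
#' @export
fill_all_holes <- function(mesh, cfg = fill_config()) {
  loops <- find_holes(mesh)
  if (length(loops) == 0L) return(mesh)
  ord <- order(-vapply(loops, function(l) length(l$vertices), integer(1)))
  for (li in ord) {
    loop <- loops[[li]]
    P <- mesh$vertices[loop$vertices, , drop = FALSE]
    k <- nrow(P)
    eps <- cfg$epsilon_factor *
      mean(sqrt(rowSums((P - P[c(2:k, 1), , drop = FALSE])^2)))
    patch <- tryCatch(
      afm_fill(mesh, loop, epsilon = eps,
               max_iter_factor = cfg$max_iter_factor),
      error = function(e) stop("hole ", li, ": ", conditionMessage(e)))
    mesh <- tryCatch(
      harmonic_refine(mesh, patch, cot_clamp = cfg$cot_clamp),
      error = function(e) stop("hole ", li, ": ", conditionMessage(e)))
  }
  mesh
}
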