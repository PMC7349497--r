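inner_loop <- function(mesh, k) {
  holes <- find_holes(mesh)
  holes[[which(vapply(holes, function(h) all(h$vertices <= k), logical(1)))]]
}

test_that("a triangular hole closes with one triangle and no new vertices", {
  m <- ring_around_polygon(regular_polygon(3, 2))
  patch <- afm_fill(m, inner_loop(m, 3))
  expect_equal(nrow(patch$new_vertices), 0L)
  expect_equal(nrow(patch$new_faces), 1L)
  expect_setequal(as.vector(patch$new_faces), 1:3)
})

test_that("a square hole starts with the bisector rule: one mid-angle vertex", {
  cube <- make_cube(7)
  open_cube <- triangle_mesh(cube$vertices, cube$faces[-(3:4), ])
  loop <- find_holes(open_cube)[[1]]
  patch <- afm_fill(open_cube, loop, epsilon = 0)  # no merging: raw rule
  expect_equal(nrow(patch$new_vertices), 1L)
  vn <- patch$new_vertices[1, ]
  # picked front vertex: all angles tie at 90, lowest index wins
  vi_id <- min(loop$vertices)
  pos <- loop$vertices == vi_id
  k <- length(loop$vertices)
  vi <- cube$vertices[vi_id, ]
  nbrs <- loop$vertices[c(which(pos) %% k + 1L, (which(pos) - 2L) %% k + 1L)]
  e1 <- cube$vertices[nbrs[1], ] - vi
  e2 <- cube$vertices[nbrs[2], ] - vi
  d <- vn - vi
  # on the bisector: equal angles to both edges; at the mean edge length
  a1 <- acos(sum(d * e1) / sqrt(sum(d^2) * sum(e1^2)))
  a2 <- acos(sum(d * e2) / sqrt(sum(d^2) * sum(e2^2)))
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_equal(sqrt(sum(d^2)), (sqrt(sum(e1^2)) + sqrt(sum(e2^2))) / 2,
               tolerance = 1e-9)
  # in the plane of the two edges (the removed face's plane)
  expect_equal(vn[3], 7, tolerance = 1e-9)
})

test_that("a reflex front vertex adds two vertices on the trisectors", {
  k <- 36                                   # regular 36-gon: theta = 170
  m <- ring_around_polygon(regular_polygon(k, 3))
  loop <- inner_loop(m, k)
  expect_equal(loop$theta, rep(170, k), tolerance = 1e-9)
  patch <- afm_fill(m, loop)                # first step is unmerged
  expect_gte(nrow(patch$new_vertices), 2L)
  # the first step emits faces (vn1, vi, v_prev), (vn2, vi, vn1),
  # (v_next, vi, vn2): recover the pivot and its boundary edges from them
  vi_id <- patch$new_faces[1, 2]
  vi <- m$vertices[vi_id, ]
  e1 <- m$vertices[patch$new_faces[1, 3], ] - vi
  e2 <- m$vertices[patch$new_faces[3, 1], ] - vi
  L <- (sqrt(sum(e1^2)) + sqrt(sum(e2^2))) / 2
  d1 <- patch$new_vertices[1, ] - vi
  d2 <- patch$new_vertices[2, ] - vi
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  # trisection: edge-to-new, new-to-new, new-to-edge all 170/3 degrees
  spans <- sort(c(ang(e1, d1), ang(e1, d2)))
  expect_equal(spans[1], 170 / 3, tolerance = 1e-6)
  expect_equal(ang(d1, d2), 170 / 3, tolerance = 1e-6)
  expect_equal(min(ang(e2, d1), ang(e2, d2)), 170 / 3, tolerance = 1e-6)
  expect_equal(sqrt(sum(d1^2)), L, tolerance = 1e-9)
  expect_equal(sqrt(sum(d2^2)), L, tolerance = 1e-9)
  expect_equal(unname(abs(patch$new_vertices[1:2, 3])), c(0, 0))  # in-plane
})

test_that("a candidate vertex within epsilon reuses the existing one", {
  # rectangle hole 1 x 0.8: the bisector candidate from one corner lands
  # 0.4 * epsilon away from the opposite corner when epsilon = 1
  m <- ring_around_polygon(rbind(c(0, 0), c(1, 0), c(1, 0.8), c(0, 0.8)))
  loop <- inner_loop(m, 4)
  patch <- afm_fill(m, loop, epsilon = 1)
  expect_equal(nrow(patch$new_vertices), 0L)
  expect_equal(nrow(patch$new_faces), 2L)
  filled <- harmonic_refine(m, patch)
  # only the outer rectangle boundary remains open
  expect_equal(inspect(filled)$n_boundary_edges, 4L)
})

test_that("filling requires at least a 3-vertex loop and bounded iterations", {
  m <- ring_around_polygon(regular_polygon(4, 2))
  bad <- structure(list(vertices = c(1L, 2L), theta = c(90, 90)),
                   class = "boundary_loop")
  expect_error(afm_fill(m, bad), "fewer than 3")
})

test_that("planar holes fill coplanar with area recovered within 0.5%", {
  for (k in c(6, 12, 20)) {
    poly <- regular_polygon(k, 3)
    m <- ring_around_polygon(poly)
    loop <- inner_loop(m, k)
    patch <- afm_fill(m, loop)
    refined <- harmonic_refine(m, patch)
    # coplanarity of every patch vertex (z = 0 plane)
    if (nrow(patch$new_vertices) > 0) {
      idx <- nrow(m$vertices) + seq_len(nrow(patch$new_vertices))
      expect_lt(max(abs(refined$vertices[idx, 3])), 1e-8)
    }
    patch_area <- sum(mealvol:::face_areas(refined$vertices,
                                           patch$new_faces))
    true_area <- k / 2 * 3^2 * sin(2 * pi / k)   # regular polygon area
    expect_lt(abs(patch_area - true_area) / true_area, 0.005)
  }
})

test_that("one free vertex ringed by a regular hexagon relaxes to its centroid", {
  # symmetric fan: the six cotangent weights are equal, so the 1x1 system
  # solves by hand to the weighted mean of the ring = the hexagon centroid
  hex <- cbind(regular_polygon(6, 1), 0)
  base <- triangle_mesh(hex, matrix(integer(0), ncol = 3))
  fan <- function(start) structure(list(
    new_vertices = matrix(start, 1),
    new_faces = cbind(1:6, c(2:6, 1), 7L),
    free = 7L, boundary = 1:6), class = "patch_fill")
  refined <- harmonic_refine(base, fan(c(0, 0, 0.4)))  # lifted off-plane
  expect_equal(refined$vertices[7, ], colMeans(hex), tolerance = 1e-10)
  # cotangent weights reproduce linear functions: a vertex already in the
  # ring's plane satisfies the harmonic equation wherever it sits
  refined2 <- harmonic_refine(base, fan(c(0.3, -0.2, 0)))
  expect_equal(refined2$vertices[7, ], c(0.3, -0.2, 0), tolerance = 1e-9)
})

test_that("a spherical cap patch is depressed but stays inside the cap box", {
  dome <- make_dome(4, 16, 32)
  holed <- puncture(dome, c(0, 0, 4), 1.6)   # blind spot at the apex
  removed <- setdiff(seq_len(n_faces(dome)), integer(0))
  loop <- find_holes(holed)[[2]]             # rim is loop 1 (larger)
  if (length(find_holes(holed)[[1]]$vertices) <
      length(find_holes(holed)[[2]]$vertices)) loop <- find_holes(holed)[[1]]
  patch <- afm_fill(holed, loop)
  refined <- harmonic_refine(holed, patch)
  idx <- nrow(holed$vertices) + seq_len(nrow(patch$new_vertices))
  ring <- holed$vertices[loop$vertices, , drop = FALSE]
  # maximum principle: each coordinate within the boundary ring's range;
  # the membrane fill sits at or below the cap it replaces
  for (d in 1:3) {
    expect_gte(min(refined$vertices[idx, d]), min(ring[, d]) - 1e-6)
    expect_lte(max(refined$vertices[idx, d]), max(ring[, d]) + 1e-6)
  }
  expect_lt(max(refined$vertices[idx, 3]), 4)
})

test_that("fill_all_holes leaves a closed mesh untouched", {
  cube <- make_cube(7)
  expect_identical(fill_all_holes(cube), cube)
})

test_that("an open cube refills watertight with volume error under 5%", {
  cube <- make_cube(7)
  open_cube <- triangle_mesh(cube$vertices, cube$faces[-(3:4), ])
  filled <- fill_all_holes(open_cube)
  expect_watertight(filled)
  v <- signed_volume(filled)$volume
  expect_lt(abs(v - 343) / 343, 0.05)
})

test_that("a blob with its bottom removed refills watertight", {
  s <- simulate_scan("apple", 8, seed = 11, noise = 0)
  expect_length(find_holes(s$degraded), 1L)
  filled <- fill_all_holes(s$degraded)
  expect_watertight(filled)
  err <- abs(signed_volume(filled)$volume - s$true_volume) / s$true_volume
  expect_lt(err, 0.05)
})

test_that("vertices away from the patch are bit-identical after filling", {
  s <- simulate_scan("mound", 7, seed = 9, noise = 0.02)
  filled <- fill_all_holes(s$degraded)
  n0 <- nrow(s$degraded$vertices)
  expect_identical(filled$vertices[seq_len(n0), ], s$degraded$vertices)
  expect_identical(filled$faces[seq_len(nrow(s$degraded$faces)), ],
                   s$degraded$faces)
})

test_that("patch vertex count is non-increasing in epsilon", {
  m <- ring_around_polygon(regular_polygon(12, 3))
  loop <- inner_loop(m, 12)
  mean_edge <- mean(sqrt(rowSums((m$vertices[loop$vertices, ] -
    m$vertices[loop$vertices[c(2:12, 1)], ])^2)))
  counts <- vapply(c(0, 0.25, 0.5, 1, 2) * mean_edge, function(eps) {
    nrow(afm_fill(m, loop, epsilon = eps)$new_vertices)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical input and config give identical filled meshes", {
  s <- simulate_scan("cone", c(3, 6), seed = 21, noise = 0.03)
  f1 <- fill_all_holes(s$degraded)
  f2 <- fill_all_holes(s$degraded)
  expect_identical(f1, f2)
})
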