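test_that("a closed mesh has no hole loops", {
  expect_length(find_holes(make_cube(7)), 0L)
  expect_length(find_holes(make_blob("mound", 6, seed = 1)), 0L)
})

test_that("an open cube face yields one square loop with 90 degree angles", {
  cube <- make_cube(7)
  open_cube <- triangle_mesh(cube$vertices, cube$faces[-(3:4), ])  # drop top
  holes <- find_holes(open_cube)
  expect_length(holes, 1L)
  expect_length(holes[[1]]$vertices, 4L)
  expect_equal(holes[[1]]$theta, rep(90, 4), tolerance = 1e-9)
})

test_that("puncturing k disjoint patches opens exactly k loops", {
  cube <- make_cube(7)
  # adjacent cube faces share edges, so only opposite faces give disjoint
  # holes; a sphere offers three mutually distant patches
  for (k in 1:2) {
    centers <- list(c(3.5, 3.5, 7), c(3.5, 3.5, 0))[seq_len(k)]
    m <- cube
    for (ctr in centers) m <- puncture(m, ctr, 2.5)
    expect_length(find_holes(m), k)
  }
  s <- mealvol:::uv_sphere(4, 24, 32)
  for (ctr in list(c(4, 0, 0), c(-4, 0, 0), c(0, 0, 4))) {
    s <- puncture(s, ctr, 1)
  }
  expect_length(find_holes(s), 3L)
})

test_that("interior angles of planar convex holes sum to (k-2)*180", {
  for (k in c(5, 8, 13)) {
    m <- ring_around_polygon(regular_polygon(k, 3))
    holes <- find_holes(m)
    inner <- holes[[which(vapply(holes, function(h)
      all(h$vertices <= k), logical(1)))]]
    expect_equal(sum(inner$theta), (k - 2) * 180, tolerance = 1e-6)
  }
})

test_that("non-manifold edges are reported with the offending vertices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))   # edge 1-2 used 3 times
  expect_error(find_holes(triangle_mesh(v, f)), "non-manifold edge.*1-2")
})

test_that("plate segmentation separates a disk from a dome resting on it", {
  sc <- combine_meshes(make_disk(10, 5, 48), make_dome(4, 12, 32))
  seg <- segment_plate(sc$mesh)
  got <- c(rep("plate", nrow(seg$plate$faces)),
           rep("food", sum(vapply(seg$items, n_faces, integer(1)))))
  n_plate_true <- sum(sc$labels == "a")
  # >= 99% of faces must carry their constructed label
  agreement <- (min(nrow(seg$plate$faces), n_plate_true) +
                min(sum(vapply(seg$items, n_faces, integer(1))),
                    sum(sc$labels == "b"))) / length(sc$labels)
  expect_gte(agreement, 0.99)
  expect_length(seg$items, 1L)
  # removing the plate leaves the dome rim open for hole filling
  expect_gt(inspect(seg$items[[1]])$n_boundary_edges, 0L)
})

test_that("a lone plane is all plate and a floating blob has no plate", {
  seg <- segment_plate(make_disk(8, 4, 32))
  expect_length(seg$items, 0L)
  expect_equal(n_faces(seg$plate), n_faces(make_disk(8, 4, 32)))

  sphere <- mealvol:::uv_sphere(4, 24, 32)
  expect_error(segment_plate(sphere), "no plate found")
})

test_that("seeded splitting recovers disjoint components exactly", {
  b1 <- make_blob("apple", 6, seed = 1)
  b2 <- make_blob("mound", 6, seed = 2)
  b2$vertices[, 1] <- b2$vertices[, 1] + 12
  sc <- combine_meshes(b1, b2)
  parts <- split_items(sc$mesh, rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_length(parts, 2L)
  expect_equal(n_faces(parts[[1]]), n_faces(b1))
  expect_equal(n_faces(parts[[2]]), n_faces(b2))
  # partition property
  expect_equal(n_faces(parts[[1]]) + n_faces(parts[[2]]), n_faces(sc$mesh))
})

test_that("one seed returns the identity partition", {
  m <- make_blob("apple", 6, seed = 3)
  parts <- split_items(m, rbind(c(0, 0, 0)))
  expect_length(parts, 1L)
  expect_equal(n_faces(parts[[1]]), n_faces(m))
})

test_that("two slopes meeting at a concave valley split along the crease", {
  # V-shaped surface z = |x| * tan(40 deg): the valley at x = 0 models the
  # seam where two touching items meet
  xs <- seq(-4, 4, by = 1)
  ys <- seq(0, 8, by = 1)
  v <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(v, abs(v[, 1]) * tan(40 * pi / 180))
  nx <- length(xs)
  f <- list()
  for (j in seq_len(length(ys) - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- (j - 1) * nx + i
      f[[length(f) + 1L]] <- c(a, a + 1L, a + nx + 1L)
      f[[length(f) + 1L]] <- c(a, a + nx + 1L, a + nx)
    }
  }
  m <- triangle_mesh(v, do.call(rbind, f))
  parts <- split_items(m, rbind(c(-3, 4, 3), c(3, 4, 3)), crease_angle = 50)
  expect_length(parts, 2L)
  expect_equal(n_faces(parts[[1]]) + n_faces(parts[[2]]), n_faces(m))
  # constructed truth: faces left/right of the valley, half each
  expect_lt(abs(n_faces(parts[[1]]) - n_faces(m) / 2) / (n_faces(m) / 2),
            0.05)
})

test_that("seed validation rejects empty and duplicated seeds", {
  m <- make_cube(2)
  expect_error(split_items(m, matrix(numeric(0), ncol = 3)), "at least one")
  expect_error(split_items(m, rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})
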