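# geometry fixtures built in code

# dense triangulated disk in the z = 0 plane (a plate stand-in)
make_disk <- function(radius = 10, n_rings = 5, n_seg = 48) {
  rs <- radius * seq_len(n_rings) / n_rings
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  rings <- do.call(rbind, lapply(rs, function(r) {
    cbind(r * cos(ang), r * sin(ang), 0)
  }))
  v <- rbind(c(0, 0, 0), rings)
  idx <- function(i, j) 1L + (i - 1L) * n_seg + (j - 1L) %% n_seg + 1L
  f <- list()
  for (j in seq_len(n_seg)) {
    f[[length(f) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(n_rings - 1L)) {
    for (j in seq_len(n_seg)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      f[[length(f) + 1L]] <- c(a, b, c2)
      f[[length(f) + 1L]] <- c(a, c2, d)
    }
  }
  triangle_mesh(v, do.call(rbind, f), label = "disk")
}

# open hemispherical dome of radius R resting on z = 0 (rim open)
make_dome <- function(R = 4, n_lat = 12, n_lon = 32) {
  elev <- pi / 2 * (seq_len(n_lat) - 1) / n_lat
  phi <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  v <- do.call(rbind, lapply(elev, function(e) {
    cbind(R * cos(e) * cos(phi), R * cos(e) * sin(phi), R * sin(e))
  }))
  apex <- nrow(v) + 1L
  v <- rbind(v, c(0, 0, R))
  idx <- function(i, j) (i - 1L) * n_lon + (j - 1L) %% n_lon + 1L
  f <- list()
  for (i in seq_len(n_lat - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      f[[length(f) + 1L]] <- c(a, b, c2)
      f[[length(f) + 1L]] <- c(a, c2, d)
    }
  }
  for (j in seq_len(n_lon)) {
    f[[length(f) + 1L]] <- c(idx(n_lat, j), idx(n_lat, j + 1L), apex)
  }
  triangle_mesh(v, do.call(rbind, f), label = "dome")
}

# two meshes side by side as one mesh; returns also the true face labels
combine_meshes <- function(a, b) {
  m <- triangle_mesh(rbind(a$vertices, b$vertices),
                     rbind(a$faces, b$faces + nrow(a$vertices)))
  list(mesh = m,
       labels = c(rep("a", nrow(a$faces)), rep("b", nrow(b$faces))))
}

# planar polygonal hole in a rectangular patch of surface: returns a mesh
# whose single hole has the given 2D polygon as boundary (z = 0 plane).
# Built as a ring of triangles between the polygon and an enclosing box.
ring_around_polygon <- function(poly_xy, pad = 2) {
  k <- nrow(poly_xy)
  lo <- apply(poly_xy, 2, min) - pad
  hi <- apply(poly_xy, 2, max) + pad
  # outer box sampled with the same vertex count for a clean strip
  t <- (seq_len(k) - 1) / k
  per <- function(s) {
    # point at parameter s along the box perimeter, s in [0,1)
    L <- c(hi[1] - lo[1], hi[2] - lo[2], hi[1] - lo[1], hi[2] - lo[2])
    d <- s * sum(L)
    if (d < L[1]) return(c(lo[1] + d, lo[2]))
    d <- d - L[1]
    if (d < L[2]) return(c(hi[1], lo[2] + d))
    d <- d - L[2]
    if (d < L[3]) return(c(hi[1] - d, hi[2]))
    d <- d - L[3]
    c(lo[1], hi[2] - d)
  }
  outer <- t(vapply(t, per, numeric(2)))
  v <- rbind(cbind(poly_xy, 0), cbind(outer, 0))
  f <- list()
  for (j in seq_len(k)) {
    a <- j; b <- j %% k + 1L          # inner (hole) polygon, CCW
    oa <- k + j; ob <- k + j %% k + 1L
    f[[length(f) + 1L]] <- c(a, oa, ob)
    f[[length(f) + 1L]] <- c(a, ob, b)
  }
  triangle_mesh(v, do.call(rbind, f))
}

# regular k-gon (CCW) of circumradius r
regular_polygon <- function(k, r = 1) {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(r * cos(ang), r * sin(ang))
}

expect_watertight <- function(mesh) {
  rep_ <- inspect(mesh)
  expect_equal(rep_$n_boundary_edges, 0L)
  expect_true(rep_$is_watertight)
}
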