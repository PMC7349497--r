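#' Closed cube mesh
#'
#' Axis-aligned cube with one corner at the origin: 8 vertices, 12 outward
#' counter-clockwise triangles. The reference solid for volumetric
#' validation (a 7 cm cube encloses exactly 343 cm^3).
#'
#' @param edge edge length (cm).
#' @return A watertight [triangle_mesh].
#' @export
make_cube <- function(edge) {
  stopifnot(edge > 0)
  e <- edge
  v <- rbind(c(0, 0, 0), c(e, 0, 0), c(e, e, 0), c(0, e, 0),
             c(0, 0, e), c(e, 0, e), c(e, e, e), c(0, e, e))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),      # bottom (z = 0)
             c(5, 6, 7), c(5, 7, 8),      # top (z = e)
             c(1, 2, 6), c(1, 6, 5),      # front (y = 0)
             c(2, 3, 7), c(2, 7, 6),      # right (x = e)
             c(3, 4, 8), c(3, 8, 7),      # back (y = e)
             c(4, 1, 5), c(4, 5, 8))      # left (x = 0)
  triangle_mesh(v, f, label = "cube")
}

#' Closed cone mesh
#'
#' Circular fan cone, apex up, base on z = 0. The inscribed polygonal base
#' makes the discrete volume approach `pi * r^2 * h / 3` from below as
#' `n_segments` grows.
#'
#' @param radius base radius (cm).
#' @param height height (cm).
#' @param n_segments number of base segments (>= 8).
#' @return A watertight [triangle_mesh].
#' @export
make_cone <- function(radius, height, n_segments = 64L) {
  stopifnot(radius > 0, height > 0, n_segments >= 8L)
  n <- as.integer(n_segments)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rim <- cbind(radius * cos(ang), radius * sin(ang), 0)
  v <- rbind(rim, c(0, 0, height), c(0, 0, 0))    # apex = n+1, base ctr = n+2
  nxt <- c(2:n, 1)
  f <- rbind(cbind(seq_len(n), nxt, n + 1L),      # lateral, outward
             cbind(n + 2L, nxt, seq_len(n)))      # base, outward (-z)
  triangle_mesh(v, f, label = "cone")
}

# closed latitude/longitude sphere triangulation with pole fans
uv_sphere <- function(radius = 1, n_lat = 24L, n_lon = 32L) {
  stopifnot(n_lat >= 3L, n_lon >= 3L)
  theta <- pi * seq_len(n_lat - 1L) / n_lat       # polar angle, poles apart
  phi <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  ring <- function(th) cbind(radius * sin(th) * cos(phi),
                             radius * sin(th) * sin(phi),
                             radius * cos(th))
  v <- do.call(rbind, lapply(theta, ring))
  north <- nrow(v) + 1L
  south <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) (i - 1L) * n_lon + (j - 1L) %% n_lon + 1L
  f <- list()
  for (j in seq_len(n_lon)) {                     # pole fans
    f[[length(f) + 1L]] <- c(north, idx(1L, j), idx(1L, j + 1L))
    f[[length(f) + 1L]] <- c(south, idx(n_lat - 1L, j + 1L), idx(n_lat - 1L, j))
  }
  for (i in seq_len(n_lat - 2L)) {                # quad strips
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      f[[length(f) + 1L]] <- c(a, c2, b)
      f[[length(f) + 1L]] <- c(a, d, c2)
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

#' Food-like blob meshes
#'
#' Deterministic stand-ins for whole food items: a deformed sphere with a
#' seeded smooth radial perturbation, shaped per kind — `apple` (slightly
#' oblate with a stem dimple), `croissant` (elongated, flattened, bent into
#' a crescent), `mound` (low ellipsoid, like a scoop of mashed potatoes).
#' Identical `seed` gives an identical mesh.
#'
#' @param kind one of `"apple"`, `"croissant"`, `"mound"`.
#' @param scale characteristic diameter (cm).
#' @param seed integer seed for the radial perturbation.
#' @param n_lat,n_lon sphere resolution.
#' @return A watertight [triangle_mesh].
#' @export
make_blob <- function(kind = c("apple", "croissant", "mound"), scale = 8,
                      seed = 1L, n_lat = 24L, n_lon = 32L) {
  kind <- match.arg(kind)
  stopifnot(scale > 0)
  rng <- local_rng(seed + 7919L)
  cf <- rnorm_rng(rng, 6) * 0.04                  # smooth bump coefficients
  m <- uv_sphere(1, n_lat, n_lon)
  v <- m$vertices
  r <- sqrt(rowSums(v^2))
  th <- acos(pmin(1, pmax(-1, v[, 3] / r)))       # polar angle from +z
  ph <- atan2(v[, 2], v[, 1])
  bump <- cf[1] * sin(2 * ph + cf[4] * 10) * sin(th) +
    cf[2] * cos(3 * ph + cf[5] * 10) * sin(th)^2 +
    cf[3] * cos(2 * th + cf[6] * 10)
  v <- v * (1 + bump)
  if (kind == "apple") {
    v[, 3] <- v[, 3] * 0.90
    dimple <- 0.22 * exp(-(th / 0.35)^2)          # stem well at the top
    v <- v * (1 - dimple)
  } else if (kind == "croissant") {
    v[, 1] <- v[, 1] * 1.5
    v[, 3] <- v[, 3] * 0.55
    v[, 2] <- v[, 2] + 0.35 * v[, 1]^2            # crescent bend
  } else {
    v[, 3] <- v[, 3] * 0.55
  }
  triangle_mesh(v * scale / 2, m$faces, label = kind)
}

#' Punch a hole in a mesh
#'
#' Removes every face whose centroid lies within `radius` of `center` —
#' emulating depth-scan blind spots such as an unseen bottom surface or the
#' occluded seam where two items touch. Vertices are untouched; nothing
#' else changes.
#'
#' @param mesh a [triangle_mesh].
#' @param center 3D point (cm).
#' @param radius cm; a radius covering no face centroid returns the mesh
#'   unchanged.
#' @return A [triangle_mesh] with the covered faces removed.
#' @export
puncture <- function(mesh, center, radius) {
  stopifnot(radius > 0, length(center) == 3L)
  ctr <- face_centroids(mesh$vertices, mesh$faces)
  d2 <- rowSums(sweep(ctr, 2, center)^2)
  keep <- d2 > radius^2
  triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                label = mesh$label)
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh$vertices, mesh$faces)
  ar <- face_areas(mesh$vertices, mesh$faces)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (corner in 1:3) {
    s <- rowsum(fn * ar, group = mesh$faces[, corner])
    rows <- as.integer(rownames(s))
    n[rows, ] <- n[rows, ] + s
  }
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

#' Simulate a degraded depth-sensor capture
#'
#' Builds a closed ground-truth solid, perturbs its vertices with Gaussian
#' noise along vertex normals (the desk-scale proxy for depth error along
#' the view ray), then punches the requested holes. Fully reproducible from
#' `seed`.
#'
#' @param shape `"cube"`, `"cone"`, `"apple"`, `"croissant"` or `"mound"`.
#' @param size for a cube the edge (cm); for a cone `c(radius, height)`;
#'   for blobs the scale.
#' @param punctures list of `list(center =, radius =)` holes, or the string
#'   `"auto"` for one shape-appropriate blind spot (top patch for a cube,
#'   lateral patch for a cone, bottom cap for blobs).
#' @param noise Gaussian noise standard deviation along vertex normals (cm).
#' @param seed integer seed driving noise and blob shape.
#' @return A `scan_scenario` list: `ground_truth` (closed mesh),
#'   `true_volume` (cm^3, from [signed_volume()] of the ground truth),
#'   `degraded` (noised, punched mesh), `holes` (descriptors with faces
#'   removed and area fraction), `noise`, `seed`.
#' @export
simulate_scan <- function(shape, size, punctures = "auto", noise = 0.02,
                          seed = 1L) {
  stopifnot(noise >= 0)
  gt <- switch(shape,
    cube = make_cube(size),
    cone = make_cone(size[1], size[2]),
    apple = ,
    croissant = ,
    mound = make_blob(shape, scale = size, seed = seed),
    stop("unknown shape '", shape, "'"))
  true_vol <- signed_volume(gt)$volume

  degraded <- gt
  if (noise > 0) {
    rng <- local_rng(seed + 104729L)
    vn <- vertex_normals(gt)
    amp <- rnorm_rng(rng, nrow(gt$vertices)) * noise
    degraded <- triangle_mesh(gt$vertices + vn * amp, gt$faces,
                              label = gt$label)
  }
  if (identical(punctures, "auto")) {
    punctures <- list(default_puncture(shape, size))
  }
  holes <- list()
  for (p in punctures) {
    before <- nrow(degraded$faces)
    area_all <- sum(face_areas(degraded$vertices, degraded$faces))
    degraded <- puncture(degraded, p$center, p$radius)
    area_rem <- area_all - sum(face_areas(degraded$vertices, degraded$faces))
    holes[[length(holes) + 1L]] <- list(
      center = p$center, radius = p$radius,
      n_faces_removed = before - nrow(degraded$faces),
      area_fraction = area_rem / area_all)
  }
  structure(list(ground_truth = gt, true_volume = true_vol,
                 degraded = degraded, holes = holes, noise = noise,
                 seed = seed),
            class = "scan_scenario")
}

# one blind-spot hole sized well under 15% of the surface area
default_puncture <- function(shape, size) {
  switch(shape,
    cube = {
      e <- size                      # one triangle of the top face (1/12)
      list(center = c(2 * e / 3, e / 3, e), radius = 0.2 * e)
    },
    cone = {
      r <- size[1]; h <- size[2]     # patch on the lateral surface
      list(center = c(r * 0.75, 0, h * 0.25), radius = 0.35 * r)
    },
    {
      s <- size                      # unseen bottom cap
      list(center = c(0, 0, -s / 2), radius = 0.22 * s)
    })
}

#' Deterministic validation suite of cube and cone scan scenarios
#'
#' Twelve scenarios — cubes with edges 5 to 10 cm and cones with radii 2 to
#' 4 cm and heights 4 to 8 cm — each with one blind-spot puncture (well
#' under 15% of the surface area) and normal-direction Gaussian noise
#' cycling through 0 to 0.05 cm. Used to measure mean volumetric recovery
#' accuracy of the full hole-filling pipeline.
#'
#' @param seed base integer seed; scenario `i` uses `seed + i`.
#' @return List of `scan_scenario` objects.
#' @export
scan_suite <- function(seed = 1L) {
  noise_levels <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05)
  scenarios <- list()
  edges <- 5:10
  for (i in seq_along(edges)) {
    scenarios[[length(scenarios) + 1L]] <- simulate_scan(
      "cube", edges[i], noise = noise_levels[i], seed = seed + i)
  }
  cone_dims <- list(c(2, 4), c(2.5, 5), c(3, 6), c(3.5, 7), c(4, 8),
                    c(3, 8))
  for (i in seq_along(cone_dims)) {
    scenarios[[length(scenarios) + 1L]] <- simulate_scan(
      "cone", cone_dims[[i]], noise = noise_levels[i],
      seed = seed + 100L + i)
  }
  scenarios
}
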