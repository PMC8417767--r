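# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small folded pair (642 vertices) + decimation, for fast orientation tests
small_pair <- function() fixture("small_pair", function() {
  make_cortical_pair(subdivisions = 3, fold_amplitude_mm = 3, fold_degree = 6,
                     thickness_mm = 2.5, seed = 42)
})
small_dec <- function() fixture("small_dec", function() decimate_pair(small_pair(), 10))

# concentric-sphere pair (analytic limit; acceptance-scale resolution)
sphere_pair <- function() fixture("sphere_pair", function() {
  make_cortical_pair(subdivisions = 4, fold_amplitude_mm = 0, thickness_mm = 2.5,
                     seed = 1)
})
sphere_dec <- function() fixture("sphere_dec", function() decimate_pair(sphere_pair(), 10))

# full-size pair matching the simulation experiments (2562 vertices)
big_pair <- function() fixture("big_pair", function() {
  make_cortical_pair(subdivisions = 4, fold_amplitude_mm = 3, fold_degree = 8,
                     thickness_mm = 2.5, seed = derive_seed(1, "anatomy"))
})
big_dec <- function() fixture("big_dec", function() decimate_pair(big_pair(), 10))

small_helmet <- function() fixture("small_helmet", function() {
  make_helmet(n_sensors = 60, radius_mm = 110)
})

# inversion-ready small setup: basis, reference field, distances
small_setup <- function() fixture("small_setup", function() {
  dec <- small_dec()
  mesh <- dec$pair$pial
  center <- fit_sphere_center(mesh$vertices)
  list(dec = dec, mesh = mesh, center = center,
       basis = sphere_leadfield_basis(mesh$vertices, small_helmet(), center),
       ref = link_vectors(dec$pair),
       dist = megorient:::geodesic_distance_matrix(mesh))
})

# planar grid mesh (n x n vertices in the z = 0 plane, spacing 1 mm)
grid_mesh <- function(n = 5) {
  xy <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(xy$x, xy$y, 0)
  f <- NULL
  idx <- function(i, j) (j - 1) * n + i
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(v, f)
}

# straight chain of vertices 1 mm apart, triangulated as a thin strip
chain_mesh <- function(n = 6) {
  v <- rbind(cbind(seq_len(n) - 1, 0, 0), cbind(seq_len(n) - 1, 100, 0))
  f <- NULL
  for (i in seq_len(n - 1)) {
    f <- rbind(f, c(i, i + 1, n + i), c(i + 1, n + i + 1, n + i))
  }
  triangle_mesh(v, f)
}

# independent brute-force all-pairs shortest path (Floyd-Warshall)
brute_force_geodesics <- function(mesh) {
  n <- mesh$n_vertices
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  for (k in seq_len(nrow(e))) {
    D[e[k, 1], e[k, 2]] <- min(D[e[k, 1], e[k, 2]], w[k])
    D[e[k, 2], e[k, 1]] <- D[e[k, 1], e[k, 2]]
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# rigid rotation applied to a mesh / pair
rotate_mesh <- function(mesh, R) triangle_mesh(mesh$vertices %*% t(R), mesh$faces,
                                               validate = FALSE)
rotate_pair <- function(pair, R) surface_pair(rotate_mesh(pair$pial, R),
                                              rotate_mesh(pair$white, R))
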