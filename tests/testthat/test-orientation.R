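test_that("angular difference matches the arccos oracle and its axioms", {
  expect_equal(angular_difference(c(1, 0, 0), c(0, 1, 0)), 90)
  v <- c(0.3, -0.5, 0.8)
  expect_equal(angular_difference(v, -v), 180)
  expect_error(angular_difference(c(0, 0, 0), v), "nonzero")

  withr::with_seed(7, {
    a <- matrix(rnorm(3e6), ncol = 3)
    a <- a / sqrt(rowSums(a^2))
    b <- matrix(rnorm(3e6), ncol = 3)
    b <- b / sqrt(rowSums(b^2))
  })
  ours <- angular_difference(a, b)
  oracle <- acos(pmin(pmax(rowSums(a * b), -1), 1)) * 180 / pi
  expect_lt(max(abs(ours - oracle)), 1e-6)
  # symmetry
  expect_equal(angular_difference(b, a), ours, tolerance = 1e-12)
  # spherical triangle inequality on random triples
  withr::with_seed(8, {
    c3 <- matrix(rnorm(300), ncol = 3); c3 <- c3 / sqrt(rowSums(c3^2))
  })
  i <- 1:100
  expect_true(all(angular_difference(a[i, ], b[i, ]) <=
                    angular_difference(a[i, ], c3) +
                    angular_difference(c3, b[i, ]) + 1e-9))
})

test_that("downsampled normals equal vertex normals of the decimated mesh", {
  # on a regular coarse sphere the field is near-radial at every vertex
  reg <- icosphere(2, 70)
  expect_lt(max(angular_difference(downsampled_normals(reg)$vectors,
                                   reg$vertices)), 5)

  # on a decimated sphere the faces are distorted, which biases the normals:
  # near-radial on average, with a visible per-vertex decimation bias
  dec <- sphere_dec()
  f <- downsampled_normals(dec$pair$pial)
  expect_identical(f$vectors, vertex_normals(dec$pair$pial))
  expect_lt(mean(angular_difference(f$vectors, dec$pair$pial$vertices)), 5)
  expect_lt(max(angular_difference(f$vectors, dec$pair$pial$vertices)), 15)

  g <- grid_mesh(4)
  expect_equal(downsampled_normals(g)$vectors,
               matrix(c(0, 0, 1), 16, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("cortical patch statistics average original-mesh neighbor normals", {
  dec <- sphere_dec()
  cps <- cortical_patch_statistics(sphere_pair()$pial, dec$map)
  dsn <- downsampled_normals(dec$pair$pial)
  expect_lt(mean(angular_difference(cps$vectors, dsn$vectors)), 5)

  # planar original mesh: constant (0,0,1) regardless of decimation
  g <- grid_mesh(5)
  dmap <- decimation_map(c(7L, 13L, 19L), rbind(1:3), 25)
  expect_equal(cortical_patch_statistics(g, dmap)$vectors,
               matrix(c(0, 0, 1), 3, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("original normals sample the non-decimated normals at retained vertices", {
  dec <- small_dec()
  f <- original_normals(small_pair()$pial, dec$map)
  vn <- vertex_normals(small_pair()$pial)
  expect_identical(f$vectors, vn[dec$map$retained, , drop = FALSE])

  ident <- decimation_map(seq_len(small_pair()$pial$n_vertices),
                          small_pair()$pial$faces,
                          small_pair()$pial$n_vertices)
  expect_identical(original_normals(small_pair()$pial, ident)$vectors, vn)

  ico <- icosphere(3, 1)
  identico <- decimation_map(seq_len(ico$n_vertices), ico$faces, ico$n_vertices)
  expect_lt(max(angular_difference(original_normals(ico, identico)$vectors,
                                   ico$vertices)), 2)
})

test_that("link vectors join corresponding vertices; pial/white fields are antiparallel", {
  p <- triangle_mesh(rbind(c(0, 0, 10), c(1, 0, 10), c(0, 1, 10)), rbind(1:3))
  w <- triangle_mesh(rbind(c(0, 0, 8), c(1, 0, 8), c(0, 1, 8)), rbind(1:3))
  f <- link_vectors(surface_pair(p, w))
  expect_equal(f$vectors[1, ], c(0, 0, -1), tolerance = 1e-12)

  dec <- sphere_dec()
  lv <- link_vectors(dec$pair)
  # concentric spheres: inward radial
  expect_lt(max(angular_difference(lv$vectors, -dec$pair$pial$vertices)), 5)

  lw <- link_vectors(dec$pair, surface = "white")
  expect_identical(lw$vectors, -lv$vectors)
  expect_equal(unname(field_difference_summary(lv, lw)$angles),
               rep(180, lv$n), tolerance = 1e-9)
})

test_that("variational field minimizes the normal-alignment + parallelism energy", {
  dec <- sphere_dec()
  f <- variational_field(sphere_pair(), dec$map, max_iter = 200)
  # concentric spheres: all energy terms favor the outward radial direction
  expect_lt(max(angular_difference(f$vectors, dec$pair$pial$vertices)), 5)
  # energy non-increasing along the descent
  tr <- attr(f, "energy_trace")
  expect_true(all(diff(tr) <= 0))

  # beta = 0: per-vertex closed form, the normalized sum of the two normals
  f0 <- variational_field(small_pair(), small_dec()$map, weights = c(1, 0),
                          max_iter = 4000, tol = 1e-12)
  np <- vertex_normals(small_pair()$pial)
  nw <- vertex_normals(small_pair()$white)
  closed <- (np + nw) / sqrt(rowSums((np + nw)^2))
  expect_lt(max(angular_difference(f0$vectors,
                                   closed[small_dec()$map$retained, ])), 0.5)
})

test_that("all five estimators give unit fields that co-rotate with the anatomy", {
  dec <- small_dec()
  pair <- small_pair()
  R <- megorient:::rotation_matrix(c(1, 2, 3), 0.7)
  dec_r <- list(pair = rotate_pair(dec$pair, R), map = dec$map)
  pair_r <- rotate_pair(pair, R)

  fields <- list(
    dsn = function(d, p, m) downsampled_normals(d$pial),
    cps = function(d, p, m) cortical_patch_statistics(p$pial, m),
    osn = function(d, p, m) original_normals(p$pial, m),
    lv  = function(d, p, m) link_vectors(d),
    var = function(d, p, m) variational_field(p, m, max_iter = 50)
  )
  for (nm in names(fields)) {
    f <- fields[[nm]](dec$pair, pair, dec$map)
    expect_equal(unname(sqrt(rowSums(f$vectors^2))), rep(1, f$n),
                 tolerance = 1e-9, label = nm)
    f_r <- fields[[nm]](dec_r$pair, pair_r, dec$map)
    expect_lt(max(angular_difference(f_r$vectors, f$vectors %*% t(R))), 0.75)
  }
})

test_that("in the concentric-sphere limit all estimators agree within 5 degrees", {
  dec <- sphere_dec()
  pair <- sphere_pair()
  fields <- list(downsampled_normals(dec$pair$pial),
                 cortical_patch_statistics(pair$pial, dec$map),
                 original_normals(pair$pial, dec$map),
                 orientation_field(-link_vectors(dec$pair)$vectors, "link_vectors"),
                 variational_field(pair, dec$map, max_iter = 200))
  radial <- dec$pair$pial$vertices / sqrt(rowSums(dec$pair$pial$vertices^2))
  # estimators drawing on the original fine mesh track the radial direction
  # at every vertex; the downsampled-normal field carries a decimation bias
  # and is held to its mean
  for (f in fields[2:5]) expect_lt(max(angular_difference(f$vectors, radial)), 5)
  expect_lt(mean(angular_difference(fields[[1]]$vectors, radial)), 5)
  # mutual mean differences near zero, in contrast to folded fixtures
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(field_difference_summary(fields[[i]], fields[[j]])$mean, 5)
  }
  # folded fixture: single- vs multi-surface methods differ by tens of degrees
  fdec <- small_dec()
  dsn <- downsampled_normals(fdec$pair$pial)
  lvf <- orientation_field(-link_vectors(fdec$pair)$vectors, "link_vectors")
  expect_gt(field_difference_summary(dsn, lvf)$mean, 5)
})

test_that("field difference summaries reduce to per-vertex angles", {
  f <- downsampled_normals(sphere_dec()$pair$pial)
  s <- field_difference_summary(f, f)
  expect_equal(s$angles, rep(0, f$n))
  expect_equal(s$mean, 0)

  neg <- orientation_field(-f$vectors, f$method, f$surface)
  expect_equal(field_difference_summary(f, neg)$angles, rep(180, f$n),
               tolerance = 1e-9)
  g <- link_vectors(sphere_dec()$pair)
  s2 <- field_difference_summary(f, g)
  expect_equal(s2$mean, mean(angular_difference(f$vectors, g$vectors)))
  expect_error(field_difference_summary(f, orientation_field(matrix(c(1, 0, 0), 1),
                                                             "link_vectors")),
               "mismatch")
})

test_that("cone rotation yields the exact angle with uniform azimuths", {
  v <- c(0, 0, 1)
  expect_equal(rotate_on_cone(v, 0, seed = 1), v)
  out90 <- rotate_on_cone(v, 90, seed = 2)
  expect_lt(abs(out90[3]), 1e-9)

  draws <- t(vapply(1:10000, function(i) rotate_on_cone(v, 21, seed = i),
                    numeric(3)))
  ang <- angular_difference(draws, matrix(v, 1e4, 3, byrow = TRUE))
  expect_true(all(ang > 21 - 1e-6 & ang < 21 + 1e-6))
  az <- atan2(draws[, 2], draws[, 1])
  ks <- suppressWarnings(stats::ks.test((az + pi) / (2 * pi), "punif"))
  expect_gt(ks$p.value, 0.01)

  # whole-field rotation: every vertex at the requested angle
  f <- link_vectors(sphere_dec()$pair)
  fr <- rotate_field_on_cone(f, 42, seed = 3)
  expect_equal(unname(field_difference_summary(f, fr)$angles), rep(42, f$n),
               tolerance = 1e-6)
})
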