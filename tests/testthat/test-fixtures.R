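test_that("the cortical pair fixture honors the sphere limit and thickness", {
  sp <- sphere_pair()
  r_pial <- sqrt(rowSums(sp$pial$vertices^2))
  r_white <- sqrt(rowSums(sp$white$vertices^2))
  expect_equal(r_pial, rep(70, length(r_pial)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r_white, rep(67.5, length(r_white)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # folded pair: per-vertex thickness within [0.5, 1.5] x nominal
  fp <- small_pair()
  expect_true(all(fp$thickness > 0.5 * 2.5 & fp$thickness < 1.5 * 2.5))
  expect_equal(sqrt(mean((sqrt(rowSums(fp$pial$vertices^2)) - 70)^2)), 3,
               tolerance = 0.05)

  # same seed, bit-identical pair
  a <- make_cortical_pair(2, 3, 6, seed = 9)
  b <- make_cortical_pair(2, 3, 6, seed = 9)
  expect_identical(a$pial$vertices, b$pial$vertices)
  expect_error(make_cortical_pair(2, 0, thickness_mm = 80), "self-intersects")
})

test_that("the helmet covers the upper cap with adequate spacing", {
  helm <- make_helmet(275, 110)
  expect_equal(helm$n_sensors, 275)
  expect_equal(sqrt(rowSums(helm$positions^2)), rep(110, 275), tolerance = 1e-9)
  expect_gt(min(dist(helm$positions)), 10)
  # all sensors outside the pial fixture surface
  expect_true(all(sqrt(rowSums(helm$positions^2)) >
                    max(sqrt(rowSums(big_pair()$pial$vertices^2)))))
  # no RNG: identical arrays
  expect_identical(make_helmet(275, 110)$positions, helm$positions)
  # sensitive axes radial
  expect_equal(helm$orientations, helm$positions / 110, tolerance = 1e-9)
})

test_that("orientation estimators matter under folding, hardly on the sphere", {
  # In the concentric-sphere limit the five estimators nearly coincide, so
  # their models earn nearly equal evidence; on a folded cortex they diverge
  # by tens of degrees and the evidence spread grows by orders of magnitude.
  # Radial dipoles are invisible in a spherical conductor, so a common
  # off-radial tilt (same per-vertex cone azimuths for every model) makes the
  # sphere-limit fields visible without introducing model differences.
  model_fields <- function(dec, pair) {
    list(dsn = downsampled_normals(dec$pair$pial),
         cps = cortical_patch_statistics(pair$pial, dec$map),
         osn = original_normals(pair$pial, dec$map),
         lv = orientation_field(-link_vectors(dec$pair)$vectors, "link_vectors"),
         var = variational_field(pair, dec$map, max_iter = 200))
  }
  evidence_spread <- function(dec, pair, tilt_deg) {
    mesh <- dec$pair$pial
    center <- fit_sphere_center(mesh$vertices)
    basis <- sphere_leadfield_basis(mesh$vertices, small_helmet(), center)
    dist <- megorient:::geodesic_distance_matrix(mesh)
    az <- withr::with_seed(11, runif(mesh$n_vertices, 0, 2 * pi))
    tilt <- function(f) {
      if (tilt_deg == 0) return(f)
      v <- t(vapply(seq_len(f$n), function(i) {
        megorient:::rotate_on_cone_az(f$vectors[i, ], tilt_deg, az[i])
      }, numeric(3)))
      orientation_field(v, f$method, f$surface)
    }
    fields <- lapply(model_fields(dec, pair), tilt)
    ds <- simulate_dataset(orient_leadfield(basis, fields$lv), mesh,
                           min(20, mesh$n_vertices), 0, n_trials = 32, seed = 2)
    red <- reduce_data(ds)
    vapply(fields, function(f) {
      invert_ebb(red, source_model(dec$pair, "pial", f, basis = basis),
                 dist = dist)$F
    }, numeric(1))
  }
  F_sphere <- evidence_spread(sphere_dec(), sphere_pair(), tilt_deg = 10)
  F_folded <- evidence_spread(small_dec(), small_pair(), tilt_deg = 0)
  spread_sphere <- max(F_sphere) - min(F_sphere)
  spread_folded <- max(F_folded) - min(F_folded)
  # sphere-limit spread reflects only the residual decimation bias of the
  # single-surface estimators; folding widens the spread severalfold
  expect_lt(spread_sphere, spread_folded / 2)
  # the two multi-surface estimators coincide on the sphere: equal evidence
  expect_lt(abs(F_sphere[["lv"]] - F_sphere[["var"]]), 1)
})

test_that("a miniature SNR experiment is deterministic with a zero reference row", {
  spec <- experiment_spec(n_locations = 2, snr_levels_db = 0,
                          rotation_angles_deg = c(21, 63), n_trials = 8,
                          seed = 3)
  res <- run_snr_experiment(spec, small_pair(), small_helmet(),
                            decimation = small_dec())
  expect_equal(nrow(res), 2 * 3)  # 2 locations x (reference + 2 angles)
  expect_true(all(res$delta_F[res$angle_deg == 0] == 0))
  res2 <- run_snr_experiment(spec, small_pair(), small_helmet(),
                             decimation = small_dec())
  expect_identical(res, res2)

  s <- summarize_delta_f(res)
  expect_equal(nrow(s), 3)
  expect_equal(s$n, rep(2, 3))
})

test_that("the zero-error co-registration rows reproduce the SNR experiment", {
  spec <- experiment_spec(n_locations = 2, snr_levels_db = 0,
                          coreg_levels_mm_deg = rbind(c(0, 0), c(4, 4)),
                          rotation_angles_deg = 21, n_trials = 8, seed = 3)
  snr <- run_snr_experiment(spec, small_pair(), small_helmet(),
                            decimation = small_dec())
  coreg <- run_coreg_experiment(spec, small_pair(), small_helmet(),
                                decimation = small_dec())
  zero <- coreg[coreg$translation_mm == 0, ]
  expect_equal(zero$F_model, snr$F_model, tolerance = 1e-9)
  expect_equal(zero$delta_F, snr$delta_F, tolerance = 1e-9)
  # perturbed rows differ
  pert <- coreg[coreg$translation_mm == 4, ]
  expect_false(isTRUE(all.equal(pert$F_model, snr$F_model)))
})

test_that("seed derivation is stable, label-sensitive, and in integer range", {
  expect_identical(derive_seed(1, "a", 2), derive_seed(1, "a", 2))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- vapply(1:50, function(i) derive_seed(i, "stage", i * 3), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
})
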