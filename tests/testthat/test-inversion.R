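test_that("data reduction keeps the top temporal modes of the analysis window", {
  # rank-2 data: modes 3 and 4 carry (numerically) no variance
  withr::with_seed(1, {
    u <- matrix(rnorm(60 * 2), 60)
    v <- matrix(rnorm(2 * 251), 2)
  })
  red <- reduce_data(u %*% v, fs = 250)
  energy <- colSums(red$Y^2)
  expect_lt(sum(energy[3:4]) / sum(energy[1:2]), 1e-9)

  # 100 ms at 250 Hz: a 25-sample window
  expect_length(red$window_idx, 25)

  # SVD optimality: retained variance beats any random rank-4 projector
  withr::with_seed(2, Yw <- matrix(rnorm(60 * 25), 60))
  red2 <- reduce_data(Yw, fs = 250, window_center = 13)
  var_svd <- sum((Yw %*% red2$projector)^2)
  for (i in 1:5) {
    P <- qr.Q(qr(matrix(rnorm(25 * 4), 25)))
    expect_gte(var_svd, sum((Yw %*% P)^2))
  }
  expect_error(reduce_data(Yw, n_temporal_modes = 30, fs = 250, window_center = 13),
               "temporal modes")
})

test_that("the beamformer prior peaks at the active source and scales as c^2", {
  s <- small_setup()
  L <- orient_leadfield(s$basis, s$ref)
  ds <- simulate_dataset(L, s$mesh, 11, 0, n_trials = 64, seed = 4)
  red <- reduce_data(ds)
  Gam <- ebb_prior(L, red)
  expect_equal(which.max(Gam), 11)

  Gam2 <- ebb_prior(L$gain, red$Y %*% diag(3, ncol(red$Y)), pseudo_inverse = TRUE)
  Gam1 <- ebb_prior(L$gain, red$Y, pseudo_inverse = TRUE)
  expect_equal(Gam2, 9 * Gam1, tolerance = 1e-9)

  # strict default: singular YY' with lambda = 0 errors
  expect_error(ebb_prior(L$gain, red$Y), "singular")
})

test_that("mirror-symmetric sources with symmetric data get equal prior weight", {
  # two sensors and two sources mirrored through x = 0
  sens <- sensor_array(rbind(c(-60, 0, 90), c(60, 0, 90)),
                       rbind(c(0, 0, 1), c(0, 0, 1)), kind = "magnetometer")
  pos <- rbind(c(-30, 0, 20), c(30, 0, 20))
  ori <- rbind(c(0, 1, 0), c(0, 1, 0))
  L <- sphere_leadfield(pos, ori, sens, c(0, 0, 0))
  Y <- matrix(c(1, 1), 2, 1)  # symmetric data (rank 1)
  Gam <- ebb_prior(L, Y, pseudo_inverse = TRUE)
  expect_equal(Gam[1], Gam[2], tolerance = 1e-6)
})

test_that("coherence smoothing reduces to the diagonal and stays PSD", {
  mesh <- sphere_dec()$pair$pial
  withr::with_seed(5, Gam <- runif(mesh$n_vertices))
  expect_equal(coherence_smooth(Gam, mesh, fwhm_mm = 0), diag(Gam))

  Q <- coherence_smooth(Gam, mesh, fwhm_mm = 20)
  expect_equal(Q, t(Q))
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9 * max(ev))
  # at the study kernel width the row-normalized smoothing approximately
  # conserves the total variance
  Q5 <- coherence_smooth(Gam, mesh, fwhm_mm = 5)
  expect_lt(abs(sum(diag(Q5)) / sum(Gam) - 1), 0.05)
})

test_that("ReML recovers known covariance mixtures within 10%", {
  withr::with_seed(6, {
    nc <- 24
    A <- matrix(rnorm(nc * 8), nc)
  })
  Q2 <- A %*% t(A) / 8
  C_true <- 2 * diag(nc) + 3 * Q2
  # exact covariance (infinite-data limit)
  fit <- reml_optimize(C_true, list(diag(nc), Q2), N = 1e4)
  expect_lt(abs(fit$scale[1] - 2) / 2, 0.1)
  expect_lt(abs(fit$scale[2] - 3) / 3, 0.1)
  # F decomposition identity
  expect_equal(fit$F, fit$accuracy - fit$complexity, tolerance = 1e-9)
  expect_gte(fit$complexity, 0)

  # sampled covariance across seeds (property-style)
  for (seed in 1:20) {
    C_s <- withr::with_seed(seed, {
      X <- matrix(rnorm(2000 * nc), 2000) %*% chol(C_true)
      crossprod(X) / 2000
    })
    fit_s <- reml_optimize(C_s, list(diag(nc), Q2), N = 2000)
    expect_lt(abs(fit_s$scale[1] - 2) / 2, 0.1)
    expect_lt(abs(fit_s$scale[2] - 3) / 3, 0.1)
  }
})

test_that("ReML accuracy takes the standard form in the identity case", {
  withr::with_seed(7, {
    nc <- 10
    B <- matrix(rnorm(nc * nc), nc)
  })
  C_Y <- B %*% t(B) / nc + diag(nc)
  # single component equal to C_Y: optimum at scale 1, trace term = Nc
  fit <- reml_optimize(C_Y, list(C_Y), N = 50, tol = 1e-10, max_iter = 512)
  expect_equal(fit$scale[1], 1, tolerance = 1e-3)
  ld <- as.numeric(determinant(C_Y)$modulus)
  expected_acc <- -50 / 2 * nc - 50 / 2 * ld - nc * 50 / 2 * log(2 * pi)
  expect_equal(fit$accuracy, expected_acc, tolerance = 1e-2)

  # prior mean at the optimum: quadratic complexity term vanishes (printed form)
  fitp <- reml_optimize(C_Y, list(C_Y), N = 50, prior_mean = fit$lambda_hat,
                        prior_precision = diag(1e-8, 1), tol = 1e-10,
                        free_energy_convention = "printed")
  ldSP <- as.numeric(determinant(fitp$Sigma_lambda %*% diag(1e-8, 1))$modulus)
  expect_equal(fitp$complexity, 0.5 * ldSP, tolerance = 1e-4)
})

test_that("inversion localizes a strong patch and honors degenerate input", {
  s <- small_setup()
  L <- orient_leadfield(s$basis, s$ref)
  ds <- simulate_dataset(L, s$mesh, 23, 0, n_trials = 64, seed = 8)
  red <- reduce_data(ds)
  model <- source_model(s$dec$pair, "pial", s$ref, basis = s$basis)
  res <- invert_ebb(red, model, dist = s$dist)
  pk <- peak_vertex(res)
  expect_lte(s$dist[23, pk$vertex], 5)
  expect_equal(res$F, res$accuracy - res$complexity, tolerance = 1e-9)
  # reconstructed time course spans the analysis window
  expect_length(pk$timecourse, length(red$window_idx))

  # zero data: zero estimate
  red0 <- red
  red0$Y <- red$Y * 0
  red0$YY <- red$YY * 0
  res0 <- invert_ebb(red0, model, dist = s$dist)
  expect_equal(max(abs(res0$J_hat)), 0)
})

test_that("model ranking is invariant to global data rescaling", {
  s <- small_setup()
  L <- orient_leadfield(s$basis, s$ref)
  ds <- simulate_dataset(L, s$mesh, 23, 0, n_trials = 32, seed = 12)
  red <- reduce_data(ds)
  m_ref <- source_model(s$dec$pair, "pial", s$ref, basis = s$basis)
  m_rot <- source_model(s$dec$pair, "pial",
                        rotate_field_on_cone(s$ref, 42, seed = 5), basis = s$basis)
  dF <- invert_ebb(red, m_rot, dist = s$dist)$F -
        invert_ebb(red, m_ref, dist = s$dist)$F
  red_c <- red
  red_c$Y <- red$Y * 10
  red_c$YY <- red$YY * 100
  dF_c <- invert_ebb(red_c, m_rot, dist = s$dist)$F -
          invert_ebb(red_c, m_ref, dist = s$dist)$F
  expect_equal(dF_c, dF, tolerance = 1e-6 * max(1, abs(dF)))
})

test_that("free energy decreases with orientation rotation at high SNR", {
  s <- small_setup()
  L <- orient_leadfield(s$basis, s$ref)
  m_ref <- source_model(s$dec$pair, "pial", s$ref, basis = s$basis)
  angles <- c(0, 21, 42, 63)
  meanF <- numeric(length(angles))
  for (loc in c(9, 23, 40)) {
    ds <- simulate_dataset(L, s$mesh, loc, 0, n_trials = 64,
                           seed = derive_seed(3, "mono", loc))
    red <- reduce_data(ds)
    for (k in seq_along(angles)) {
      m <- if (angles[k] == 0) m_ref else {
        source_model(s$dec$pair, "pial",
                     rotate_field_on_cone(s$ref, angles[k],
                                          seed = derive_seed(3, "az", loc, k)),
                     basis = s$basis)
      }
      meanF[k] <- meanF[k] + invert_ebb(red, m, dist = s$dist)$F / 3
    }
  }
  # evidence drops sharply away from the true orientation, then saturates:
  # every rotated model sits decisively below the reference
  expect_true(all(meanF[2:4] < meanF[1] - 3))
  expect_lt(meanF[2], meanF[1])
  # the 45-degree-class rotation is decisively worse than the truth
  expect_gt(meanF[1] - meanF[3], 3)
})

test_that("peak vertex breaks ties toward the lowest index", {
  fake <- structure(list(J_hat = rbind(c(1, 1), c(1, 1), c(0, 1)),
                         projector = NULL),
                    class = "inversion_result")
  expect_equal(peak_vertex(fake)$vertex, 1)
})

test_that("combined-surface models double the source count", {
  s <- small_setup()
  comb_basis <- sphere_leadfield_basis(rbind(s$dec$pair$pial$vertices,
                                             s$dec$pair$white$vertices),
                                       small_helmet(), s$center)
  m <- source_model(s$dec$pair, "combined", s$ref, basis = comb_basis)
  expect_equal(m$n_sources, 2 * s$mesh$n_vertices)
  ds <- simulate_dataset(orient_leadfield(s$basis, s$ref), s$mesh, 11, 0,
                         n_trials = 16, seed = 13)
  res <- invert_ebb(reduce_data(ds), m, dist = s$dist)
  expect_equal(nrow(res$J_hat), m$n_sources)
  expect_equal(res$F, res$accuracy - res$complexity, tolerance = 1e-9)
})
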