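#' Simulation experiment specification
#'
#' Bundles the levels swept by the two simulation experiments. Defaults are
#' the package's desk-scale study conditions (20 source locations, 128
#' trials); the full-scale values (100 locations, 515 trials) are reachable
#' through the same fields.
#'
#' @param n_locations Number of random pial source locations.
#' @param snr_levels_db Per-trial amplitude SNR levels (dB).
#' @param coreg_levels_mm_deg 2-column matrix of (translation mm, rotation
#'   deg) co-registration error levels.
#' @param rotation_angles_deg Cone-rotation angles for the candidate
#'   orientation models (degrees).
#' @param n_trials Trials per simulated dataset.
#' @param fs,n_samples Acquisition parameters.
#' @param seed Master seed; all per-stage seeds are derived from it.
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_locations = 20,
                            snr_levels_db = c(-50, -40, -30, -20, -10, 0),
                            coreg_levels_mm_deg = cbind(seq(0, 10, 2), seq(0, 10, 2)),
                            rotation_angles_deg = seq(7, 63, 7),
                            n_trials = 128, fs = 250, n_samples = 251,
                            seed = 1) {
  stopifnot(length(snr_levels_db) >= 1, length(rotation_angles_deg) >= 1,
            all(rotation_angles_deg > 0), all(rotation_angles_deg < 180),
            n_locations >= 1, n_trials >= 1)
  structure(list(n_locations = n_locations, snr_levels_db = snr_levels_db,
                 coreg_levels_mm_deg = as.matrix(coreg_levels_mm_deg),
                 rotation_angles_deg = rotation_angles_deg,
                 n_trials = n_trials, fs = fs, n_samples = n_samples,
                 seed = seed),
            class = "experiment_spec")
}

# Shared per-experiment setup: decimation, forward basis, reference field,
# source locations, geodesic distances.
experiment_setup <- function(spec, pair, helmet, decimation = NULL,
                             decimation_factor = 10) {
  dec <- decimation %||% decimate_pair(pair, decimation_factor)
  dpair <- dec$pair
  mesh <- dpair$pial
  center <- fit_sphere_center(mesh$vertices)
  basis <- sphere_leadfield_basis(mesh$vertices, helmet, center)
  ref_field <- link_vectors(dpair)
  dist <- geodesic_distance_matrix(mesh)
  locations <- withr::with_seed(derive_seed(spec$seed, "locations"),
                                sample(mesh$n_vertices, spec$n_locations))
  list(dpair = dpair, map = dec$map, mesh = mesh, center = center,
       basis = basis, ref_field = ref_field, dist = dist,
       locations = locations, helmet = helmet)
}

# Invert one dataset with the reference and all rotated orientation models
# for one sensor geometry; returns rows of the tidy result table.
invert_rotation_grid <- function(spec, setup, Y, loc, basis, level_label, level_value) {
  ref_model <- source_model(setup$dpair, "pial", setup$ref_field, basis = basis)
  res_ref <- invert_ebb(Y, ref_model, dist = setup$dist)
  rows <- data.frame(location = loc, level = level_value, angle_deg = 0,
                     F_ref = res_ref$F, F_model = res_ref$F, delta_F = 0)
  for (angle in spec$rotation_angles_deg) {
    fld <- rotate_field_on_cone(setup$ref_field, angle,
                                derive_seed(spec$seed, "cone", loc, angle))
    mod <- source_model(setup$dpair, "pial", fld, basis = basis)
    res <- invert_ebb(Y, mod, dist = setup$dist)
    rows <- rbind(rows, data.frame(location = loc, level = level_value,
                                   angle_deg = angle, F_ref = res_ref$F,
                                   F_model = res$F, delta_F = res$F - res_ref$F))
  }
  names(rows)[names(rows) == "level"] <- level_label
  rows
}

simulate_for_location <- function(spec, setup, loc, snr_db) {
  L_ref <- orient_leadfield(setup$basis, setup$ref_field)
  simulate_dataset(L_ref, setup$mesh, loc, snr_db,
                   n_trials = spec$n_trials, fs = spec$fs,
                   n_samples = spec$n_samples,
                   seed = derive_seed(spec$seed, "noise", loc, snr_db))
}

#' SNR simulation experiment
#'
#' For each random pial source location and each SNR level: simulate a patch
#' source with link-vector orientations, invert with the link-vector
#' reference model and with each cone-rotated orientation model, and tabulate
#' the free energy of every model relative to the reference. Co-registration
#' error is zero throughout.
#'
#' @param spec An `experiment_spec`.
#' @param pair Original-resolution `surface_pair`.
#' @param helmet A `sensor_array`.
#' @param decimation Optional precomputed result of [decimate_pair()] (to
#'   share the decimation across experiments).
#' @param snr_levels_db Optional subset of SNR levels to run (defaults to
#'   `spec$snr_levels_db`).
#' @param progress Print per-location progress.
#' @return Tidy data frame: `location`, `snr_db`, `angle_deg` (0 = reference
#'   model), `F_ref`, `F_model`, `delta_F`.
#' @export
run_snr_experiment <- function(spec, pair, helmet, decimation = NULL,
                               snr_levels_db = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  setup <- experiment_setup(spec, pair, helmet, decimation)
  levels <- snr_levels_db %||% spec$snr_levels_db
  out <- list()
  for (snr in levels) {
    for (loc in setup$locations) {
      if (progress) message(sprintf("snr %g dB, location %d", snr, loc))
      ds <- simulate_for_location(spec, setup, loc, snr)
      Y <- reduce_data(ds, window_center = (spec$n_samples - 1) %/% 2 + 1)
      out[[length(out) + 1]] <-
        invert_rotation_grid(spec, setup, Y, loc, setup$basis, "snr_db", snr)
    }
  }
  do.call(rbind, out)
}

#' Co-registration error simulation experiment
#'
#' As [run_snr_experiment()] but at a fixed per-trial SNR of 0 dB: for each
#' co-registration error level, a random rigid transform of the given
#' translation/rotation magnitude (re-drawn per source location, seeded) is
#' applied to the sensor array before inversion, and the rotation grid of
#' orientation models is compared against the link-vector reference under
#' the same perturbed geometry. The zero-error level reproduces the 0 dB
#' rows of the SNR experiment under the same master seed.
#'
#' @inheritParams run_snr_experiment
#' @param snr_db The fixed SNR (default 0 dB).
#' @return Tidy data frame: `location`, `translation_mm`, `rotation_coreg_deg`,
#'   `angle_deg`, `F_ref`, `F_model`, `delta_F`.
#' @export
run_coreg_experiment <- function(spec, pair, helmet, decimation = NULL,
                                 snr_db = 0, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  setup <- experiment_setup(spec, pair, helmet, decimation)
  out <- list()
  for (li in seq_len(nrow(spec$coreg_levels_mm_deg))) {
    tr_mm <- spec$coreg_levels_mm_deg[li, 1]
    rot_deg <- spec$coreg_levels_mm_deg[li, 2]
    for (loc in setup$locations) {
      if (progress) message(sprintf("coreg %g mm / %g deg, location %d", tr_mm, rot_deg, loc))
      ds <- simulate_for_location(spec, setup, loc, snr_db)
      Y <- reduce_data(ds, window_center = (spec$n_samples - 1) %/% 2 + 1)
      basis <- if (tr_mm == 0 && rot_deg == 0) setup$basis else {
        sens_p <- apply_coregistration_error(
          setup$helmet, tr_mm, rot_deg,
          seed = derive_seed(spec$seed, "coreg", loc, tr_mm, rot_deg))
        sphere_leadfield_basis(setup$mesh$vertices, sens_p, setup$center)
      }
      rows <- invert_rotation_grid(spec, setup, Y, loc, basis, "level", li)
      rows$translation_mm <- tr_mm
      rows$rotation_coreg_deg <- rot_deg
      rows$level <- NULL
      out[[length(out) + 1]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Mean delta-F per condition from an experiment table
#'
#' Averages `delta_F` over source locations for each (level, angle) cell and
#' attaches the standard error over locations.
#'
#' @param results Output of [run_snr_experiment()] or [run_coreg_experiment()].
#' @param level_col Name of the level column ("snr_db" or "translation_mm").
#' @return Data frame with `level`, `angle_deg`, `mean_delta_F`, `se_delta_F`,
#'   `n`.
#' @export
summarize_delta_f <- function(results, level_col = "snr_db") {
  key <- interaction(results[[level_col]], results$angle_deg, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    data.frame(level = d[[level_col]][1], angle_deg = d$angle_deg[1],
               mean_delta_F = mean(d$delta_F),
               se_delta_F = sd(d$delta_F) / sqrt(nrow(d)), n = nrow(d))
  })
  out <- do.call(rbind, agg)
  out[order(out$level, out$angle_deg), , drop = FALSE]
}
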