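#' Gaussian source activity time course
#'
#' A Gaussian pulse centered within the epoch (at sample `(n_samples-1)/2`,
#' 0-based), with the given full width at half maximum in milliseconds and
#' peak moment in nA·m.
#'
#' @param n_samples Number of samples in the epoch.
#' @param fs Sampling rate (Hz).
#' @param width_ms FWHM of the pulse (ms).
#' @param peak_nAm Peak dipole moment (nA·m).
#' @return Numeric vector of length `n_samples` (nA·m).
#' @export
gaussian_timecourse <- function(n_samples, fs, width_ms = 25, peak_nAm = 10) {
  stopifnot(n_samples >= 2, fs > 0, width_ms > 0, peak_nAm > 0)
  if (width_ms < 2 * 1000 / fs) stop("pulse width shorter than 2 samples")
  t_ms <- (seq_len(n_samples) - 1) * 1000 / fs
  center <- (n_samples - 1) / 2 * 1000 / fs
  sigma <- width_ms / (2 * sqrt(2 * log(2)))
  peak_nAm * exp(-(t_ms - center)^2 / (2 * sigma^2))
}

#' Gaussian patch weights on a mesh
#'
#' Spatial profile of a patch source: `w_i = exp(-d_i^2 / (2 sigma^2))` with
#' `sigma = fwhm / 2.355` and `d_i` the geodesic distance from the center
#' vertex, truncated at 3 sigma. The center has weight 1.
#'
#' @param mesh Source-space `triangle_mesh`.
#' @param center_vertex 1-based center vertex index.
#' @param fwhm_mm Kernel FWHM (mm).
#' @return Numeric vector of per-vertex weights in \[0, 1\] (zeros outside
#'   the truncation radius).
#' @export
patch_weights <- function(mesh, center_vertex, fwhm_mm = 5) {
  w <- numeric(mesh$n_vertices)
  if (fwhm_mm <= 0) { w[center_vertex] <- 1; return(w) }
  sigma <- fwhm_mm / 2.355
  d <- geodesic_distances(mesh, center_vertex, radius = 3 * sigma)
  w[as.integer(names(d))] <- exp(-d^2 / (2 * sigma^2))
  w
}

#' Simulate a multi-trial MEG dataset from a patch source
#'
#' The noiseless sensor signal is `L %*% (weights %o% timecourse)` — a patch
#' of spatially distributed activity whose every vertex follows the same
#' Gaussian pulse, scaled by the geodesic Gaussian patch weight — identical
#' across trials. Independent Gaussian white noise is added per trial,
#' channel, and sample, with a single noise SD chosen so that the per-trial
#' amplitude SNR, averaged over channels
#' (`mean_ch 20*log10(RMS_signal_ch / RMS_noise_ch)`), equals `snr_db`.
#'
#' @param leadfield A `lead_field` over the source mesh (fT per nA·m).
#' @param mesh The source-space `triangle_mesh` (for patch geometry).
#' @param center_vertex Patch center (1-based source index).
#' @param snr_db Target per-trial amplitude SNR in dB.
#' @param n_trials,fs,n_samples Acquisition parameters.
#' @param patch_fwhm_mm Patch FWHM (mm).
#' @param width_ms,peak_nAm Pulse parameters (see [gaussian_timecourse()]).
#' @param seed Integer seed for the noise.
#' @param coreg Optional list `(translation_mm, rotation_deg)` recorded in
#'   the truth block.
#' @return Object of class `simulated_dataset`: `data` (trials x channels x
#'   samples array, fT), `noiseless` (channels x samples), `fs`, and a fully
#'   populated `truth` block from which the simulation is reproducible.
#' @export
simulate_dataset <- function(leadfield, mesh, center_vertex, snr_db,
                             n_trials = 515, fs = 250, n_samples = 251,
                             patch_fwhm_mm = 5, width_ms = 25, peak_nAm = 10,
                             seed = 1, coreg = list(translation_mm = 0, rotation_deg = 0)) {
  stopifnot(inherits(leadfield, "lead_field"),
            center_vertex >= 1, center_vertex <= ncol(leadfield$gain))
  w <- patch_weights(mesh, center_vertex, patch_fwhm_mm)
  tc <- gaussian_timecourse(n_samples, fs, width_ms, peak_nAm)
  signal <- leadfield$gain %*% (w %o% tc)          # channels x samples, fT
  rms_ch <- sqrt(rowMeans(signal^2))
  if (all(rms_ch < 1e-12)) {
    stop("noiseless signal is (numerically) zero: the patch is invisible to ",
         "the sensors (e.g. purely radial source); choose a different center vertex")
  }
  # mean_ch 20*log10(rms_ch / sigma) = snr_db  =>  solve for sigma
  sigma <- 10^((mean(20 * log10(rms_ch[rms_ch > 0])) - snr_db) / 20)
  nc <- nrow(signal)
  data <- withr::with_seed(seed, {
    arr <- array(rnorm(n_trials * nc * n_samples, sd = sigma),
                 dim = c(n_trials, nc, n_samples))
    arr + rep(signal, each = n_trials)
  })
  structure(list(data = data, noiseless = signal, fs = fs,
                 n_trials = n_trials, n_channels = nc, n_samples = n_samples,
                 truth = list(center_vertex = center_vertex,
                              patch_fwhm_mm = patch_fwhm_mm,
                              width_ms = width_ms, peak_moment_nAm = peak_nAm,
                              snr_db = snr_db, noise_sd = sigma,
                              coreg = coreg, seed = seed)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("simulated_dataset: %d trials x %d channels x %d samples, ",
                     "fs=%g Hz, target SNR %g dB\n"),
              x$n_trials, x$n_channels, x$n_samples, x$fs, x$truth$snr_db))
  invisible(x)
}

#' Measure the per-trial amplitude SNR of a dataset
#'
#' Mean over channels of `20*log10(RMS signal / RMS noise)` where the noise
#' of each trial is `trial - signal`, averaged over trials — the operational
#' definition used by [simulate_dataset()] to scale its noise.
#'
#' @param dataset A `simulated_dataset` (or trials x channels x samples array).
#' @param noiseless Channels x samples noiseless signal (defaults to the
#'   dataset's own).
#' @return SNR in dB (`Inf` if the noise is exactly zero).
#' @export
measure_snr <- function(dataset, noiseless = NULL) {
  if (inherits(dataset, "simulated_dataset")) {
    if (is.null(noiseless)) noiseless <- dataset$noiseless
    data <- dataset$data
  } else data <- dataset
  stopifnot(dim(data)[2] == nrow(noiseless), dim(data)[3] == ncol(noiseless))
  rms_sig <- sqrt(rowMeans(noiseless^2))
  keep <- rms_sig > 0
  per_trial <- vapply(seq_len(dim(data)[1]), function(tr) {
    noise <- data[tr, , ] - noiseless
    rms_noise <- sqrt(rowMeans(noise^2))
    if (all(rms_noise == 0)) return(Inf)
    mean(20 * log10(rms_sig[keep] / rms_noise[keep]))
  }, numeric(1))
  mean(per_trial)
}

#' Trial-averaged sensor data
#'
#' @param dataset A `simulated_dataset`.
#' @return Channels x samples matrix (fT).
#' @export
average_trials <- function(dataset) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  apply(dataset$data, c(2, 3), mean)
}
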