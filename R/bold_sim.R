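#' Noise parameters
#'
#' Two noise sources: structured physiological noise with a low-dimensional
#' basis over voxels (scaled by the superficial bias, like the signal) and
#' additive Rician thermal noise (independent of depth). Defaults sigma_p =
#' 11, sigma_t = 15 mimic the contrast scatter of real 7T acquisitions; the
#' high-noise regime uses sigma_p = 20, sigma_t = 30.
#'
#' @param sigma_p Physiological noise sd (per voxel, after rescaling).
#' @param sigma_t Thermal noise component sd.
#' @param n_physio_components Number of shared Gaussian time vectors
#'   (default 20).
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_p = 11, sigma_t = 15,
                         n_physio_components = 20L) {
  stopifnot(sigma_p >= 0, sigma_t >= 0, n_physio_components >= 1)
  structure(list(sigma_p = sigma_p, sigma_t = sigma_t,
                 n_physio_components = as.integer(n_physio_components)),
            class = "noise_params")
}

#' Multiplicative superficial-bias profile
#'
#' Gain applied to signal plus physiological noise in each layer, modeling
#' depth-varying baseline physiology (CBV, T2*). The exact values are not
#' critical for ratio-family metrics, which are provably invariant to a
#' per-layer rescale; the default `c(3, 2, 1)` is any strictly decreasing
#' positive profile.
#'
#' @param l_bias Positive length-3 vector (superficial, middle, deep).
#' @return Named numeric vector of class `layer_bias`.
#' @export
layer_bias <- function(l_bias = c(3, 2, 1)) {
  stopifnot(length(l_bias) == 3, all(l_bias > 0))
  structure(stats::setNames(as.numeric(l_bias), layer_names()),
            class = "layer_bias")
}

#' Canonical double-gamma HRF parameters
#'
#' @param peak_delay,undershoot_delay Gamma shape-like delays (s); defaults
#'   6 and 16.
#' @param peak_disp,undershoot_disp Dispersions (s); defaults 1 and 1.
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param length Kernel length (s, default 32).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       ratio = 6, length = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, ratio > 0, length > 0)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length = length),
            class = "hrf_params")
}

#' Sample the canonical double-gamma HRF on the TR grid
#'
#' Difference of two gamma densities (peak minus undershoot/ratio), sampled
#' at t = 0, tr, 2 tr, ... up to the kernel length and, following the SPM
#' convention, scaled to unit sum so that a sustained boxcar of amplitude A
#' plateaus at A. Peaks near 5 s. The unit-sum convention fixes the scale of
#' the simulated signal relative to the stated noise sds.
#'
#' @param hrf An `hrf_params`.
#' @param tr Sampling interval (s).
#' @return Numeric kernel vector.
#' @export
hrf_kernel <- function(hrf = hrf_params(), tr) {
  stopifnot(tr > 0)
  t <- seq(0, hrf$length, by = tr)
  k <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_disp,
                     scale = hrf$peak_disp) -
    stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_disp,
                  scale = hrf$undershoot_disp) / hrf$ratio
  k / sum(k)
}

#' Condition boxcar on the volume grid
#'
#' A volume is active for a block if its acquisition onset falls inside the
#' block's active window `[onset, onset + duration)`.
#'
#' @param schedule A `block_schedule`.
#' @param condition Condition label to mark.
#' @param block_index Optional single block index; when given only that
#'   block is marked (used by the per-block design matrix).
#' @return 0/1 vector of length `n_volumes`.
#' @keywords internal
condition_boxcar <- function(schedule, condition = NULL, block_index = NULL) {
  box <- numeric(schedule$n_volumes)
  vol_times <- (seq_len(schedule$n_volumes) - 1) * schedule$tr
  blocks <- schedule$blocks
  idx <- if (!is.null(block_index)) block_index else
    which(blocks$condition == condition)
  for (b in idx) {
    on <- blocks$onset[b]
    box[vol_times >= on - 1e-9 & vol_times < on + blocks$duration[b] - 1e-9] <- 1
  }
  box
}

#' Noise-free neural timecourse for one run
#'
#' Per voxel, a boxcar over each block's active volumes with amplitude given
#' by [block_amplitude()] for that block's context and attended category;
#' zero during rest.
#'
#' @param schedule A `block_schedule`.
#' @param vox A `voxel_population`.
#' @param attn An `attention_profile`.
#' @return Matrix voxels x volumes.
#' @export
neural_timecourse <- function(schedule, vox, attn) {
  out <- matrix(0, vox$n_voxels, schedule$n_volumes)
  # amplitude depends only on (context, attended); cache the two variants
  amps <- list(
    face = block_amplitude(vox, schedule$context, "face", attn),
    house = block_amplitude(vox, schedule$context, "house", attn))
  for (b in seq_len(nrow(schedule$blocks))) {
    box <- condition_boxcar(schedule, block_index = b)
    active <- which(box > 0)
    out[, active] <- out[, active] +
      amps[[schedule$blocks$attended_category[b]]]
  }
  out
}

#' Causal convolution with an HRF kernel, truncated to the input length
#'
#' @param timecourse Matrix voxels x volumes (or a numeric vector).
#' @param kernel Numeric kernel from [hrf_kernel()].
#' @return Convolved matrix of the same dimensions.
#' @export
convolve_with_hrf <- function(timecourse, kernel) {
  stopifnot(length(kernel) >= 1)
  vec <- is.null(dim(timecourse))
  if (vec) timecourse <- matrix(timecourse, nrow = 1)
  n <- ncol(timecourse)
  # voxels x volumes %*% (volumes x volumes lower-triangular Toeplitz)
  conv <- matrix(0, n, n)
  for (lag in seq_along(kernel)) {
    if (lag > n) break
    conv[cbind(seq_len(n - lag + 1L), seq(lag, n))] <- kernel[lag]
  }
  out <- timecourse %*% conv
  if (vec) drop(out) else out
}

#' Structured physiological noise
#'
#' Draws `n_physio_components` independent standard-Gaussian time vectors
#' shared by all voxels; each voxel receives a random standard-Gaussian
#' weighting of them, then is recentred to mean 0 and rescaled to sample sd
#' `sigma_p`. The resulting voxels-by-volumes matrix has temporal covariance
#' of rank at most `n_physio_components`.
#'
#' @param n_voxels,n_volumes Dimensions.
#' @param noise A `noise_params`.
#' @param weights Optional voxels x components weight matrix; when omitted a
#'   fresh standard-Gaussian weight matrix is drawn. [simulate_session()]
#'   redraws both the temporal basis and the weights independently for every
#'   run, so the run-averaged contrast noise is close to exchangeable across
#'   voxels, which keeps the pooled Deming estimator stable.
#' @return Matrix voxels x volumes.
#' @export
sample_physio_noise <- function(n_voxels, n_volumes, noise, weights = NULL) {
  if (noise$sigma_p == 0) return(matrix(0, n_voxels, n_volumes))
  k <- noise$n_physio_components
  basis <- matrix(stats::rnorm(k * n_volumes), k, n_volumes)
  if (is.null(weights)) {
    weights <- matrix(stats::rnorm(n_voxels * k), n_voxels, k)
  }
  stopifnot(nrow(weights) == n_voxels, ncol(weights) == k)
  e <- weights %*% basis
  e <- e - rowMeans(e)
  sds <- sqrt(rowSums(e^2) / (n_volumes - 1))
  e * (noise$sigma_p / sds)
}

#' Rician (zero-offset, i.e. Rayleigh) thermal noise
#'
#' Magnitude noise `sqrt(g1^2 + g2^2)` with `g1, g2 ~ N(0, sigma_t)`;
#' non-negative and identical in distribution across layers. Its nonzero
#' mean is absorbed by the GLM intercept.
#'
#' @param n_voxels,n_volumes Dimensions.
#' @param noise A `noise_params`.
#' @return Matrix voxels x volumes.
#' @export
sample_thermal_noise <- function(n_voxels, n_volumes, noise) {
  if (noise$sigma_t == 0) return(matrix(0, n_voxels, n_volumes))
  n <- n_voxels * n_volumes
  matrix(sqrt(stats::rnorm(n, 0, noise$sigma_t)^2 +
                stats::rnorm(n, 0, noise$sigma_t)^2),
         n_voxels, n_volumes)
}

#' Simulate a full scanning session
#'
#' For each run, the measured timeseries is
#' `y = L_bias(layer) * (h + E_p) + E_t`, where `h` is the HRF-convolved
#' neural timecourse, `E_p` the structured physiological noise (which, like
#' the signal, is scaled by the superficial bias) and `E_t` the additive
#' thermal noise. Noise is drawn independently for every run.
#'
#' @param vox A `voxel_population`.
#' @param attn An `attention_profile`.
#' @param schedules List of `block_schedule` from [generate_schedules()].
#' @param bias A `layer_bias`.
#' @param noise A `noise_params`.
#' @param hrf An `hrf_params`.
#' @param keep_clean Retain the noise-free signal `h` per run (for tests).
#' @return An object of class `simulated_session`: list with `runs`, each
#'   holding `schedule`, `y` (voxels x volumes) and optionally `h`; plus
#'   `vox`, `kernel`.
#' @export
simulate_session <- function(vox, attn, schedules, bias = layer_bias(),
                             noise = noise_params(), hrf = hrf_params(),
                             keep_clean = FALSE) {
  kernel <- hrf_kernel(hrf, schedules[[1]]$tr)
  lb <- unclass(bias)[as.integer(vox$layer)]
  runs <- lapply(schedules, function(sch) {
    stopifnot(sch$tr == schedules[[1]]$tr)
    h <- convolve_with_hrf(neural_timecourse(sch, vox, attn), kernel)
    ep <- sample_physio_noise(vox$n_voxels, sch$n_volumes, noise)
    et <- sample_thermal_noise(vox$n_voxels, sch$n_volumes, noise)
    run <- list(schedule = sch, y = lb * (h + ep) + et)
    if (keep_clean) run$h <- h
    run
  })
  structure(list(runs = runs, vox = vox, kernel = kernel),
            class = "simulated_session")
}
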