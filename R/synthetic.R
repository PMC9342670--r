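#' Simulation configuration
#'
#' Parameters of the seeded generator of fNIRS-like verbal-fluency-task
#' datasets. The generator targets the statistical structure the analysis
#' pipeline assumes rather than biophysical realism: a task-evoked
#' hemodynamic response whose amplitude is reduced in the patient group at
#' a known subset of channels (a hypofrontality analogue), region-shared
#' physiological oscillations that induce functional-connectivity
#' structure, slow drift, and white noise.
#'
#' @param n_per_group Participants per group (default 100; groups are
#'   patients first, labels 1, then controls, labels 0).
#' @param n_channels Number of channels (default 52).
#' @param sampling_rate Hz (default 10).
#' @param duration Task-window length in seconds (default 60).
#' @param informative_channels 1-based channel ids carrying the group
#'   effect (default 19, 30, 39, 48).
#' @param effect_size Fractional task-amplitude reduction in patients at
#'   the informative channels, in [0, 1] (default 0.5).
#' @param task_amplitude Mean task-response amplitude (arbitrary
#'   concentration-change units; default 1).
#' @param amplitude_cv Between-participant coefficient of variation of the
#'   task amplitude (default 0.2).
#' @param hrf_peak Hemodynamic impulse-response peak time in seconds
#'   (default 6).
#' @param osc_freqs,osc_amps Frequencies (Hz) and amplitudes of the shared
#'   physiological oscillations (defaults: Mayer 0.1 Hz at 0.3, respiratory
#'   0.25 Hz at 0.2, cardiac 1.1 Hz at 0.15).
#' @param drift_slope_range Range of the uniform linear drift per
#'   `duration` (default c(-0.3, 0.3)); a 0.02 Hz sinusoid of amplitude
#'   `drift_sin_amp` (default 0.2) is added.
#' @param noise_sd White-noise standard deviation (default 0.3).
#' @param phase_sharing In [0, 1]: 1 means channels of a montage region
#'   share oscillation phases exactly; 0 means fully independent phases
#'   (default 0.8).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 100L, n_channels = 52L,
                       sampling_rate = 10, duration = 60,
                       informative_channels = c(19L, 30L, 39L, 48L),
                       effect_size = 0.5, task_amplitude = 1,
                       amplitude_cv = 0.2, hrf_peak = 6,
                       osc_freqs = c(mayer = 0.1, resp = 0.25, cardiac = 1.1),
                       osc_amps = c(mayer = 0.3, resp = 0.2, cardiac = 0.15),
                       drift_slope_range = c(-0.3, 0.3),
                       drift_sin_amp = 0.2, noise_sd = 0.3,
                       phase_sharing = 0.8, seed = 1L) {
  if (!is_count(n_per_group) || n_per_group < 1L) {
    stop_("n_per_group must be a positive integer")
  }
  if (effect_size < 0 || effect_size > 1) stop_("effect_size must lie in [0, 1]")
  informative_channels <- as.integer(informative_channels)
  if (any(informative_channels < 1L | informative_channels > n_channels)) {
    stop_("informative_channels must lie in 1..%d", n_channels)
  }
  if (any(osc_amps < 0) || noise_sd < 0 || drift_sin_amp < 0) {
    stop_("amplitudes must be non-negative")
  }
  if (phase_sharing < 0 || phase_sharing > 1) {
    stop_("phase_sharing must lie in [0, 1]")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, duration = duration,
                 informative_channels = informative_channels,
                 effect_size = effect_size, task_amplitude = task_amplitude,
                 amplitude_cv = amplitude_cv, hrf_peak = hrf_peak,
                 osc_freqs = osc_freqs, osc_amps = osc_amps,
                 drift_slope_range = drift_slope_range,
                 drift_sin_amp = drift_sin_amp, noise_sd = noise_sd,
                 phase_sharing = phase_sharing, seed = as.integer(seed)),
            class = "sim_config")
}

#' Hemodynamic impulse response
#'
#' Gamma-shaped kernel `(t / peak)^shape * exp(shape * (1 - t / peak))`:
#' zero at t = 0, unit amplitude at t = peak, non-negative everywhere.
#'
#' @param t Time in seconds (>= 0).
#' @param peak Peak time in seconds (default 6).
#' @param shape Shape exponent controlling the kernel width (default 4).
#' @return Response values, same length as `t`.
#' @export
hrf <- function(t, peak = 6, shape = 4) {
  stopifnot(all(t >= 0), peak > 0, shape > 0)
  (t / peak)^shape * exp(shape * (1 - t / peak))
}

# Task regressor: boxcar over the whole provided window convolved with the
# hemodynamic kernel, normalized to unit peak.
task_response <- function(n_samples, sampling_rate, hrf_peak) {
  t_kernel <- seq(0, 5 * hrf_peak, by = 1 / sampling_rate)
  k <- hrf(t_kernel, hrf_peak)
  box <- rep(1, n_samples)
  r <- stats::convolve(c(box, numeric(length(k))), rev(k), type = "open")
  r <- r[seq_len(n_samples)]
  r / max(r)
}

#' Simulate an fNIRS-like verbal-fluency-task dataset
#'
#' Per participant and channel the signal is the sum of: linear drift plus
#' a 0.02 Hz sinusoid; a group-dependent amplitude times the task response
#' (boxcar convolved with the hemodynamic kernel); region-shared
#' sinusoidal physiological oscillations; and white noise. Patients
#' (labels 1, first half of participants) have their task amplitude at the
#' informative channels multiplied by `1 - effect_size`. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param montage Optional [default_montage()]-style montage assigning
#'   channels to regions for oscillation-phase sharing; defaults to the
#'   packaged 52-channel montage when `n_channels` is 52, otherwise to a
#'   single shared region.
#' @return List with `dataset` (an [fnirs_dataset()]) and
#'   `informative_channels` (the planted ground-truth channel set).
#' @export
simulate_dataset <- function(config = sim_config(), montage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- 2L * config$n_per_group
  C <- config$n_channels
  S <- as.integer(round(config$duration * config$sampling_rate))
  tt <- (seq_len(S) - 1L) / config$sampling_rate
  if (is.null(montage) && C == 52L) montage <- default_montage()
  region <- if (is.null(montage)) rep("all", C) else montage$region[seq_len(C)]
  regions <- unique(region)
  resp <- task_response(S, config$sampling_rate, config$hrf_peak)
  labels <- c(rep(1L, config$n_per_group), rep(0L, config$n_per_group))
  local_seed(config$seed, {
    sig <- array(0, dim = c(n, C, S))
    n_osc <- length(config$osc_freqs)
    for (p in seq_len(n)) {
      # per-region oscillation phases for this participant
      phi_region <- matrix(stats::runif(length(regions) * n_osc, 0, 2 * pi),
                           length(regions), n_osc,
                           dimnames = list(regions, NULL))
      amp_p <- config$task_amplitude *
        (1 + config$amplitude_cv * stats::rnorm(1))
      for (ch in seq_len(C)) {
        amp <- abs(amp_p)
        if (labels[p] == 1L && ch %in% config$informative_channels) {
          amp <- amp * (1 - config$effect_size)
        }
        y <- amp * resp
        slope <- stats::runif(1, config$drift_slope_range[1L],
                              config$drift_slope_range[2L])
        y <- y + slope * tt / config$duration +
          config$drift_sin_amp * sin(2 * pi * 0.02 * tt +
                                       stats::runif(1, 0, 2 * pi))
        phi_own <- stats::runif(n_osc, 0, 2 * pi)
        w <- config$phase_sharing
        for (o in seq_len(n_osc)) {
          phi <- w * phi_region[region[ch], o] + (1 - w) * phi_own[o]
          y <- y + config$osc_amps[o] *
            sin(2 * pi * config$osc_freqs[o] * tt + phi)
        }
        y <- y + stats::rnorm(S, 0, config$noise_sd)
        sig[p, ch, ] <- y
      }
    }
    list(dataset = fnirs_dataset(sig, config$sampling_rate, labels),
         informative_channels = config$informative_channels)
  })
}
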