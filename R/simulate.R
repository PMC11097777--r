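#' Synthetic RSVP recording configuration
#'
#' Generative parameters for an oddball RSVP session: stimuli arrive at
#' `stimulus_rate` (10 Hz), each is a target with probability `target_prob`
#' (the paradigm uses 1-4%), and every target adds a Gaussian-shaped positive
#' P300 deflection peaking `p300_latency` ms post-stimulus over
#' centro-parietal channels, with per-event latency jitter (truncated at
#' +/- 3 SD) and lognormal amplitude variability (sigma 0.3, mean 1).
#' The background is spatially mixed 1/f noise plus a 10 Hz alpha oscillation
#' with random per-channel phase plus white sensor noise. Overlapping target
#' responses superpose linearly, as in real RSVP.
#'
#' @param n_channels,sampling_rate,stimulus_rate Recording geometry (defaults
#'   62 channels at 250 Hz, stimuli at 10 Hz).
#' @param n_stimuli Number of stimulus presentations.
#' @param target_prob Target probability; values outside \[0.01, 0.04\] are
#'   accepted with a warning (balanced sets are useful in tests).
#' @param p300_amplitude Peak amplitude in microvolts at the best channel
#'   (0 gives the null model: labels independent of the data).
#' @param p300_latency,latency_jitter_sd,p300_width_sd Template latency,
#'   per-event latency jitter SD and Gaussian width SD, all in ms.
#' @param topography Per-channel gain in \[0, 1\] (maximum exactly 1);
#'   default peaks at three designated centro-parietal indices and decays
#'   exponentially with channel-index distance.
#' @param one_over_f_exponent,pink_sd Spectral exponent and RMS (microvolts)
#'   of the 1/f background.
#' @param alpha_amplitude,white_sd Alpha oscillation amplitude and white
#'   noise SD (microvolts).
#' @param spatial_mixing Channel-correlation strength in \[0, 1): each
#'   channel mixes `sqrt(1-m^2)` own noise with `m` shared noise.
#' @param overlap If `FALSE`, stimuli are spaced one full epoch apart so
#'   trials are independent (unit-test mode).
#' @param seed RNG seed; all draws are from the R generator in a fixed
#'   documented order (labels, background noise, per-event effects).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 62L, sampling_rate = 250,
                       stimulus_rate = 10, n_stimuli = 2000L,
                       target_prob = 0.02, p300_amplitude = 5,
                       p300_latency = 300, latency_jitter_sd = 30,
                       p300_width_sd = 60, topography = NULL,
                       one_over_f_exponent = 1, pink_sd = 5,
                       alpha_amplitude = 2, white_sd = 1,
                       spatial_mixing = 0.3, overlap = TRUE, seed = 1L) {
  if (sampling_rate <= 0 || stimulus_rate <= 0) stop("rates must be positive")
  if (p300_amplitude < 0) stop("p300_amplitude must be >= 0")
  if (target_prob < 0 || target_prob > 1) stop("target_prob must be in [0, 1]")
  if (target_prob < 0.01 || target_prob > 0.04)
    warning("target_prob ", target_prob,
            " is outside the usual RSVP range [0.01, 0.04]")
  if (spatial_mixing < 0 || spatial_mixing >= 1)
    stop("spatial_mixing must be in [0, 1)")
  if (is.null(topography)) topography <- default_topography(n_channels)
  if (length(topography) != n_channels || any(topography < 0))
    stop("topography must give one non-negative gain per channel")
  topography <- topography / max(topography)
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 stimulus_rate = stimulus_rate,
                 n_stimuli = as.integer(n_stimuli),
                 target_prob = target_prob,
                 p300_amplitude = p300_amplitude,
                 p300_latency = p300_latency,
                 latency_jitter_sd = latency_jitter_sd,
                 p300_width_sd = p300_width_sd,
                 topography = topography,
                 one_over_f_exponent = one_over_f_exponent,
                 pink_sd = pink_sd, alpha_amplitude = alpha_amplitude,
                 white_sd = white_sd, spatial_mixing = spatial_mixing,
                 overlap = isTRUE(overlap), seed = seed),
            class = "sim_config")
}

#' Default centro-parietal topography
#'
#' Gain 1 at three designated centro-parietal channel indices (around 45-52%
#' of the montage), decaying as `exp(-distance/6)` with channel-index
#' distance elsewhere. Arbitrary but fixed.
#'
#' @param n_channels Montage size.
#' @export
default_topography <- function(n_channels) {
  cp <- unique(pmax(1L, pmin(n_channels,
                             round(n_channels * c(0.45, 0.48, 0.52)))))
  d <- vapply(seq_len(n_channels),
              function(i) min(abs(i - cp)), numeric(1))
  exp(-d / 6)
}

# Gaussian deflection with unit peak, sampled on the epoch grid (ms).
gauss_wave <- function(n_samples, rate, latency_ms, width_ms) {
  t_ms <- (seq_len(n_samples) - 1L) / rate * 1000
  exp(-((t_ms - latency_ms)^2) / (2 * width_ms^2))
}

#' P300 template waveform
#'
#' Single-channel Gaussian positive deflection with unit peak at the
#' configured latency, sampled over one epoch; amplitude and channel
#' topography are applied at simulation time.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of one epoch length (e.g. 250 samples at 250 Hz).
#' @export
p300_template <- function(config) {
  n <- round(config$sampling_rate)            # one second epoch
  epoch_ms <- n / config$sampling_rate * 1000
  if (config$p300_latency < 0 ||
      config$p300_latency + 3 * config$p300_width_sd > epoch_ms)
    stop("P300 template (latency + 3 widths) leaks outside the epoch window")
  gauss_wave(n, config$sampling_rate, config$p300_latency,
             config$p300_width_sd)
}

# 1/f^beta noise of length n with unit RMS, via FFT spectral shaping of white
# Gaussian noise.
pink_noise <- function(n, beta) {
  x <- rnorm(n)
  if (beta == 0) return(x / stats::sd(x))
  k <- 0:(n - 1)
  fsym <- pmin(k, n - k)                      # two-sided frequency index
  shape <- c(0, fsym[-1]^(-beta / 2))         # symmetric; DC removed
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate a continuous RSVP recording
#'
#' Generates the event stream (Bernoulli targets), the structured background
#' (spatially mixed 1/f + alpha + white noise) and adds the jittered,
#' amplitude-varying P300 response of every target event; overlapping
#' responses superpose linearly. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [continuous_recording()].
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rate <- config$sampling_rate
  epoch_len <- round(rate)
  spacing <- if (config$overlap) round(rate / config$stimulus_rate)
             else epoch_len
  lead <- epoch_len
  n_total <- lead + (config$n_stimuli - 1L) * spacing + 2L * epoch_len
  nch <- config$n_channels

  labels <- rbinom(config$n_stimuli, 1L, config$target_prob)
  ev_samples <- lead + (seq_len(config$n_stimuli) - 1L) * spacing + 1L

  data <- matrix(0, nch, n_total)
  shared <- pink_noise(n_total, config$one_over_f_exponent)
  m <- config$spatial_mixing
  tt <- (seq_len(n_total) - 1L) / rate
  for (c in seq_len(nch)) {
    own <- pink_noise(n_total, config$one_over_f_exponent)
    phase <- runif(1, 0, 2 * pi)
    data[c, ] <- config$pink_sd * (sqrt(1 - m^2) * own + m * shared) +
      config$alpha_amplitude * sin(2 * pi * 10 * tt + phase) +
      rnorm(n_total, sd = config$white_sd)
  }

  if (config$p300_amplitude > 0 && any(labels == 1L)) {
    sigma <- 0.3
    for (i in which(labels == 1L)) {
      jit <- max(-3, min(3, rnorm(1))) * config$latency_jitter_sd
      amp <- config$p300_amplitude *
        stats::rlnorm(1, meanlog = -sigma^2 / 2, sdlog = sigma)
      wave <- gauss_wave(epoch_len, rate, config$p300_latency + jit,
                         config$p300_width_sd)
      idx <- ev_samples[i]:(ev_samples[i] + epoch_len - 1L)
      data[, idx] <- data[, idx] + outer(amp * config$topography, wave)
    }
  }

  continuous_recording(data, rate,
                       data.frame(sample = ev_samples, label = labels))
}

#' Simulate one subject's preprocessed epoch set
#'
#' Composes [simulate_recording()], the zero-phase 2-30 Hz Butterworth
#' [bandpass()], and [extract_epochs()] over 0-1000 ms, mirroring the
#' preprocessing a real recording receives. Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @param filter A [filter_spec()] (default 2-30 Hz, order 4, zero-phase).
#' @param window_ms Epoch window, default `c(0, 1000)` ms.
#' @return An [epoch_set()] of `n_stimuli` trials.
#' @export
simulate_subject <- function(config, filter = filter_spec(),
                             window_ms = c(0, 1000)) {
  rec <- simulate_recording(config)
  rec <- bandpass(rec, filter)
  extract_epochs(rec, window_ms)
}
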