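# Shared miniature fixtures. Everything is generated in code; the tiny
# network keeps the full four-stage architecture (both PSA blocks) at a size
# where a fit takes well under a second.

tiny_network_config <- function(psa1 = psa_config(8, c(3, 5)),
                                psa2 = psa_config(8, c(1, 3)),
                                dropout_p = 0.5, precision = "single") {
  network_config(n_channels = 6L, n_samples = 40L, temporal_filters = 4L,
                 temporal_kernel = 9L, depth_multiplier = 2L,
                 separable_kernel = 4L, pool_size = 4L,
                 dropout_p = dropout_p, psa_psfe = psa1, psa_dtfe = psa2,
                 precision = precision)
}

# Random labelled epochs matching tiny_network_config geometry; signal: class
# 1 carries a bump on channels 2-3 so the problem is learnable when
# amplitude > 0.
tiny_epochs <- function(n = 40L, amplitude = 3, seed = 1L,
                        target_prob = 0.5) {
  set.seed(seed)
  labels <- rbinom(n, 1L, target_prob)
  x <- array(rnorm(n * 6 * 40), c(n, 6, 40))
  bump <- exp(-((1:40 - 15)^2) / 18)
  for (i in which(labels == 1L))
    for (ch in 2:3) x[i, ch, ] <- x[i, ch, ] + amplitude * bump
  epoch_set(x, labels, sampling_rate = 40)
}

# A small continuous recording with a deterministic ramp, handy for indexing
# oracles.
ramp_recording <- function(n_channels = 3L, n_samples = 600L, rate = 250) {
  data <- matrix(rep(0:(n_samples - 1L), each = n_channels), n_channels)
  continuous_recording(data, rate,
                       data.frame(sample = c(101L, 201L),
                                  label = c(1L, 0L)))
}
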