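test_that("select_channels keeps requested channels in order", {
  set.seed(3)
  rec <- continuous_recording(matrix(rnorm(5 * 100), 5), 250,
                              data.frame(sample = 10L, label = 1L))
  out <- select_channels(rec, c(2L, 4L))
  expect_equal(nrow(out$data), 2L)
  expect_identical(out$data[1, ], rec$data[2, ])
  expect_identical(out$data[2, ], rec$data[4, ])
  expect_identical(out$channel_ids, c(2L, 4L))

  # identity case
  all_out <- select_channels(rec, 1:5)
  expect_identical(all_out$data, rec$data)

  # the default montage reduction: 64 -> 62, dropping electrodes 33 and 43
  rec64 <- continuous_recording(matrix(rnorm(64 * 50), 64), 250,
                                data.frame(sample = 1L, label = 0L))
  out62 <- select_channels(rec64)
  expect_equal(nrow(out62$data), 62L)
  expect_false(any(c(33L, 43L) %in% out62$channel_ids))

  expect_error(select_channels(rec, c(1L, 9L)), "9")
})

test_that("select_channels is idempotent for a fixed keep list", {
  set.seed(4)
  rec <- continuous_recording(matrix(rnorm(8 * 60), 8), 250,
                              data.frame(sample = 5L, label = 1L))
  keep <- c(1L, 3L, 5L)
  once <- select_channels(rec, keep)
  twice <- select_channels(select_channels(rec, keep), seq_along(keep))
  expect_identical(once$data, twice$data)
})

test_that("bandpass passes in-band and attenuates out-of-band sinusoids", {
  rate <- 250
  n <- 10 * rate
  t <- (0:(n - 1)) / rate
  ev <- data.frame(sample = 1L, label = 0L)
  core <- (2 * rate):(8 * rate)    # discard 2 s edges

  in_band <- continuous_recording(matrix(sin(2 * pi * 10 * t), 1), rate, ev)
  out <- bandpass(in_band, filter_spec(2, 30, 4))
  expect_lt(abs(max(abs(out$data[1, core])) - 1), 0.05)

  low <- continuous_recording(matrix(sin(2 * pi * 0.5 * t), 1), rate, ev)
  out_low <- bandpass(low, filter_spec(2, 30, 4))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out_low$data[1, core]) / rms(low$data[1, core]), 0.2)
})

test_that("bandpass suppresses out-of-band spectral power by >= 12 dB", {
  set.seed(11)
  rate <- 250
  x <- rnorm(20 * rate)
  rec <- continuous_recording(matrix(x, 1), rate,
                              data.frame(sample = 1L, label = 0L))
  out <- bandpass(rec, filter_spec(2, 30, 4))
  pg <- function(v) {
    s <- stats::spec.pgram(stats::ts(v, frequency = rate), taper = 0,
                           plot = FALSE, detrend = FALSE)
    s
  }
  s_out <- pg(out$data[1, ])
  inside <- s_out$freq >= 4 & s_out$freq <= 25
  outside <- (s_out$freq >= 40 & s_out$freq <= 120) | s_out$freq <= 1
  # white input has flat spectrum, so in/out band power ratio of the output
  # measures the filter response directly
  ratio_db <- 10 * log10(mean(s_out$spec[inside]) /
                         mean(s_out$spec[outside]))
  expect_gte(ratio_db, 12)
})

test_that("filtering is linear", {
  set.seed(12)
  rate <- 250
  fs <- filter_spec(2, 30, 4)
  mk <- function(v) continuous_recording(matrix(v, 1), rate,
                                         data.frame(sample = 1L, label = 0L))
  x <- rnorm(1000); y <- rnorm(1000)
  a <- 2.5; b <- -1.3
  lhs <- bandpass(mk(a * x + b * y), fs)$data
  rhs <- a * bandpass(mk(x), fs)$data + b * bandpass(mk(y), fs)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("bandpass rejects passband edges at or above Nyquist", {
  rec <- ramp_recording()
  expect_error(bandpass(rec, filter_spec(2, 125, 4)), "Nyquist")
})

test_that("extract_epochs indexes half-open windows bit-exactly", {
  rec <- ramp_recording()        # data value v at 1-based sample v+1
  es <- extract_epochs(rec, c(0, 1000))
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$epochs), c(2, 3, 250))
  # event at 1-based sample 101 (ramp value 100): first value 100, last 349
  expect_identical(es$epochs[1, 1, 1], 100)
  expect_identical(es$epochs[1, 1, 250], 349)
  expect_identical(es$epochs[2, 2, 1], 200)
  expect_identical(es$labels, c(1L, 0L))

  # event at the first sample with a (0, 1000) ms window: samples 1..250
  rec2 <- continuous_recording(rec$data, 250,
                               data.frame(sample = 1L, label = 1L))
  es2 <- extract_epochs(rec2, c(0, 1000))
  expect_equal(dim(es2$epochs)[3], 250L)
  expect_identical(es2$epochs[1, 1, ], as.numeric(0:249))

  # shifted window start
  es3 <- extract_epochs(rec, c(200, 600))
  expect_equal(dim(es3$epochs)[3], 100L)
  expect_identical(es3$epochs[1, 1, 1], 150)
})

test_that("extract_epochs handles zero events and window overruns", {
  rec <- ramp_recording()
  rec$events <- data.frame(sample = integer(0), label = integer(0))
  es <- extract_epochs(rec, c(0, 1000))
  expect_equal(dim(es$epochs)[1], 0L)
  expect_length(es$labels, 0L)

  rec_bad <- continuous_recording(matrix(0, 2, 300), 250,
                                  data.frame(sample = 200L, label = 1L))
  expect_error(extract_epochs(rec_bad, c(0, 1000)), "event 1")
})

test_that("recording and epoch-set constructors validate invariants", {
  expect_error(continuous_recording(matrix(0, 2, 10), -1,
                                    data.frame(sample = 1L, label = 0L)),
               "positive")
  expect_error(continuous_recording(matrix(0, 2, 10), 250,
                                    data.frame(sample = c(5L, 5L),
                                               label = c(0L, 1L))),
               "increasing")
  expect_error(epoch_set(array(0, c(2, 3, 4)), c(0L, 1L, 1L), 250),
               "labels length")
  expect_error(epoch_set(array(0, c(2, 3, 4)), c(0L, 2L), 250), "0 or 1")
})
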