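fs <- 22050

test_that("envelope of silence is silence", {
  z <- audio_buffer(rep(0, 1000), fs)
  expect_equal(extract_envelope(z, 300)$samples, rep(0, 1000))
})

test_that("steady-state envelope of a tone matches the rectified-sine oracle", {
  # oracle: mean of a half-wave rectified sine of amplitude A is A / pi,
  # carried through the unit-DC-gain low-pass
  a <- 0.8
  t <- seq(0, 1, length.out = fs)
  tone <- audio_buffer(a * sin(2 * pi * 1000 * t), fs)
  env <- extract_envelope(tone, 300)$samples
  steady <- env[2000:20000]
  expect_equal(mean(steady), a / pi, tolerance = 0.01)
})

test_that("envelope tracks a 4 Hz amplitude modulator", {
  t <- seq(0, 2, length.out = 2 * fs)
  modulator <- 1 + 0.9 * sin(2 * pi * 4 * t)
  am <- audio_buffer(0.3 * modulator * sin(2 * pi * 1000 * t), fs)
  env <- extract_envelope(am, 30)$samples
  keep <- 2000:(2 * fs - 2000)
  expect_gt(cor(env[keep], modulator[keep]), 0.95)
})

test_that("envelope cutoff at or above Nyquist is rejected", {
  buf <- audio_buffer(rnorm(100), fs)
  expect_error(extract_envelope(buf, fs / 2), "Nyquist")
})

test_that("vocoding preserves length and is deterministic given the seed", {
  t <- seq(0, 0.5, length.out = fs / 2)
  buf <- audio_buffer(sin(2 * pi * 440 * t), fs)
  p <- vocoder_params(n_bands = 4, noise_seed = 11)
  v1 <- vocode(buf, p)
  v2 <- vocode(buf, p)
  expect_equal(length(v1), length(buf))
  expect_identical(v1$samples, v2$samples)
  v3 <- vocode(buf, vocoder_params(n_bands = 4, noise_seed = 12))
  expect_false(identical(v1$samples, v3$samples))
})

test_that("a band-centered tone vocodes into its own band", {
  # oracle: periodogram band integration
  edges <- band_edges(greenwood_map(), 8, 50, 5000)
  t <- seq(0, 1, length.out = fs)
  for (j in c(3, 5, 7)) {
    fc <- sqrt(edges[j] * edges[j + 1])   # geometric band center
    tone <- audio_buffer(sin(2 * pi * fc * t), fs)
    v <- vocode(tone, vocoder_params(n_bands = 8, noise_seed = 3))
    p <- Mod(fft(v$samples))^2
    f <- (seq_along(p) - 1) * fs / length(p)
    half <- f <= fs / 2
    frac <- sum(p[half & f >= edges[j] & f <= edges[j + 1]]) / sum(p[half])
    expect_gt(frac, 0.7)
  }
})

test_that("single-band vocoding preserves the slow amplitude envelope", {
  set.seed(5)
  n <- 2 * fs
  t <- (0:(n - 1)) / fs
  carrier <- signal::filtfilt(signal::butter(2, c(100, 3000) / (fs / 2), "pass"),
                              rnorm(n))
  x <- (1 + 0.9 * sin(2 * pi * 3 * t)) * carrier  # syllable-rate modulation
  v <- vocode(audio_buffer(x, fs), vocoder_params(n_bands = 1, noise_seed = 2))
  bandin <- audio_buffer(
    signal::filtfilt(signal::butter(4, c(50, 4999) / (fs / 2), "pass"), x), fs)
  # compare smoothed envelopes: the noise carrier contributes envelope
  # jitter above the syllable rate, so both sides use a 30 Hz extractor
  e_in <- extract_envelope(bandin, 30)$samples
  e_out <- extract_envelope(v, 30)$samples
  keep <- 2000:(n - 2000)
  expect_gt(cor(e_in[keep], e_out[keep]), 0.9)
})

test_that("summed filterbank output reconstructs in-band energy", {
  # spectral oracle: energy in [f_lo, f_hi] via periodogram integration
  set.seed(9)
  n <- 2 * fs
  w <- rnorm(n)
  edges <- band_edges(greenwood_map(), 8, 50, 5000)
  s <- 0
  for (i in 1:8) {
    s <- s + signal::filtfilt(
      signal::butter(4, c(edges[i], edges[i + 1]) / (fs / 2), "pass"), w)
  }
  band_power <- function(sig, lo, hi) {
    p <- Mod(fft(sig))^2
    f <- (seq_along(p) - 1) * fs / length(p)
    sum(p[f >= lo & f <= hi])
  }
  expect_gt(band_power(s, 50, 5000) / band_power(w, 50, 5000), 0.9)
})

test_that("vocode validates its inputs", {
  expect_error(audio_buffer(numeric(0), fs), "empty")
  buf <- audio_buffer(rnorm(100), 16000)
  expect_error(vocode(buf, vocoder_params(sample_rate = fs)), "rate")
})

test_that("RMS normalization rescales exactly and idempotently", {
  set.seed(2)
  buf <- audio_buffer(rnorm(1000), fs)
  r <- audio_rms(buf)
  out <- rms_normalize(buf, 0.1)
  expect_equal(audio_rms(out), 0.1, tolerance = 1e-9)
  expect_equal(out$samples, buf$samples * (0.1 / r), tolerance = 1e-12)
  expect_equal(rms_normalize(out, 0.1)$samples, out$samples, tolerance = 1e-12)
  expect_error(rms_normalize(audio_buffer(rep(0, 10), fs), 0.1), "all-zero")
})

test_that("4- and 8-band vocoded outputs equate after normalization", {
  set.seed(4)
  t <- seq(0, 0.5, length.out = fs / 2)
  buf <- audio_buffer((1 + sin(2 * pi * 3 * t)) * rnorm(fs / 2, sd = 0.2), fs)
  target <- dbfs_to_amp(-20)
  v4 <- rms_normalize(vocode(buf, vocoder_params(n_bands = 4)), target)
  v8 <- rms_normalize(vocode(buf, vocoder_params(n_bands = 8)), target)
  expect_equal(audio_rms(v4), audio_rms(v8), tolerance = 1e-9)
})

test_that("WAV files round-trip in both supported encodings", {
  set.seed(3)
  buf <- audio_buffer(runif(500, -0.9, 0.9), fs)
  f32 <- tempfile(fileext = ".wav")
  p16 <- tempfile(fileext = ".wav")
  write_wav(buf, f32, "float32")
  write_wav(buf, p16, "pcm16")
  back32 <- read_wav(f32)
  back16 <- read_wav(p16)
  expect_equal(back32$rate, fs)
  expect_equal(back32$samples, buf$samples, tolerance = 1e-6)
  expect_equal(back16$samples, buf$samples, tolerance = 1 / 32768)
  unlink(c(f32, p16))
})
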