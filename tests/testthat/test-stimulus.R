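test_that("make_echoic superposes an impulse and its delayed copy", {
  imp <- impulse_track(0.2)
  mix <- make_echoic(imp, echo_spec(1, 0.125))
  idx <- which(mix$samples != 0)
  expect_equal(idx, round(c(0.2, 0.325) * 8000) + 1L)
  expect_equal(mix$samples[idx], c(1, 1))
  expect_equal(track_length(mix), track_length(imp) + 1000L)
})

test_that("a unit-gain echo at half period cancels a 4 Hz sinusoid", {
  rate <- 8000
  t <- (0:(2 * rate - 1)) / rate
  s <- audio_track(sin(2 * pi * 4 * t), rate)
  mix <- make_echoic(s, echo_spec(1, 0.125))
  overlap <- (0.125 * rate + 1):(2 * rate)   # both components present
  expect_lt(max(abs(mix$samples[overlap])), 1e-9)
})

test_that("make_echoic is linear and validates its inputs", {
  set.seed(1)
  a <- audio_track(rnorm(4000), 8000)
  b <- audio_track(rnorm(4000), 8000)
  spec <- echo_spec(0.7, 0.25)
  lhs <- make_echoic(audio_track(a$samples + b$samples, 8000), spec)
  rhs <- make_echoic(a, spec)$samples + make_echoic(b, spec)$samples
  expect_equal(lhs$samples, rhs)
  expect_error(make_echoic(a, echo_spec(1, 0.1001)), "not an integer number")
  expect_error(make_echoic(a, echo_spec(1, 2)), "shorter")
  expect_error(echo_spec(0), "positive")
})

test_that("variable-delay schedules apply segment-wise delays", {
  rate <- 8000
  x <- numeric(4 * rate)
  x[c(0.5, 2.5) * rate + 1] <- 1                 # impulses in each segment
  spec <- echo_spec(1, schedule = data.frame(start = c(0, 2),
                                             delay = c(0.125, 0.25)))
  mix <- make_echoic(audio_track(x, rate), spec)
  idx <- which(mix$samples > 0.5)
  expect_equal(idx, c(0.5, 0.625, 2.5, 2.75) * rate + 1)
})

test_that("RMS gain matches theory for decorrelated signals", {
  expect_equal(rms_gain_db(impulse_track(0.1), impulse_track(0.1)), 0)
  cfg <- tiny_cfg(duration_s = 120, seed = 3)
  aud <- synth_speech_audio(cfg)
  g1 <- rms_gain_db(make_echoic(aud, echo_spec(1, 0.125)), aud)
  g2 <- rms_gain_db(make_echoic(aud, echo_spec(0.5, 0.125)), aud)
  expect_equal(g1, 10 * log10(2), tolerance = 0.05 / 3)
  expect_equal(g2, 10 * log10(1.25), tolerance = 0.05)
  silent <- audio_track(numeric(100) + 0, 100)
  expect_error(rms_gain_db(silent, silent), "silent")
})

test_that("echo-related frequencies are the odd multiples of 1/(2 delay)", {
  expect_equal(echo_related_frequencies(0.125, 10), 4)
  expect_equal(echo_related_frequencies(0.25, 10), c(2, 6))
  expect_equal(echo_related_frequencies(0.25, 15), c(2, 6, 10, 14))
  expect_equal(echo_related_frequencies(0.125, 4), numeric(0))
})

test_that("echo transfer function vanishes only at the echo-related frequencies", {
  f <- seq(0.01, 20, by = 0.01)
  for (tau in c(0.125, 0.25)) {
    H <- Mod(1 + exp(-2i * pi * f * tau))
    zeros <- f[H < 1e-3]
    expect_true(all(vapply(zeros, function(z) {
      min(abs(z - echo_related_frequencies(tau, 21))) < 0.02
    }, logical(1))))
    # A != 1 never cancels fully
    expect_gt(min(Mod(0.5 + exp(-2i * pi * f * tau))), 0.4)
  }
})

test_that("mixture power approaches (A^2+1) x direct power as duration grows", {
  errs <- vapply(c(30, 120, 480), function(dur) {
    aud <- synth_speech_audio(tiny_cfg(duration_s = dur, seed = 7))
    mix <- make_echoic(aud, echo_spec(1, 0.125))
    n <- track_length(aud)
    abs(mean(mix$samples[1:n]^2) / mean(aud$samples^2) - 2)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 0.02)   # shrinking with duration
})

test_that("segment_pauses finds silent gaps", {
  allz <- envelope_track(numeric(1000) + 0, 200)
  p <- segment_pauses(allz)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(0, 5))

  env <- gapped_envelope(gap_start = 2, gap_len = 0.6)
  p <- segment_pauses(env, 0.5)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 2, tolerance = 0.02)
  expect_equal(p$duration, 0.6, tolerance = 0.02)

  expect_equal(nrow(segment_pauses(gapped_envelope(gap_len = 0.3), 0.5)), 0L)
})

test_that("speech stretches between long pauses average about 3.4 s", {
  env <- speech_like_envelope(synth_config(duration_s = 600, seed = 42))
  ipi <- echostream:::inter_pause_intervals(env)
  expect_gt(length(ipi), 50)
  expect_equal(mean(ipi), 3.4, tolerance = 0.8 / 3.4)
})

test_that("one-channel vocoding preserves RMS and the broadband envelope", {
  cfg <- tiny_cfg(duration_s = 20, seed = 4)
  aud <- synth_speech_audio(cfg)
  spec <- echo_spec(1, 0.125)
  voc <- vocode_one_channel(aud, spec, seed = 2)
  mix <- make_echoic(aud, spec)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(voc$samples) / rms(mix$samples), 1, tolerance = 1e-6)
  expect_gt(stats::cor(extract_envelope_broadband(voc)$values,
                       extract_envelope_broadband(mix)$values), 0.9)
  expect_error(vocode_one_channel(audio_track(rnorm(8000), 8000), spec),
               "8 kHz")
})

test_that("vocoding silence gives silence and flattens fine structure", {
  rate <- 16000
  silent <- audio_track(rep(1e-30, rate), rate)
  voc <- vocode_one_channel(silent, echo_spec(1, 0.125), seed = 1)
  expect_lt(max(abs(voc$samples)), 1e-12)

  # harmonic complex: energy on a line spectrum; vocoding spreads it
  t <- (0:(2 * rate - 1)) / rate
  harm <- audio_track(rowSums(sapply(1:8, function(h) sin(2 * pi * 220 * h * t) / h)), rate)
  voch <- vocode_one_channel(harm, echo_spec(1, 0.125), seed = 3)
  flatness <- function(x) {
    p <- Mod(stats::fft(x))^2
    n <- length(p)
    f <- (seq_len(n) - 1) * rate / n
    p <- p[f > 100 & f < 3000]
    exp(mean(log(p + 1e-20))) / mean(p)
  }
  expect_gt(flatness(voch$samples[1:rate]), 10 * flatness(harm$samples[1:rate]))
})

test_that("broadband envelope extraction matches closed forms", {
  rate <- 16000
  const <- audio_track(rep(0.5, rate), rate)
  e <- extract_envelope_broadband(const)
  expect_equal(track_rate(e), 100)
  expect_equal(mean(e$values[20:80]), 0.5, tolerance = 0.02)

  tone <- audio_track(0.7 * sin(2 * pi * 1000 * (0:(5 * rate - 1)) / rate), rate)
  et <- extract_envelope_broadband(tone)
  expect_equal(mean(et$values[100:400]), 2 * 0.7 / pi, tolerance = 0.02)

  t <- (0:(10 * rate - 1)) / rate
  am <- audio_track((1 + 0.8 * sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t), rate)
  ea <- extract_envelope_broadband(am)
  v <- ea$values - mean(ea$values)
  f <- (seq_along(v) - 1) * 100 / length(v)
  keep <- f > 0.3 & f < 50
  expect_equal(f[keep][which.max(Mod(stats::fft(v))[keep])], 4, tolerance = 0.05)
  expect_true(all(ea$values >= 0))
})
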