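test_that("compiled recursion matches the plain-R oracle bit for bit", {
  set.seed(1)
  sp <- aud_spectrogram(matrix(stats::runif(8 * 1000), 8), 200)  # 5-s fixture
  for (p in list(adaptation_params(0.2, 300, 300),
                 adaptation_params(0.6, 50, 450),
                 adaptation_params(0.05, 450, 50))) {
    a <- adapt(sp, p)
    b <- adapt(sp, p, engine = "reference")
    expect_identical(a$r, b$r)
    expect_identical(a$envelope$values, b$envelope$values)
  }
})

test_that("the identity limit returns the input", {
  set.seed(2)
  sp <- aud_spectrogram(matrix(stats::runif(4 * 400), 4), 200)
  a <- adapt(sp, adaptation_params(1e-12, 0, 0), normalize = FALSE)
  expect_equal(a$r, sp$values, tolerance = 1e-10)
  # with normalization the output is the input on the normalized scale
  an <- adapt(sp, adaptation_params(1e-12, 0, 0))
  q <- stats::quantile(sp$values, 0.95, names = FALSE)
  expect_equal(an$r, sp$values / q, tolerance = 1e-10)
})

test_that("constant input below threshold produces zero output", {
  sp <- aud_spectrogram(matrix(0.1, 2, 200), 200)
  a <- adapt(sp, adaptation_params(0.5, 0, 0), normalize = FALSE)
  expect_equal(max(a$r), 0)
})

test_that("depression suppresses the response to a repeated pulse", {
  env <- numeric(600)
  env[100:110] <- 1
  env[125:135] <- 1                        # echo pulse 0.125 s later
  sp <- aud_spectrogram(matrix(rep(env, each = 4), 4), 200)
  a <- adapt(sp, adaptation_params(0.2, 300, 300), normalize = FALSE)
  r1 <- sum(a$envelope$values[100:110])
  r2 <- sum(a$envelope$values[125:135])
  expect_gt(r1, 0)
  expect_lt(r2, r1)
})

test_that("gain control stays in (0, 1] and output is bounded and monotone in V", {
  set.seed(3)
  sp <- aud_spectrogram(matrix(stats::runif(6 * 600), 6), 200)
  a <- adapt(sp, adaptation_params(0.3, 200, 400), normalize = FALSE,
             keep_intermediates = TRUE)
  expect_true(all(a$G > 0 & a$G <= 1))
  expect_true(all(a$r >= 0))
  expect_true(all(a$r <= sp$values + 1e-12))
  prev <- NULL
  for (V in c(0.1, 0.3, 0.6, 0.9)) {
    r <- adapt(sp, adaptation_params(V, 200, 400), normalize = FALSE)$r
    if (!is.null(prev)) expect_true(all(r <= prev + 1e-12))
    prev <- r
  }
  expect_error(adapt(aud_spectrogram(matrix(0.5, 2, 10), 200),
                     adaptation_params(0.2, 301, 300)), "whole number")
})

test_that("grid search returns the identity-like corner when input is the target", {
  env <- speech_like_envelope(tiny_cfg(duration_s = 30, seed = 2))
  sess <- list(list(spec = envelope_to_spectrogram(env, 8),
                    direct = echostream:::resample_track(env, 100)))
  grid <- adaptation_grid(V = c(0.001, 0.4), tau_sd = c(0, 400), tau_gc = c(0, 400))
  fp <- fit_adaptation_params(sess, grid)
  expect_equal(fp$V, 0.001)
  expect_equal(fp$tau_sd, 0)
  expect_equal(fp$tau_gc, 0)
  expect_equal(nrow(attr(fp, "scores")), 8L)

  g1 <- adaptation_grid(V = 0.3, tau_sd = 100, tau_gc = 100)
  fp1 <- fit_adaptation_params(sess, g1)
  expect_equal(unclass(fp1)[c("V", "tau_sd", "tau_gc")],
               list(V = 0.3, tau_sd = 100, tau_gc = 100))
  expect_error(adaptation_grid(V = numeric(0)), "empty grid")
})

test_that("adaptation restores the 4 Hz notch for a 0-dB echo but degrades it for a 6-dB echo", {
  cfg <- tiny_cfg(duration_s = 240, seed = 11)
  env <- speech_like_envelope(cfg)
  p <- adaptation_params(0.2, 300, 300)
  d100 <- echostream:::resample_track(env, 100)
  c4 <- function(resp) {
    co <- phase_coherence(d100, resp$values[seq_len(track_length(d100))])
    co$coherence[co$frequency == 4]
  }
  res <- sapply(c(1, 0.5), function(A) {
    mix <- make_echoic(env, echo_spec(A, 0.125))
    un <- c4(echostream:::resample_track(mix, 100))
    sg <- envelope_to_spectrogram(
      envelope_track(mix$values[seq_len(track_length(env))], 200), 32)
    ad <- c4(echostream:::resample_track(adapt(sg, p)$envelope, 100))
    c(unadapted = un, adapted = ad)
  })
  expect_gt(res["adapted", 1], res["unadapted", 1])   # 0-dB: helps
  expect_lt(res["adapted", 2], res["unadapted", 2])   # 6-dB: hurts
})

test_that("adapted coherence: partial restoration between notch and anechoic levels", {
  cfg <- tiny_cfg(duration_s = 240, seed = 13)
  env <- speech_like_envelope(cfg)
  p <- adaptation_params(0.2, 300, 300)
  d100 <- echostream:::resample_track(env, 100)
  mix <- make_echoic(env, echo_spec(1, 0.25))
  sg_mix <- envelope_to_spectrogram(
    envelope_track(mix$values[seq_len(track_length(env))], 200), 32)
  sg_ane <- envelope_to_spectrogram(env, 32)
  co_ad <- adapted_coherence_spectrum(list(spec = sg_mix, direct = d100), p)
  co_an <- adapted_coherence_spectrum(list(spec = sg_ane, direct = d100), p)
  un <- phase_coherence(d100, echostream:::resample_track(mix, 100)$values[
    seq_len(track_length(d100))])
  at6 <- function(co) co$coherence[co$frequency == 6]
  expect_gt(at6(co_ad), at6(un))      # boosted above ideal-tracking notch
  expect_lt(at6(co_ad), at6(co_an))   # but below the anechoic curve
  # anechoic self-tracking: strongly driven low bins far above chance
  # (the adaptation nonlinearity keeps the squared coherence below 1)
  expect_gt(min(co_an$coherence[co_an$frequency %in% c(2, 3, 4)]),
            25 / attr(co_an, "n_epochs"))
  expect_gt(max(co_an$coherence[co_an$frequency %in% c(2, 3, 4)]), 0.4)
})
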