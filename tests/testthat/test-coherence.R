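test_that("epoch segmentation produces the DFT bin grid", {
  env <- envelope_track(abs(sin(seq_len(12000) / 50)) + 0.1, 100)
  ph <- epoch_phases(env, env$values, epoch_len_s = 2)
  expect_equal(ph$n_epochs, 60L)
  expect_equal(ph$frequency[1:4], c(0, 0.5, 1, 1.5))
  expect_equal(max(ph$frequency), 50)
  expect_true(all(abs(ph$theta) <= pi + 1e-12))
  expect_error(epoch_phases(envelope_track(1:100 / 100, 100), 1:100 / 100,
                            epoch_len_s = 2), "shorter")
})

test_that("identical signals give zero phase difference and coherence 1", {
  set.seed(4)
  v <- abs(rnorm(2000)) + 0.1
  env <- envelope_track(v, 100)
  ph <- epoch_phases(env, v, epoch_len_s = 2)
  expect_lt(max(abs(ph$theta)), 1e-8)
  expect_equal(unname(coherence(ph)), rep(1, length(ph$frequency)),
               tolerance = 1e-10)
})

test_that("a pure delay gives a constant, frequency-proportional phase lag", {
  set.seed(5)
  v <- abs(rnorm(4000)) + 0.2
  lag <- 10                                  # 0.1 s at 100 Hz
  stim <- envelope_track(v, 100)
  # delay realized circularly within each epoch: the shift theorem is exact
  resp <- as.vector(apply(matrix(v, 200), 2, function(e) {
    c(e[(200 - lag + 1):200], e[1:(200 - lag)])
  }))
  ph <- epoch_phases(stim, resp, epoch_len_s = 2)
  co <- coherence(ph)
  expect_equal(unname(co[ph$frequency > 0]),
               rep(1, sum(ph$frequency > 0)), tolerance = 1e-9)
  i4 <- which(ph$frequency == 4)
  expected <- echostream:::wrap_pi(2 * pi * 4 * 0.1)
  expect_equal(max(abs(ph$theta[i4, ] - expected)), 0, tolerance = 1e-8)

  # a genuine (non-circular) delay still yields high coherence; epoch-edge
  # mismatch (0.1 s of each 2-s epoch) keeps it below 1
  v2 <- abs(rnorm(12000)) + 0.2
  resp2 <- c(rep(v2[1], lag), v2[1:(12000 - lag)])
  co2 <- phase_coherence(envelope_track(v2, 100), resp2)
  expect_gt(min(co2$coherence[co2$frequency > 0 & co2$frequency < 20]), 0.5)
})

test_that("coherence matches hand-computed phase configurations", {
  ph <- structure(list(frequency = 1, theta = matrix(c(0, pi / 2, pi, 3 * pi / 2), 1),
                       n_epochs = 4L), class = "epoch_phases")
  expect_equal(coherence(ph), 0, tolerance = 1e-12)
  ph$theta <- matrix(rep(1.3, 4), 1)
  expect_equal(coherence(ph), 1, tolerance = 1e-12)
  expect_equal(coherence(ph, type = "resultant"), 1, tolerance = 1e-12)
})

test_that("chance-level coherence matches the Monte-Carlo oracle for independent phases", {
  # frozen oracle values, computed from 4000 draws of T iid uniform phases:
  # squared mean resultant has expectation 1/T; unsquared ~ 0.886/sqrt(T)
  set.seed(3)
  T <- 390L
  mc <- replicate(4000, {
    th <- stats::runif(T, -pi, pi)
    Mod(mean(exp(1i * th)))
  })
  expect_equal(mean(mc^2), 1 / T, tolerance = 0.05)
  expect_equal(mean(mc), sqrt(pi) / (2 * sqrt(T)), tolerance = 0.02)

  # independent stimulus/response pair hits that chance level
  set.seed(6)
  stim <- envelope_track(abs(rnorm(78000)) + 0.1, 100)
  resp <- abs(rnorm(78000)) + 0.1
  co <- phase_coherence(stim, resp)
  mid <- co$coherence[co$frequency > 1 & co$frequency < 40]
  expect_equal(mean(mid), 1 / 390, tolerance = 0.2)
})

test_that("coherence is invariant to a constant per-channel phase offset", {
  cfg <- tiny_cfg(duration_s = 60, seed = 12, n_channels = 1, snr_db = 10,
                  regime = "idealized")
  ss <- synth_session(cfg)
  resp <- ss$recording$data[1, ]
  co0 <- phase_coherence(ss$streams$direct, resp)
  # constant phase offset applied exactly: circular delay within each epoch
  L <- 200
  T <- length(resp) %/% L
  shifted <- as.vector(apply(matrix(resp[1:(T * L)], L), 2, function(e) {
    c(e[(L - 14):L], e[1:(L - 15)])
  }))
  co1 <- phase_coherence(ss$streams$direct, shifted)
  keep <- co0$frequency > 0
  expect_equal(co0$coherence[keep], co1$coherence[keep], tolerance = 1e-9)
})

test_that("shuffle null yields the (M+1)/(n+1) significance convention", {
  cfg <- tiny_cfg(duration_s = 120, seed = 7, n_channels = 2, snr_db = 5,
                  regime = "idealized")
  ss <- synth_session(cfg)
  cn <- chance_null(ss$streams$direct, ss$recording, n_shuffles = 99, seed = 2)
  expect_true(all(cn$p >= 1 / 100))
  # strongly driven low-frequency bins beat all 99 nulls
  expect_equal(min(cn$p[cn$frequency %in% c(2, 3)]), 1 / 100)
  expect_true(all(cn$observed >= 0 & cn$observed <= 1))
  expect_true(all(cn$p_fdr >= cn$p - 1e-12))
})

test_that("shuffle-null p-values are uniform under independence", {
  set.seed(9)
  n_rep <- 200
  ps <- replicate(n_rep, {
    stim <- envelope_track(abs(rnorm(3000)) + 0.1, 100)
    resp <- abs(rnorm(3000)) + 0.1
    cn <- chance_null(stim, resp, n_shuffles = 39, seed = sample.int(1e6, 1))
    cn$p[cn$frequency == 4]
  })
  rej <- mean(ps <= 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
  expect_gt(mean(ps), 0.4)   # grid-uniform mean ~ 0.5
})
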