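test_that("lag expansion has the right shape and alignment", {
  set.seed(1)
  n <- 1200
  s <- abs(rnorm(n)) + 0.1
  resp <- matrix(rnorm(n), 1)
  d <- build_design(list(list(streams = list(mixture = s), response = resp)),
                    "mixture", n_lags = 100)
  expect_equal(dim(d$X), c(n - 100, 100))
  expect_equal(dim(d$Y), c(n - 100, 1))
  # column tau holds s(t - tau)
  expect_equal(d$X[1, 7], s[101 - 7])
  expect_equal(d$X[50, 100], s[150 - 100])
})

test_that("single fixed-delay streaming designs are rank-deficient; pooling repairs them", {
  cfg <- tiny_cfg(duration_s = 60, seed = 5, n_channels = 2)
  ss <- synth_participant(cfg, specs = list(echo_spec(1, 0.25)))
  expect_warning(d1 <- build_design(ss[[1]], "streaming"), "rank-deficient")
  expect_lt(d1$diag$sv_ratio, 1e-6)

  ss2 <- synth_participant(cfg)          # 0.125 s + 0.25 s pooled
  d2 <- build_design(ss2, "streaming")
  expect_gt(d2$diag$sv_ratio, 1e-6)
  expect_gt(d1$diag$condition / d2$diag$condition, 10)
})

test_that("ridge at lambda 0 equals OLS on an orthonormal design", {
  set.seed(2)
  n <- 600
  Q <- qr.Q(qr(matrix(rnorm(n * 20), n)))
  w <- rnorm(20)
  y <- Q %*% w
  d <- structure(list(X = Q, Y = cbind(y), kind = "mixture",
                      streams = "mixture", n_lags = 20,
                      session = rep(1, n),
                      diag = list(sv_ratio = 1, condition = 1)),
                 class = "trf_design")
  fit <- fit_ridge(d, 0)
  ols <- qr.solve(sweep(Q, 2, colMeans(Q)), y - mean(y))
  expect_equal(unname(fit$W[, 1]), unname(drop(ols)), tolerance = 1e-8)
  expect_error(fit_ridge(d, -1), "nonnegative")
})

test_that("closed-form ridge equals the augmented least-squares oracle", {
  set.seed(3)
  n <- 500; p <- 30
  X <- matrix(rnorm(n * p), n)
  y <- X %*% rnorm(p) + rnorm(n)
  d <- structure(list(X = X, Y = cbind(y), kind = "mixture",
                      streams = "mixture", n_lags = p, session = rep(1, n),
                      diag = list(sv_ratio = 1, condition = 1)),
                 class = "trf_design")
  lambda <- 3.7
  fit <- fit_ridge(d, lambda)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w_aug <- qr.solve(rbind(Xc, diag(sqrt(lambda), p)), c(yc, numeric(p)))
  expect_equal(unname(fit$W[, 1]), unname(drop(w_aug)), tolerance = 1e-6)
})

test_that("noiseless streaming data yields exact kernel recovery", {
  cfg <- tiny_cfg(duration_s = 120, seed = 5, n_channels = 4, snr_db = Inf)
  ss <- synth_participant(cfg)
  d <- build_design(ss, "streaming")
  fit <- fit_ridge(d, 0)
  kt <- ss[[1]]$truth$kernels
  g <- ss[[1]]$truth$gains
  for (ch in 1:4) {
    expect_gte(stats::cor(fit$kernels[1:50, "direct", ch], g[ch] * kt$direct), 0.99)
    expect_gte(stats::cor(fit$kernels[1:50, "echo", ch], g[ch] * kt$echo), 0.99)
  }
  td <- tidy(fit)
  expect_equal(nrow(td), 100 * 2 * 4)
  expect_equal(glance(fit)$kind, "streaming")
})

test_that("shrinkage limit sends kernels and predictive power to zero", {
  cfg <- tiny_cfg(duration_s = 60, seed = 9, n_channels = 1, snr_db = 0)
  ss <- synth_participant(cfg, specs = list(echo_spec(1, 0.25)))
  d <- build_design(ss, "mixture")
  fit <- fit_ridge(d, 1e12)
  expect_lt(max(abs(fit$W)), 1e-4)
  # predictions shrink toward a constant; held-out correlation collapses
  cv <- cross_validate(d, lambda_grid = 1e14)
  expect_lt(abs(cv$power), 0.02)
})

test_that("pure-noise responses have predictive power near zero, with no NaN across the lambda grid", {
  set.seed(7)
  n <- 4000
  s <- abs(rnorm(n)) + 0.1
  resp <- matrix(rnorm(n), 1)
  d <- build_design(list(list(streams = list(mixture = s), response = resp)),
                    "mixture", n_lags = 50)
  for (lam in 10^(0:6) * mean(apply(d$X, 2, stats::var))) {
    cv <- cross_validate(d, lambda_grid = lam)
    expect_true(all(is.finite(cv$folds$power)))
  }
  cv <- cross_validate(d)
  expect_lt(abs(cv$power), 2 / sqrt(n / 10))
  expect_error(cross_validate(build_design(
    list(list(streams = list(mixture = s[1:300]), response = resp[, 1:300, drop = FALSE])),
    "mixture", n_lags = 50)), "too short")
})

test_that("sufficient-statistics cross-validation matches the naive oracle", {
  cfg <- tiny_cfg(duration_s = 60, seed = 4, n_channels = 3, snr_db = 0)
  ss <- synth_participant(cfg)
  d <- build_design(ss, "streaming", n_lags = 40)
  lambda <- 10 * mean(apply(d$X, 2, stats::var))
  cv <- cross_validate(d, lambda_grid = lambda)
  expect_equal(cv$folds$power, naive_cv(d, lambda), tolerance = 1e-8)
})

test_that("the generating regime wins the model comparison in expectation", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- tiny_cfg(duration_s = 90, seed = 200 + s, n_channels = 16, snr_db = -5)
    ss <- synth_participant(cfg)
    cmp <- compare_trf_models(ss, n_lags = 60)
    wins <- wins + (cmp$kind[which.max(cmp$power)] == "streaming")
  }
  expect_gte(wins, 9L)
})

test_that("the identity-limit adaptation corner reduces the adapted TRF to the plain TRF", {
  cfg <- tiny_cfg(duration_s = 60, seed = 8, n_channels = 2, snr_db = 0)
  ss <- synth_participant(cfg)
  plain <- cross_validate(build_design(ss, "idealized"))
  ad <- fit_adapted_trf(ss, "idealized",
                        grid = adaptation_grid(V = 1e-14, tau_sd = 0, tau_gc = 0),
                        n_channels_spec = 8)
  expect_equal(ad$cv$power, plain$power, tolerance = 1e-10)
})

test_that("an adaptation front end in the generator favors the adapted TRF", {
  # build sessions whose responses are driven by adapted streams
  cfg <- tiny_cfg(duration_s = 90, seed = 10, n_channels = 4, snr_db = 0,
                  regime = "idealized")
  p_true <- adaptation_params(0.3, 300, 300)
  base <- synth_participant(cfg)
  sessions <- lapply(base, function(ss) {
    sp <- envelope_to_spectrogram(ss$streams_200$direct, 8)
    drive <- echostream:::resample_track(adapt(sp, p_true)$envelope, 100)
    n <- track_length(drive)
    resp <- ss$truth$gains %o% echostream:::conv_lagged(drive$values, cfg$kernels$direct)
    noise <- matrix(stats::rnorm(length(resp)), nrow(resp))
    resp <- resp + noise * stats::sd(resp[1, ]) / stats::sd(noise[1, ])
    ss$recording <- recording(resp, 100)
    ss
  })
  plain <- cross_validate(build_design(sessions, "idealized"))
  ad <- fit_adapted_trf(sessions, "idealized",
                        grid = adaptation_grid(V = 0.3, tau_sd = 300, tau_gc = 300),
                        n_channels_spec = 8)
  expect_gt(ad$cv$power, plain$power)
})

test_that("adapted model comparison preserves the streaming advantage", {
  cfg <- tiny_cfg(duration_s = 90, seed = 21, n_channels = 8, snr_db = -5)
  ss <- synth_participant(cfg)
  grid <- adaptation_grid(V = 0.2, tau_sd = 200, tau_gc = 200)
  ad_str <- fit_adapted_trf(ss, "streaming", grid = grid, n_channels_spec = 8)
  ad_mix <- fit_adapted_trf(ss, "mixture", grid = grid, n_channels_spec = 8)
  expect_gt(ad_str$cv$power, ad_mix$cv$power)
})

test_that("band-limited TRF matches the default pipeline on the full band and splits as expected", {
  cfg <- tiny_cfg(duration_s = 90, seed = 31, n_channels = 8, snr_db = -5)
  ss <- synth_participant(cfg)
  ss <- lapply(ss, function(s) {
    s$recording <- preprocess(s$recording)   # responses already 0.8-10 Hz
    s
  })
  expect_error(bandlimited_trf(ss, c(5, 2), "streaming"), "inverted band")
  full <- suppressWarnings(bandlimited_trf(ss, c(0.8, 10), "streaming"))
  plain <- cross_validate(build_design(ss, "streaming"))
  expect_equal(full$power, plain$power, tolerance = 0.08)
  lo_str <- suppressWarnings(bandlimited_trf(ss, c(0.8, 5), "streaming"))
  lo_mix <- suppressWarnings(bandlimited_trf(ss, c(0.8, 5), "mixture"))
  expect_gt(lo_str$power, lo_mix$power)
})
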