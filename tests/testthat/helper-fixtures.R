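# Small deterministic fixtures shared across test files.

tiny_cfg <- function(duration_s = 60, seed = 1L, n_channels = 4,
                     snr_db = Inf, regime = "streaming") {
  synth_config(duration_s = duration_s, seed = seed, n_channels = n_channels,
               snr_db = snr_db, regime = regime)
}

# impulse audio: single unit sample at t0 seconds
impulse_track <- function(t0, duration_s = 1, rate = 8000) {
  x <- numeric(duration_s * rate)
  x[round(t0 * rate) + 1L] <- 1
  audio_track(x, rate)
}

# envelope with a silent gap inserted in an otherwise voiced stretch
gapped_envelope <- function(gap_start = 2, gap_len = 0.6, duration_s = 6,
                            rate = 200) {
  v <- rep(1, duration_s * rate) + 0.1 * sin(2 * pi * 3 * seq_len(duration_s * rate) / rate)
  i0 <- round(gap_start * rate) + 1L
  v[i0:(i0 + round(gap_len * rate) - 1L)] <- 0
  envelope_track(pmax(v, 0), rate)
}

# naive cross-validation oracle: explicit per-fold ridge fits and
# per-channel correlations on raw matrices (independent of the
# sufficient-statistics path in cross_validate)
naive_cv <- function(design, lambda, n_folds = 10) {
  X <- design$X; Y <- design$Y
  n <- nrow(X)
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  out <- numeric(0)
  for (f in seq_len(n_folds)) {
    te <- (bounds[f] + 1):bounds[f + 1]
    tr <- setdiff(seq_len(n), te)
    mx <- colMeans(X[tr, , drop = FALSE]); my <- colMeans(Y[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, mx)
    Yc <- sweep(Y[tr, , drop = FALSE], 2, my)
    W <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, Yc))
    pred <- sweep(sweep(X[te, , drop = FALSE], 2, mx) %*% W, 2, my, `+`)
    out <- c(out, vapply(seq_len(ncol(Y)), function(ch) {
      stats::cor(pred[, ch], Y[te, ch])
    }, numeric(1)))
  }
  out
}
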