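#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator that emulates the study conditions:
#' a narrated story whose envelope carries syllabic (2-8 Hz) modulations and
#' pauses, and 204-gradiometer MEG responses generated under a known
#' encoding regime with 1/f background plus white sensor noise.
#'
#' Defaults mirror the study conditions: speech stretches between long
#' (> 500 ms) pauses average 3.4 s within 0.4-11.2 s; envelopes are
#' generated at 200 Hz so both 0.125-s and 0.25-s echo delays are whole
#' samples; responses are delivered at the 100 Hz analysis rate with 204
#' channels.
#'
#' @param duration_s Track duration in seconds (>= 30 s recommended for
#'   stable spectral estimates).
#' @param env_rate Envelope generation rate, Hz.
#' @param audio_rate Audio carrier rate, Hz.
#' @param analysis_rate Analysis rate of responses and predictors, Hz.
#' @param n_channels Number of sensor channels.
#' @param regime Encoding regime: `"mixture"`, `"streaming"`, or
#'   `"idealized"`.
#' @param snr_db Per-channel SNR in dB: variance of the stimulus-driven
#'   signal over variance of the total noise. `Inf` disables noise.
#' @param speech_mean_s,speech_shape Gamma mean/shape of speech-stretch
#'   durations (truncated to `speech_range_s`).
#' @param speech_range_s Admissible speech-stretch durations (s).
#' @param pause_range_s Pause durations, drawn uniformly (s); all exceed the
#'   500-ms criterion so every generated pause is a delay-switch candidate.
#' @param syllable_period_s,syllable_shape Gamma mean/shape of syllable
#'   inter-onset intervals (s).
#' @param syllable_width_s Range of syllable durations (s).
#' @param kernels Ground-truth response kernels per stream at
#'   `analysis_rate` (named list `direct`, `echo`, `mixture`); defaults to
#'   [default_kernels()].
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 60,
                         env_rate = 200,
                         audio_rate = 16000,
                         analysis_rate = 100,
                         n_channels = 204,
                         regime = c("streaming", "mixture", "idealized"),
                         snr_db = -10,
                         speech_mean_s = 3.4,
                         speech_shape = 2.2,
                         speech_range_s = c(0.4, 11.2),
                         pause_range_s = c(0.55, 1.1),
                         syllable_period_s = 0.21,
                         syllable_shape = 5,
                         syllable_width_s = c(0.09, 0.15),
                         kernels = NULL,
                         seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(duration_s > 0, env_rate > 0, analysis_rate > 0,
            env_rate %% analysis_rate == 0, n_channels >= 1)
  if (is.null(kernels)) kernels <- default_kernels(analysis_rate)
  structure(list(
    duration_s = duration_s, env_rate = env_rate, audio_rate = audio_rate,
    analysis_rate = analysis_rate, n_channels = as.integer(n_channels),
    regime = regime, snr_db = snr_db,
    speech_mean_s = speech_mean_s, speech_shape = speech_shape,
    speech_range_s = speech_range_s, pause_range_s = pause_range_s,
    syllable_period_s = syllable_period_s, syllable_shape = syllable_shape,
    syllable_width_s = syllable_width_s,
    kernels = kernels, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Ground-truth response kernels
#'
#' Biphasic gamma-shaped kernels, 0.5 s long, with positive peaks near 50 ms
#' (direct stream) and 100 ms (echo stream, higher amplitude), shapes
#' consistent with cortical envelope-following responses. The `mixture`
#' kernel (used when the whole echoic envelope is encoded) equals the direct
#' kernel.
#'
#' @param rate Sampling rate of the kernels, Hz.
#' @return Named list of numeric kernels (`direct`, `echo`, `mixture`),
#'   indexed by lag starting at one sample.
#' @export
default_kernels <- function(rate = 100) {
  t <- seq_len(round(0.5 * rate)) / rate
  gpulse <- function(peak, shape = 4) {
    r <- (shape - 1) / peak
    stats::dgamma(t, shape, rate = r)
  }
  biphasic <- function(p1, p2, mix = 0.55) {
    k <- gpulse(p1) - mix * gpulse(p2)
    k / max(abs(k))
  }
  list(direct = biphasic(0.05, 0.15),
       echo = 1.4 * biphasic(0.10, 0.22),
       mixture = biphasic(0.05, 0.15))
}

# Causal convolution with lags 1..length(k): y(t) = sum_tau k[tau] x(t - tau).
conv_lagged <- function(x, k) {
  n <- length(x)
  y <- stats::filter(c(0, x[-n]), k, method = "convolution", sides = 1)
  y <- as.numeric(y)
  y[is.na(y)] <- 0
  y
}

#' Generate a speech-like envelope
#'
#' A two-state (speech/pause) semi-Markov gate times syllable-like pulses:
#' speech stretches have Gamma-distributed durations matching the printed
#' pause statistics, pauses always exceed 500 ms, and within speech,
#' Hann-shaped syllables with Gamma-distributed inter-onset intervals
#' (mean ~210 ms) and lognormal amplitudes produce a modulation spectrum
#' peaked in the 2-8 Hz syllabic range. Syllables are brief relative to the
#' echo delays, so the envelope decorrelates (|rho| < 0.05) beyond 100 ms,
#' the property that makes the echoic mixture 3.01 dB stronger than the
#' direct sound.
#'
#' @param cfg A [synth_config()].
#' @return An `envelope_track` at `cfg$env_rate`.
#' @export
speech_like_envelope <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, speech_like_envelope_impl(cfg))
}

speech_like_envelope_impl <- function(cfg) {
  rate <- cfg$env_rate
  n <- round(cfg$duration_s * rate)
  env <- numeric(n)

  # speech/pause gate
  t_cur <- 0
  segs <- list()
  while (t_cur < cfg$duration_s) {
    dur <- stats::rgamma(1, shape = cfg$speech_shape,
                         rate = cfg$speech_shape / cfg$speech_mean_s)
    dur <- min(max(dur, cfg$speech_range_s[1]), cfg$speech_range_s[2])
    segs[[length(segs) + 1L]] <- c(t_cur, min(t_cur + dur, cfg$duration_s))
    t_cur <- t_cur + dur + stats::runif(1, cfg$pause_range_s[1], cfg$pause_range_s[2])
  }

  # syllable pulses inside each speech stretch
  for (sg in segs) {
    t_on <- sg[1]
    while (t_on < sg[2]) {
      width <- stats::runif(1, cfg$syllable_width_s[1], cfg$syllable_width_s[2])
      amp <- stats::rlnorm(1, 0, 0.45)
      i0 <- round(t_on * rate) + 1L
      L <- max(2L, round(width * rate))
      i1 <- min(n, i0 + L - 1L)
      if (i0 <= n) {
        w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
        env[i0:i1] <- env[i0:i1] + amp * w[seq_len(i1 - i0 + 1L)]
      }
      gap <- stats::rgamma(1, shape = cfg$syllable_shape,
                           rate = cfg$syllable_shape / cfg$syllable_period_s)
      t_on <- t_on + max(gap, 1.2 * width)
    }
  }
  envelope_track(env, rate)
}

#' Speech-like audio carrier
#'
#' The speech-like envelope modulating a Gaussian white-noise carrier
#' (low-passed below 4 kHz). The carrier is serially uncorrelated, so the
#' audio autocorrelation vanishes at the echo lags and the RMS gain of the
#' 0-dB echoic mixture lands on the theoretical 3.01 dB.
#'
#' @param cfg A [synth_config()].
#' @return An `audio_track` at `cfg$audio_rate`.
#' @export
synth_speech_audio <- function(cfg = synth_config()) {
  env <- speech_like_envelope(cfg)
  q <- cfg$audio_rate / cfg$env_rate
  stopifnot(abs(q - round(q)) < 1e-9)
  ev <- rep(env$values, each = round(q))
  ev <- pmax(lowpass(ev, cfg$audio_rate, 90, order = 4), 0)
  cut <- min(4000, 0.45 * cfg$audio_rate)
  carrier <- with_seed(cfg$seed + 1013L,
                       lowpass(stats::rnorm(length(ev)), cfg$audio_rate, cut, order = 4))
  audio_track(ev * carrier, cfg$audio_rate)
}

#' Draw a variable-delay schedule aligned to pauses
#'
#' For every pause longer than 500 ms a new echo delay is drawn uniformly in
#' \[0.125 s, 0.25 s\] (quantized to the envelope sample grid), with the
#' switch placed at the pause midpoint so the splice is inaudible.
#'
#' @param env An `envelope_track` of the direct sound.
#' @param seed Integer seed.
#' @param delay_range Delay range in seconds.
#' @return An [echo_spec()] with amplitude 1 and a multi-segment schedule.
#' @export
draw_delay_schedule <- function(env, seed = 1L, delay_range = c(0.125, 0.25)) {
  p <- segment_pauses(env, 0.5)
  rate <- track_rate(env)
  rand_delay <- function(k) {
    lo <- round(delay_range[1] * rate); hi <- round(delay_range[2] * rate)
    sample(seq(lo, hi), k, replace = TRUE) / rate
  }
  with_seed(seed, {
    if (nrow(p) == 0L) {
      echo_spec(1, delay = rand_delay(1))
    } else {
      mids <- (p$start + p$end) / 2
      mids <- mids[mids > 0]
      echo_spec(1, schedule = data.frame(
        start = c(0, mids),
        delay = rand_delay(length(mids) + 1L)
      ))
    }
  })
}

# 1/f ("pink") noise with unit variance via FFT shaping.
pink_noise <- function(n, rate, f_floor = 0.3) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)            # two-sided symmetric frequency axis
  amp <- 1 / sqrt(pmax(f, f_floor))
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a multichannel recording under a known encoding regime
#'
#' Per channel, the response is a random mixing gain times the sum over
#' predictor streams of (ground-truth kernel convolved with the stream
#' envelope), plus 1/f background and white sensor noise scaled to the
#' configured per-channel SNR. The regimes differ in what the streams are:
#'
#' * `mixture`: one stream, the echoic-mixture envelope, with the
#'   `mixture` kernel (the brain encodes echoic speech as a whole);
#' * `streaming`: two streams, direct and echo envelopes, each with its own
#'   kernel (the brain segregates and separately encodes the two);
#' * `idealized`: one stream, the direct-sound envelope only.
#'
#' With `kernels = list(direct = 1, ...)` (a unit impulse at one lag) and
#' `snr_db = Inf`, the `idealized` response is exactly the scaled direct
#' envelope shifted by one sample: the ideal-tracking simulation.
#'
#' @param direct An `envelope_track` of the direct sound at `cfg$env_rate`.
#' @param spec An [echo_spec()].
#' @param cfg A [synth_config()]; `cfg$regime` picks the encoding regime.
#' @return A `synth_session`: list with envelope tracks (`direct`, `echo`,
#'   `mixture`, both at 200 Hz and at the analysis rate), the `recording`,
#'   and `truth` (regime, kernels, mixing gains).
#' @export
synth_recording <- function(direct, spec, cfg, gains = NULL) {
  stopifnot(inherits(direct, "envelope_track"), inherits(spec, "echo_spec"),
            inherits(cfg, "synth_config"))
  regime <- cfg$regime
  rate <- track_rate(direct)
  stopifnot(rate == cfg$env_rate)

  n <- track_length(direct)
  echo200 <- envelope_track(echo_component(direct$values, spec, rate)[seq_len(n)], rate)
  direct200 <- envelope_track(cfg_amp(spec) * direct$values, rate)
  mixture200 <- envelope_track(direct200$values + echo200$values, rate)

  to_ana <- function(e) resample_track(e, cfg$analysis_rate)
  streams <- list(direct = to_ana(direct200), echo = to_ana(echo200),
                  mixture = to_ana(mixture200))

  drive_streams <- switch(regime,
    mixture = list(mixture = streams$mixture),
    streaming = list(direct = streams$direct, echo = streams$echo),
    idealized = list(direct = streams$direct),
    stop(sprintf("unknown regime '%s'", regime), call. = FALSE)
  )
  kern <- cfg$kernels
  drive <- Reduce(`+`, lapply(names(drive_streams), function(nm) {
    conv_lagged(drive_streams[[nm]]$values, kern[[nm]])
  }))

  na <- length(drive)
  if (is.null(gains)) gains <- sensor_gains(cfg)
  stopifnot(length(gains) == cfg$n_channels)
  resp <- with_seed(cfg$seed + 271L, {
    sd_drive <- stats::sd(drive)
    mat <- matrix(0, cfg$n_channels, na)
    for (ch in seq_len(cfg$n_channels)) {
      sig <- gains[ch] * drive
      if (is.finite(cfg$snr_db)) {
        noise <- sqrt(0.8) * pink_noise(na, cfg$analysis_rate) +
          sqrt(0.2) * stats::rnorm(na)
        noise <- noise / stats::sd(noise)
        sig <- sig + noise * (abs(gains[ch]) * sd_drive) / 10^(cfg$snr_db / 20)
      }
      mat[ch, ] <- sig
    }
    list(mat = mat, gains = gains)
  })

  structure(list(
    streams_200 = list(direct = direct200, echo = echo200, mixture = mixture200),
    streams = streams,
    recording = recording(resp$mat, cfg$analysis_rate,
                          provenance = paste0("synthetic:", regime)),
    truth = list(regime = regime, kernels = kern, gains = resp$gains,
                 spec = spec, config = cfg)
  ), class = "synth_session")
}

cfg_amp <- function(spec) spec$amplitude

#' Sensor mixing gains for a simulated participant
#'
#' Signed per-channel gains (random sign, magnitude uniform in
#' \[0.5, 1.5\]) standing in for a sensor topography. Gains belong to the
#' participant, not the session: pooled conditions recorded from the same
#' participant must share them, or no single per-channel kernel can explain
#' the pooled data.
#'
#' @param cfg A [synth_config()].
#' @param seed Seed; defaults to a value derived from `cfg$seed`.
#' @return Numeric vector of length `cfg$n_channels`.
#' @export
sensor_gains <- function(cfg, seed = cfg$seed + 271L) {
  with_seed(seed, sample(c(-1, 1), cfg$n_channels, replace = TRUE) *
              stats::runif(cfg$n_channels, 0.5, 1.5))
}

#' Pooled sessions for one simulated participant
#'
#' Generates one session per echo condition with condition-specific
#' envelopes but participant-level sensor gains, ready for the pooled-delay
#' TRF analysis.
#'
#' @param cfg A [synth_config()]; `cfg$seed` identifies the participant.
#' @param specs List of [echo_spec()]s, one per condition (default the two
#'   fixed delays, 0.125 s and 0.25 s, at 0-dB echo gain).
#' @return List of `synth_session` objects sharing sensor gains.
#' @export
synth_participant <- function(cfg,
                              specs = list(echo_spec(1, 0.125), echo_spec(1, 0.25))) {
  gains <- sensor_gains(cfg)
  lapply(seq_along(specs), function(ci) {
    scfg <- cfg
    scfg$seed <- cfg$seed + 7919L * ci
    env <- speech_like_envelope(scfg)
    synth_recording(env, specs[[ci]], scfg, gains = gains)
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> regime = %s, %d channels, %.1f s @ %g Hz\n",
              x$truth$regime, nrow(x$recording$data),
              track_duration(x$recording), x$recording$rate))
  invisible(x)
}

#' Generate a complete synthetic session in one call
#'
#' Convenience wrapper: speech-like envelope + echoic mixture + recording.
#'
#' @param cfg A [synth_config()].
#' @param spec An [echo_spec()]; default 0-dB echo at 0.125 s.
#' @return A `synth_session`.
#' @export
synth_session <- function(cfg = synth_config(), spec = echo_spec(1, 0.125)) {
  synth_recording(speech_like_envelope(cfg), spec, cfg)
}

#' Save / load a session
#'
#' Sessions are runtime artifacts serialized with R's native RDS format.
#'
#' @param session A `synth_session` (or any pipeline stage output).
#' @param path Destination file.
#' @return `read_session` returns the deserialized object; `save_session`
#'   returns `path` invisibly.
#' @export
save_session <- function(session, path) {
  saveRDS(session, path)
  invisible(path)
}

#' @rdname save_session
#' @export
read_session <- function(path) readRDS(path)
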