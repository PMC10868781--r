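#' Echo specification
#'
#' Describes the echoic mixture `A * s(t) + s(t - tau(t))`: the gain `A`
#' applied to the direct sound and the delay schedule of the unit-gain echo.
#' A single schedule entry means a fixed delay; several entries (each a start
#' time on the output time axis and the delay active from that time) describe
#' a variable-delay echo whose switch points should fall inside speech pauses.
#'
#' Conventions follow the two experimental regimes: `amplitude = 1` is the
#' "0-dB echo" (echo as strong as the direct sound) and `amplitude = 0.5`
#' is the "6-dB echo" (echo twice as strong as the direct sound).
#'
#' @param amplitude Gain `A > 0` applied to the direct sound.
#' @param delay Fixed echo delay in seconds (used when `schedule` is NULL).
#' @param schedule Optional data frame with columns `start` (seconds,
#'   strictly increasing, first entry 0) and `delay` (seconds).
#' @return An object of class `echo_spec`.
#' @examples
#' echo_spec(1, delay = 0.125)
#' @export
echo_spec <- function(amplitude = 1, delay = NULL, schedule = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude <= 0) {
    stop("`amplitude` must be a single positive number", call. = FALSE)
  }
  if (is.null(schedule)) {
    if (is.null(delay)) stop("give either `delay` or `schedule`", call. = FALSE)
    schedule <- data.frame(start = 0, delay = delay)
  }
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("start", "delay") %in% names(schedule)))
  if (nrow(schedule) < 1L || schedule$start[1] != 0) {
    stop("schedule must start at time 0", call. = FALSE)
  }
  if (is.unsorted(schedule$start, strictly = TRUE)) {
    stop("schedule start times must be strictly increasing", call. = FALSE)
  }
  if (any(schedule$delay <= 0)) stop("delays must be positive", call. = FALSE)
  structure(list(amplitude = amplitude, schedule = schedule),
            class = "echo_spec")
}

#' @export
print.echo_spec <- function(x, ...) {
  cat(sprintf("<echo_spec> A = %g, %s\n", x$amplitude,
              if (nrow(x$schedule) == 1L)
                sprintf("fixed delay %g s", x$schedule$delay[1])
              else sprintf("variable delay (%d segments)", nrow(x$schedule))))
  invisible(x)
}

# Integer sample delay or an error naming the offending delay.
delay_samples <- function(delay_s, rate) {
  d <- delay_s * rate
  if (abs(d - round(d)) > 1e-8) {
    stop(sprintf("delay %g s is not an integer number of samples at %g Hz",
                 delay_s, rate), call. = FALSE)
  }
  as.integer(round(d))
}

# Unit-gain echo component on the output axis (length n + max delay).
# Variable-delay segments are joined by a short linear crossfade so switch
# points placed in pauses produce no discontinuity.
echo_component <- function(x, spec, rate, crossfade_s = 0.05) {
  n <- length(x)
  sched <- spec$schedule
  d <- vapply(sched$delay, delay_samples, integer(1), rate = rate)
  dmax <- max(d)
  out <- numeric(n + dmax)
  delayed <- function(di) c(numeric(di), x, numeric(dmax - di))
  starts <- pmin(pmax(round(sched$start * rate) + 1L, 1L), n + dmax)
  ends <- c(starts[-1] - 1L, n + dmax)
  xf <- max(0L, as.integer(round(crossfade_s * rate)))
  for (k in seq_len(nrow(sched))) {
    idx <- starts[k]:ends[k]
    out[idx] <- delayed(d[k])[idx]
    if (k > 1L && xf > 0L) {
      lo <- max(1L, starts[k] - xf %/% 2L)
      hi <- min(n + dmax, starts[k] + xf %/% 2L)
      w <- seq(0, 1, length.out = hi - lo + 1L)
      out[lo:hi] <- (1 - w) * delayed(d[k - 1L])[lo:hi] + w * delayed(d[k])[lo:hi]
    }
  }
  out
}

#' Construct an echoic mixture
#'
#' Forms `A * s(t) + s(t - tau(t))`. The output is longer than the input by
#' the maximum delay (the echo tail is kept); delays must be whole samples at
#' the track's rate. Works on audio tracks and on envelope tracks (where the
#' same superposition defines the mixture envelope).
#'
#' @param direct An `audio_track` or `envelope_track`, the direct sound.
#' @param spec An [echo_spec()].
#' @param crossfade_s Crossfade length (s) used at variable-delay switch
#'   points; irrelevant for fixed delays.
#' @return A track of the same class as `direct`.
#' @examples
#' s <- audio_track(rnorm(16000), 16000)
#' mix <- make_echoic(s, echo_spec(1, 0.125))
#' @export
make_echoic <- function(direct, spec, crossfade_s = 0.05) {
  stopifnot(inherits(spec, "echo_spec"))
  if (!inherits(direct, "audio_track") && !inherits(direct, "envelope_track")) {
    stop("`direct` must be an audio_track or envelope_track", call. = FALSE)
  }
  x <- track_values(direct)
  rate <- track_rate(direct)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (any(spec$schedule$delay >= length(x) / rate)) {
    stop("delay must be shorter than the track", call. = FALSE)
  }
  echo <- echo_component(x, spec, rate, crossfade_s)
  mix <- spec$amplitude * c(x, numeric(length(echo) - length(x))) + echo
  if (inherits(direct, "envelope_track")) envelope_track(mix, rate)
  else audio_track(mix, rate)
}

#' RMS gain of a mixture over the direct sound, in dB
#'
#' `20 * log10(RMS(mixture) / RMS(direct))` over the common support of the
#' two tracks. With a unit-gain echo added to a signal that is decorrelated
#' at the echo lag, the expected gain is `10 * log10(A^2 + 1)`: 3.01 dB for
#' the 0-dB echo and 0.97 dB for the 6-dB echo convention.
#'
#' @param mixture,direct Tracks at the same rate.
#' @return Gain in dB (scalar).
#' @export
rms_gain_db <- function(mixture, direct) {
  stopifnot(track_rate(mixture) == track_rate(direct))
  m <- track_values(mixture)
  d <- track_values(direct)
  n <- min(length(m), length(d))
  m <- m[seq_len(n)]; d <- d[seq_len(n)]
  rms <- function(v) sqrt(mean(v^2))
  if (rms(d) == 0 || rms(m) == 0) stop("silent input", call. = FALSE)
  20 * log10(rms(m) / rms(d))
}

#' Echo-related frequencies
#'
#' The modulation frequencies `(2k - 1) / (2 * delay)` at which a unit-gain
#' echo cancels the stimulus envelope (odd multiples of `1 / (2 * delay)`),
#' listed in ascending order strictly below `f_max`.
#'
#' @param delay_s Echo delay in seconds (> 0).
#' @param f_max Upper frequency bound in Hz (exclusive).
#' @return Numeric vector of frequencies in Hz.
#' @examples
#' echo_related_frequencies(0.125, 10) # 4
#' echo_related_frequencies(0.25, 15)  # 2 6 10 14
#' @export
echo_related_frequencies <- function(delay_s, f_max) {
  stopifnot(delay_s > 0, f_max > 0)
  f0 <- 1 / (2 * delay_s)
  k <- seq_len(max(0, ceiling(f_max / (2 * f0))))
  f <- (2 * k - 1) * f0
  f[f < f_max]
}

#' Locate speech pauses in an envelope
#'
#' Maximal intervals where the envelope stays below a silence threshold for
#' at least `min_pause_s`. The threshold is 5% of the median envelope over
#' voiced frames, which is robust to overall gain.
#'
#' @param env An `envelope_track`.
#' @param min_pause_s Minimum pause duration in seconds (default 0.5, the
#'   criterion used to place variable-delay switch points).
#' @return A tibble with columns `start`, `end`, `duration` (seconds; `end`
#'   exclusive). Zero rows if there is no qualifying pause.
#' @export
segment_pauses <- function(env, min_pause_s = 0.5) {
  stopifnot(inherits(env, "envelope_track"), min_pause_s >= 0)
  v <- env$values
  rate <- env$rate
  thr0 <- 0.05 * stats::median(v)
  voiced <- v > thr0
  thr <- if (any(voiced)) 0.05 * stats::median(v[voiced]) else 0
  silent <- v <= thr
  r <- rle(silent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= max(1, min_pause_s * rate))
  tibble::tibble(
    start = (starts[keep] - 1L) / rate,
    end = ends[keep] / rate,
    duration = r$lengths[keep] / rate
  )
}

# Intervals (s) between consecutive pauses longer than min_pause_s: the
# durations of the speech stretches separating them.
inter_pause_intervals <- function(env, min_pause_s = 0.5) {
  p <- segment_pauses(env, min_pause_s)
  if (nrow(p) < 2L) return(numeric(0))
  p$start[-1] - p$end[-nrow(p)]
}

# Hilbert envelope low-passed below `cutoff`, clipped at zero.
stream_envelope <- function(x, rate, cutoff = 160) {
  pmax(lowpass(Mod(analytic_signal(x)), rate, cutoff, order = 4), 0)
}

#' One-channel noise vocoding of an echoic mixture
#'
#' The direct sound and the echo are noise-vocoded separately and then mixed:
#' each stream's Hilbert envelope (low-passed below 160 Hz, fourth-order
#' Butterworth) modulates an independent Gaussian white-noise carrier
#' low-passed below 4 kHz. The output RMS is matched to the corresponding
#' non-vocoded echoic mixture. Vocoding removes the spectro-temporal fine
#' structure that supports stream segregation while preserving the envelope.
#'
#' @param direct An `audio_track` (rate > 8 kHz).
#' @param spec An [echo_spec()].
#' @param seed Integer seed for the noise carriers.
#' @return An `audio_track` of the same length as `make_echoic(direct, spec)`.
#' @export
vocode_one_channel <- function(direct, spec, seed = 1L) {
  stopifnot(inherits(direct, "audio_track"), inherits(spec, "echo_spec"))
  rate <- track_rate(direct)
  if (rate <= 8000) {
    stop("audio rate must exceed 8 kHz to carry a 4-kHz noise band", call. = FALSE)
  }
  x <- direct$samples
  mixture <- make_echoic(direct, spec)
  n_out <- track_length(mixture)
  direct_comp <- spec$amplitude * c(x, numeric(n_out - length(x)))
  echo_comp <- echo_component(x, spec, rate)
  rms <- function(v) sqrt(mean(v^2))
  vocode_stream <- function(stream) {
    env <- stream_envelope(stream, rate, 160)
    carrier <- lowpass(stats::rnorm(length(stream)), rate, 4000, order = 4)
    env * carrier
  }
  voc <- with_seed(seed, vocode_stream(direct_comp) + vocode_stream(echo_comp))
  target <- rms(track_values(mixture))
  if (target > 0 && rms(voc) > 0) voc <- voc * target / rms(voc)
  audio_track(voc, rate)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Broadband envelope of an audio track
#'
#' Full-wave rectification followed by low-pass filtering below 50 Hz and
#' decimation to the analysis rate; filter undershoot is clipped at zero.
#'
#' @param audio An `audio_track`.
#' @param out_rate Analysis rate in Hz (default 100); must divide the audio
#'   rate.
#' @return An `envelope_track` at `out_rate`.
#' @export
extract_envelope_broadband <- function(audio, out_rate = 100) {
  stopifnot(inherits(audio, "audio_track"))
  rate <- track_rate(audio)
  mid_rate <- 4 * out_rate
  if (rate < mid_rate) mid_rate <- rate
  q1 <- rate / mid_rate
  q2 <- mid_rate / out_rate
  if (abs(q1 - round(q1)) > 1e-9 || abs(q2 - round(q2)) > 1e-9) {
    stop("`out_rate` (and 4x it) must divide the audio rate", call. = FALSE)
  }
  v <- abs(audio$samples)
  # staged decimation keeps the low-pass filters numerically stable
  if (round(q1) > 1L) v <- decimate_by(v, rate, round(q1))
  v <- lowpass(v, mid_rate, min(50, 0.45 * out_rate), order = 4)
  if (round(q2) > 1L) v <- decimate_by(v, mid_rate, round(q2))
  envelope_track(pmax(v, 0), out_rate)
}
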