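#' Audio track
#'
#' A mono waveform with its sampling rate. The waveform is stored as a plain
#' numeric vector; arithmetic on tracks is done through the accessors so the
#' rate is never silently dropped.
#'
#' @param samples Numeric vector, arbitrary pressure units.
#' @param rate Sampling rate in samples/second (> 0).
#' @return An object of class `audio_track`.
#' @examples
#' tone <- audio_track(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' track_duration(tone)
#' @export
audio_track <- function(samples, rate) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) > 0)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("audio samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "audio_track")
}

#' Envelope track
#'
#' A nonnegative slow-modulation time series (speech envelope, stream
#' envelope, or summed model response) with its sampling rate.
#'
#' @param values Nonnegative numeric vector.
#' @param rate Sampling rate in samples/second (> 0).
#' @return An object of class `envelope_track`.
#' @export
envelope_track <- function(values, rate) {
  values <- as.numeric(values)
  stopifnot(length(values) > 0)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("envelope values must be finite", call. = FALSE)
  if (any(values < 0)) stop("envelope values must be nonnegative", call. = FALSE)
  structure(list(values = values, rate = as.numeric(rate)),
            class = "envelope_track")
}

#' Multichannel recording
#'
#' A channels x time array with sampling-rate metadata, the container for
#' real or synthetic MEG-like responses.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling rate in Hz.
#' @param labels Optional channel labels (default `"ch001"`, ...).
#' @param provenance Free-text origin tag (e.g. `"synthetic:streaming"`).
#' @return An object of class `recording`.
#' @export
recording <- function(data, rate, labels = NULL, provenance = "unknown") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording must contain finite values", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data))
  structure(list(data = data, rate = as.numeric(rate),
                 labels = as.character(labels), provenance = provenance),
            class = "recording")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, track_duration(x)))
  invisible(x)
}

#' @export
print.envelope_track <- function(x, ...) {
  cat(sprintf("<envelope_track> %d samples @ %g Hz (%.2f s)\n",
              length(x$values), x$rate, track_duration(x)))
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz [%s]\n",
              nrow(x$data), ncol(x$data), x$rate, x$provenance))
  invisible(x)
}

#' Duration of a track in seconds
#'
#' @param x An `audio_track`, `envelope_track`, or `recording`.
#' @return Duration in seconds.
#' @export
track_duration <- function(x) {
  n <- track_length(x)
  n / track_rate(x)
}

#' Number of samples in a track
#' @param x A track object.
#' @return Integer sample count.
#' @export
track_length <- function(x) {
  if (inherits(x, "recording")) ncol(x$data)
  else if (inherits(x, "audio_track")) length(x$samples)
  else if (inherits(x, "envelope_track")) length(x$values)
  else stop("not a track object", call. = FALSE)
}

#' Sampling rate of a track
#' @param x A track object.
#' @return Rate in Hz.
#' @export
track_rate <- function(x) x$rate

#' Raw signal values of a track
#' @param x A track object.
#' @return Numeric vector (or matrix for recordings).
#' @export
track_values <- function(x) {
  if (inherits(x, "recording")) x$data
  else if (inherits(x, "audio_track")) x$samples
  else x$values
}

#' Convert a track to a tibble
#'
#' @param x A track object.
#' @param ... Unused.
#' @return A tibble with columns `time` and `value` (plus `channel` for
#'   recordings), convenient for ggplot2.
#' @method as_tibble audio_track
#' @export
as_tibble.audio_track <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$samples) - 1) / x$rate, value = x$samples)
}

#' @rdname as_tibble.audio_track
#' @method as_tibble envelope_track
#' @export
as_tibble.envelope_track <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$values) - 1) / x$rate, value = x$values)
}

#' @rdname as_tibble.audio_track
#' @method as_tibble recording
#' @export
as_tibble.recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    channel = rep(x$labels, each = n),
    time = rep((seq_len(n) - 1) / x$rate, times = nrow(x$data)),
    value = as.vector(t(x$data))
  )
}

# ---- internal numeric helpers shared across modules ----------------------

# FFT-based analytic signal; magnitude is the Hilbert envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth low-pass (order `order`, cutoff Hz).
lowpass <- function(x, rate, cutoff, order = 4) {
  stopifnot(cutoff < rate / 2)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Low-pass + pick every q-th sample; integer-factor decimation. Large
# factors are decimated in stages of <= 8 so the anti-alias Butterworth
# stays numerically stable (transfer-function filters misbehave at very
# small normalized cutoffs).
decimate_by <- function(x, rate, q, guard = 0.8) {
  q <- as.integer(q)
  while (q > 1L) {
    g <- q
    if (q > 8L) {
      g <- 8L
      while (g > 1L && q %% g != 0L) g <- g - 1L
      if (g == 1L) g <- q
    }
    x <- lowpass(x, rate, guard * (rate / g) / 2, order = 6)
    x <- x[seq(1L, length(x), by = g)]
    rate <- rate / g
    q <- q %/% g
  }
  x
}

#' Resample a track to a lower rate
#'
#' Integer-factor decimation with staged anti-alias filtering; envelope
#' tracks are clipped at zero after filtering.
#'
#' @param x An `audio_track` or `envelope_track`.
#' @param to_rate Target rate in Hz; must divide the current rate.
#' @return A track of the same class at `to_rate`.
#' @export
resample_track <- function(x, to_rate) {
  r <- track_rate(x)
  if (r == to_rate) return(x)
  q <- r / to_rate
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    stop("resample_track only supports integer decimation factors", call. = FALSE)
  }
  v <- decimate_by(track_values(x), r, round(q))
  if (inherits(x, "envelope_track")) envelope_track(pmax(v, 0), to_rate)
  else audio_track(v, to_rate)
}
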