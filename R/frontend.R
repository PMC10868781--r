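#' Auditory spectrogram container
#'
#' Nonnegative channel x frame array of narrowband envelopes with its frame
#' rate and ascending center frequencies: the model of subcortical auditory
#' responses that feeds the adaptation simulator and the modulation
#' spectrum.
#'
#' @param values Nonnegative matrix, channels x frames.
#' @param frame_rate Frame rate in Hz (200 in the standard pipeline).
#' @param center_frequencies Ascending channel center frequencies, Hz.
#' @return An `aud_spectrogram`.
#' @export
aud_spectrogram <- function(values, frame_rate = 200, center_frequencies = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("spectrogram values must be nonnegative", call. = FALSE)
  if (is.null(center_frequencies)) {
    center_frequencies <- seq_len(nrow(values))
  }
  stopifnot(length(center_frequencies) == nrow(values),
            !is.unsorted(center_frequencies))
  structure(list(values = values, frame_rate = frame_rate,
                 center_frequencies = as.numeric(center_frequencies)),
            class = "aud_spectrogram")
}

#' @export
print.aud_spectrogram <- function(x, ...) {
  cat(sprintf("<aud_spectrogram> %d channels x %d frames @ %g Hz (%g-%g Hz)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              min(x$center_frequencies), max(x$center_frequencies)))
  invisible(x)
}

# Log-spaced center frequencies, 180 Hz - 4 kHz by default.
frontend_cf <- function(n_channels = 128, f_lo = 180, f_hi = 4000) {
  exp(seq(log(f_lo), log(f_hi), length.out = n_channels))
}

#' Auditory spectrogram of an audio track
#'
#' A 128-band filterbank front end standing in for a cochlear model: bands
#' are log-spaced between 180 Hz and 4 kHz with raised-cosine transitions
#' in log-frequency, applied in the FFT domain; the per-band envelope is
#' the magnitude of the band-limited analytic signal, averaged into frames
#' at 200 Hz. Downstream analyses only rely on "128 narrowband envelopes at
#' 200 Hz", not on any particular cochlear nonlinearity.
#'
#' @param audio An `audio_track` with rate >= 8 kHz.
#' @param n_channels Number of frequency channels (default 128).
#' @param frame_rate Output frame rate, Hz; must divide the audio rate.
#' @return An `aud_spectrogram`.
#' @export
auditory_spectrogram <- function(audio, n_channels = 128, frame_rate = 200) {
  stopifnot(inherits(audio, "audio_track"))
  rate <- track_rate(audio)
  if (rate < 8000) stop("audio rate must be at least 8 kHz", call. = FALSE)
  q <- rate / frame_rate
  if (abs(q - round(q)) > 1e-9) stop("frame rate must divide the audio rate", call. = FALSE)
  q <- as.integer(round(q))
  x <- audio$samples
  n <- length(x)
  n_pad <- q * ((n + q - 1L) %/% q)               # whole frames
  x <- c(x, numeric(n_pad - n))
  X <- stats::fft(x)
  f <- (seq_len(n_pad) - 1) * rate / n_pad
  cf <- frontend_cf(n_channels)
  lcf <- log(cf)
  half_bw <- (lcf[2] - lcf[1])                     # band half-width in log-f
  n_frames <- n_pad %/% q
  vals <- matrix(0, n_channels, n_frames)
  pos <- f > 0 & f <= rate / 2
  lf <- rep(NA_real_, n_pad)
  lf[pos] <- log(f[pos])
  for (ch in seq_len(n_channels)) {
    d <- abs(lf - lcf[ch]) / half_bw
    mask <- numeric(n_pad)
    in_band <- !is.na(d) & d < 1
    mask[in_band] <- 0.5 * (1 + cos(pi * d[in_band]))
    band <- stats::fft(X * mask, inverse = TRUE) / n_pad  # analytic band signal
    env <- Mod(band) * 2
    vals[ch, ] <- colMeans(matrix(env, nrow = q))
  }
  aud_spectrogram(vals, frame_rate, cf)
}

#' Synthetic spectrogram from an envelope
#'
#' Builds an auditory-spectrogram stand-in whose channels all follow one
#' temporal envelope, scaled by a smooth spectral profile. Useful for
#' simulations where only the temporal structure matters: an echoic
#' spectrogram constructed from an echoic-mixture envelope preserves exact
#' per-channel cancellation at the echo-related frequencies.
#'
#' @param env An `envelope_track` at the spectrogram frame rate.
#' @param n_channels Number of channels.
#' @return An `aud_spectrogram` at `track_rate(env)`.
#' @export
envelope_to_spectrogram <- function(env, n_channels = 128) {
  stopifnot(inherits(env, "envelope_track"))
  cf <- frontend_cf(n_channels)
  # broad speech-like spectral profile peaking near 500 Hz
  gains <- exp(-((log(cf) - log(500))^2) / (2 * 0.9^2))
  aud_spectrogram(outer(gains, env$values), track_rate(env), cf)
}

#' Modulation spectrum
#'
#' Each narrowband envelope of the auditory spectrogram is transformed with
#' a single full-length DFT; the modulation spectrum sums the DFT amplitude
#' spectra over channels and is normalized by the maximum of the reference
#' signal's modulation spectrum (the anechoic speech in the study's
#' figures). A unit-gain echo produces notches at the echo-related
#' frequencies; halving the direct sound (the 6-dB echo) attenuates but
#' does not cancel them.
#'
#' @param audio An `audio_track` or `aud_spectrogram`.
#' @param reference Reference for normalization (same types); default the
#'   input itself.
#' @param f_max Highest modulation frequency returned, Hz.
#' @return A tibble of class `modulation_spectrum` with columns `frequency`
#'   and `amplitude`; attribute `"reference_max"` holds the normalizer.
#' @export
modulation_spectrum <- function(audio, reference = NULL, f_max = 32) {
  spec <- if (inherits(audio, "aud_spectrogram")) audio else auditory_spectrogram(audio)
  raw <- modspec_raw(spec, f_max)
  ref_max <- if (is.null(reference)) max(raw$amplitude) else {
    rspec <- if (inherits(reference, "aud_spectrogram")) reference
             else auditory_spectrogram(reference)
    rr <- modspec_raw(rspec, f_max)
    max(rr$amplitude)
  }
  if (ref_max <= 0) stop("silent reference", call. = FALSE)
  out <- dplyr::mutate(raw, amplitude = amplitude / ref_max)
  attr(out, "reference_max") <- ref_max
  class(out) <- c("modulation_spectrum", class(out))
  out
}

modspec_raw <- function(spec, f_max) {
  v <- spec$values
  n <- ncol(v)
  amp <- rowSums(Mod(stats::mvfft(t(v))))          # sum over channels
  f <- (seq_len(n) - 1) * spec$frame_rate / n
  keep <- f > 0 & f <= f_max
  tibble::tibble(frequency = f[keep], amplitude = amp[keep])
}
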