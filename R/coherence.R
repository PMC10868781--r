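#' Per-epoch DFT phases of a stimulus/response pair
#'
#' Both signals are segmented into non-overlapping epochs (default 2 s,
#' rectangular window), each epoch is transformed with the DFT, and the
#' phase angles are extracted on the common frequency grid. The trailing
#' partial epoch is discarded.
#'
#' @param stim An `envelope_track` or numeric vector (stimulus envelope).
#' @param resp A numeric vector or `envelope_track`, same rate and length.
#' @param rate Sampling rate in Hz (taken from `stim` when it is a track).
#' @param epoch_len_s Epoch length in seconds; `epoch_len_s * rate` must be
#'   a whole number.
#' @return An `epoch_phases` list: `frequency` (Hz, DFT bins up to Nyquist),
#'   `alpha` and `beta` (bins x epochs phase matrices for stimulus and
#'   response), `theta = alpha - beta` wrapped to (-pi, pi], and `n_epochs`.
#' @export
epoch_phases <- function(stim, resp, rate = NULL, epoch_len_s = 2) {
  sv <- if (is.numeric(stim)) stim else track_values(stim)
  rv <- if (is.numeric(resp)) resp else track_values(resp)
  if (is.null(rate)) {
    rate <- if (is.numeric(stim)) stop("`rate` required for numeric input", call. = FALSE)
            else track_rate(stim)
  }
  if (!is.numeric(resp) && track_rate(resp) != rate) {
    stop("stimulus and response rates differ", call. = FALSE)
  }
  n <- min(length(sv), length(rv))
  L <- epoch_len_s * rate
  if (abs(L - round(L)) > 1e-9) stop("epoch length must be a whole number of samples", call. = FALSE)
  L <- as.integer(round(L))
  if (n < L) stop("signal shorter than one epoch", call. = FALSE)
  T <- n %/% L
  smat <- matrix(sv[seq_len(T * L)], nrow = L)
  rmat <- matrix(rv[seq_len(T * L)], nrow = L)
  nb <- L %/% 2 + 1L
  alpha <- Arg(stats::mvfft(smat))[seq_len(nb), , drop = FALSE]
  beta <- Arg(stats::mvfft(rmat))[seq_len(nb), , drop = FALSE]
  theta <- wrap_pi(alpha - beta)
  structure(list(frequency = (seq_len(nb) - 1) * rate / L,
                 alpha = alpha, beta = beta, theta = theta, n_epochs = T),
            class = "epoch_phases")
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Phase coherence from epoch phases
#'
#' The phase coherence at frequency `f` is
#' `C(f) = [(sum_t cos(theta_ft))^2 + (sum_t sin(theta_ft))^2] / T^2`,
#' the squared length of the mean resultant of the per-epoch
#' stimulus-response phase differences: 1 when the phase lag is constant
#' across epochs, near 0 when it is random. For independent signals the
#' expected value is exactly `1 / T` over `T` epochs. `type = "resultant"`
#' returns the (unsquared) mean resultant length `sqrt(C)` instead, whose
#' chance expectation is approximately `0.886 / sqrt(T)`.
#'
#' @param phases An `epoch_phases` object.
#' @param type `"squared"` (the definition above, default) or
#'   `"resultant"`.
#' @return Numeric vector `C(f)` over the epoch DFT bins, in \[0, 1\].
#' @export
coherence <- function(phases, type = c("squared", "resultant")) {
  type <- match.arg(type)
  stopifnot(inherits(phases, "epoch_phases"))
  if (phases$n_epochs < 2L) stop("need at least 2 epochs", call. = FALSE)
  r <- Mod(rowMeans(exp(1i * phases$theta)))
  if (type == "squared") r^2 else r
}

#' Phase coherence spectrum between a stimulus and a recording
#'
#' Computes [coherence()] per channel and returns a tidy spectrum.
#'
#' @param stim Stimulus `envelope_track`.
#' @param resp A `recording`, `envelope_track`, or numeric vector at the
#'   same rate.
#' @param epoch_len_s Epoch length in seconds (default 2, i.e. 0.5-Hz bins).
#' @param type Coherence form, see [coherence()].
#' @return A tibble of class `coherence_spectrum` with columns `frequency`,
#'   `channel`, `coherence`; attribute `n_epochs` records `T`.
#' @export
phase_coherence <- function(stim, resp, epoch_len_s = 2,
                            type = c("squared", "resultant")) {
  type <- match.arg(type)
  rate <- track_rate(stim)
  chans <- if (inherits(resp, "recording")) {
    stats::setNames(lapply(seq_len(nrow(resp$data)), function(i) resp$data[i, ]),
                    resp$labels)
  } else list(ch001 = if (is.numeric(resp)) resp else track_values(resp))
  out <- purrr::map_dfr(names(chans), function(nm) {
    ph <- epoch_phases(stim, chans[[nm]], rate = rate, epoch_len_s = epoch_len_s)
    tibble::tibble(frequency = ph$frequency, channel = nm,
                   coherence = coherence(ph, type = type))
  })
  ph1 <- epoch_phases(stim, chans[[1]], rate = rate, epoch_len_s = epoch_len_s)
  attr(out, "n_epochs") <- ph1$n_epochs
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("coherence_spectrum", class(out))
  out
}

#' Shuffle-based chance level for the phase coherence spectrum
#'
#' Stimulus epochs are randomly permuted (the response epoch order is kept)
#' so the envelope and response are randomly paired, and the coherence is
#' recomputed per shuffle. Observed and null coherence are averaged across
#' channels before comparison, and the one-sided significance level is
#' `(M + 1) / (n_shuffles + 1)` where `M` counts null values at or above the
#' observed one. Permutations are drawn uniformly (the identity is not
#' excluded).
#'
#' @param stim Stimulus `envelope_track`.
#' @param resp A `recording` (or vector / `envelope_track`).
#' @param n_shuffles Number of random pairings (the study used 5,000).
#' @param seed Integer seed.
#' @param epoch_len_s Epoch length in seconds.
#' @param type Coherence form, see [coherence()].
#' @param average `"channels"` (default, the group procedure) averages the
#'   coherence across channels before the null comparison; `"none"` returns
#'   per-channel p-values.
#' @return A tibble of class `coherence_null` with columns `frequency`,
#'   (`channel`,) `observed`, `chance`, `p`, `p_fdr`; the null draws are in
#'   `attr(, "null")` (frequencies x shuffles, channel-averaged).
#' @export
chance_null <- function(stim, resp, n_shuffles = 5000, seed = 1L,
                        epoch_len_s = 2, average = c("channels", "none"),
                        type = c("squared", "resultant")) {
  average <- match.arg(average)
  type <- match.arg(type)
  stopifnot(n_shuffles >= 1)
  rate <- track_rate(stim)
  mats <- if (inherits(resp, "recording")) resp$data
          else matrix(if (is.numeric(resp)) resp else track_values(resp), nrow = 1)
  phs <- lapply(seq_len(nrow(mats)), function(i) {
    epoch_phases(stim, mats[i, ], rate = rate, epoch_len_s = epoch_len_s)
  })
  T <- phs[[1]]$n_epochs
  freq <- phs[[1]]$frequency
  ea <- exp(1i * phs[[1]]$alpha)                  # stimulus is shared
  ebs <- lapply(phs, function(p) Conj(exp(1i * p$beta)))
  cfun <- function(r) if (type == "squared") r^2 else r
  obs <- vapply(ebs, function(eb) cfun(Mod(rowMeans(ea * eb))), numeric(length(freq)))
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(T)
      eap <- ea[, perm, drop = FALSE]
      nm <- vapply(ebs, function(eb) cfun(Mod(rowMeans(eap * eb))), numeric(length(freq)))
      if (average == "channels") rowMeans(nm) else nm
    }, if (average == "channels") numeric(length(freq))
       else matrix(0, length(freq), length(ebs)))
  })
  if (average == "channels") {
    obs_avg <- rowMeans(obs)
    M <- rowSums(null >= obs_avg)
    p <- (M + 1) / (n_shuffles + 1)
    out <- tibble::tibble(frequency = freq, observed = obs_avg,
                          chance = rowMeans(null), p = p,
                          p_fdr = fdr_adjust(p))
    attr(out, "null") <- null
  } else {
    # null: freq x channels x shuffles
    pmat <- sapply(seq_len(ncol(obs)), function(ch) {
      (rowSums(null[, ch, ] >= obs[, ch]) + 1) / (n_shuffles + 1)
    })
    out <- tidyr::expand_grid(channel = seq_len(ncol(obs)), frequency = freq)
    out <- dplyr::mutate(out,
      observed = as.vector(obs[cbind(match(frequency, freq), channel)]),
      chance = as.vector(apply(null, c(1, 2), mean)[cbind(match(frequency, freq), channel)]),
      p = as.vector(pmat[cbind(match(frequency, freq), channel)]))
    out$p_fdr <- fdr_adjust(out$p)
  }
  attr(out, "n_epochs") <- T
  class(out) <- c("coherence_null", class(out))
  out
}
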