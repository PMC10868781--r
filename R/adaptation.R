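#' Adaptation parameters
#'
#' The three parameters of the synaptic-depression + gain-control model:
#' the firing threshold `V` (0 < V < 1, on the normalized spectrogram
#' scale) and the widths of the Hann windows that accumulate past input
#' (depression, `tau_sd`) and past output (gain control, `tau_gc`), in
#' milliseconds.
#'
#' @param V Firing threshold in (0, 1).
#' @param tau_sd Depression window width, ms (>= 0).
#' @param tau_gc Gain-control window width, ms (>= 0).
#' @return An `adaptation_params` list.
#' @export
adaptation_params <- function(V, tau_sd, tau_gc) {
  stopifnot(V > 0, V < 1, tau_sd >= 0, tau_gc >= 0)
  structure(list(V = V, tau_sd = tau_sd, tau_gc = tau_gc),
            class = "adaptation_params")
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat(sprintf("<adaptation_params> V = %g, tau_sd = %g ms, tau_gc = %g ms\n",
              x$V, x$tau_sd, x$tau_gc))
  invisible(x)
}

# Hann weights without zero endpoints (hanning convention), length = whole
# frames; width 0 gives an empty window (the corresponding sum vanishes).
hann_weights <- function(width_ms, frame_rate = 200) {
  L <- width_ms * frame_rate / 1000
  if (abs(L - round(L)) > 1e-9) {
    stop("window width must be a whole number of frames", call. = FALSE)
  }
  L <- as.integer(round(L))
  if (L == 0L) return(numeric(0))
  k <- seq_len(L)
  0.5 * (1 - cos(2 * pi * k / (L + 1)))
}

#' Simulate synaptic depression and gain control on a spectrogram
#'
#' Per frequency channel, a causal recursion subtracts a depression term
#' driven by the recent input (Hann window of width `tau_sd`, including the
#' current frame), thresholds at zero, and divides by a gain-control term
#' driven by the strictly past output (Hann window of width `tau_gc`):
#' \deqn{r(t,c) = \max(s(t,c) - D(t,c), 0)\, G(t,c)}
#' \deqn{D(t,c) = V (1 + \sum_{n=0} s(t-n,c) W(n))}
#' \deqn{G(t,c) = 1 / (1 + \sum_{n\ge 1} r(t-n,c) W(n))}
#' The gain-control sum starts at the first past frame so the recursion is
#' well defined. The simulated envelope-tracking response is the model
#' output summed across channels.
#'
#' By default the spectrogram is normalized so its 95th percentile equals 1
#' before adaptation, making the threshold `V` scale-free.
#'
#' @param spec An `aud_spectrogram`.
#' @param p An [adaptation_params()].
#' @param normalize Normalize the input scale first (default TRUE).
#' @param keep_intermediates Also return the `D` and `G` fields.
#' @param engine `"compiled"` (default) or `"reference"`, a plain-R
#'   double-loop used as an independent oracle; both produce bit-identical
#'   output.
#' @return An `adapted_response`: list with `r` (channels x frames,
#'   nonnegative), `envelope` (summed response as an `envelope_track` at the
#'   frame rate), `params`, and optionally `D`, `G`.
#' @export
adapt <- function(spec, p, normalize = TRUE, keep_intermediates = FALSE,
                  engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "aud_spectrogram"), inherits(p, "adaptation_params"))
  s <- spec$values
  if (any(s < 0)) stop("spectrogram must be nonnegative", call. = FALSE)
  if (normalize) {
    q <- stats::quantile(s, 0.95, names = FALSE)
    if (q > 0) s <- s / q
  }
  w_sd <- hann_weights(p$tau_sd, spec$frame_rate)
  w_gc <- hann_weights(p$tau_gc, spec$frame_rate)
  st <- t(s)                                      # frames x channels
  r <- if (engine == "compiled") adapt_core(st, p$V, w_sd, w_gc)
       else adapt_reference(st, p$V, w_sd, w_gc)
  out <- list(r = t(r),
              envelope = envelope_track(pmax(rowSums(r), 0), spec$frame_rate),
              params = p)
  if (keep_intermediates) {
    Tn <- nrow(r)
    acc <- function(x, w) {          # sum_n x(t-n) w[n], n >= 1
      if (!length(w)) return(matrix(0, Tn, ncol(r)))
      y <- stats::filter(rbind(0, x[-Tn, , drop = FALSE]), w,
                         method = "convolution", sides = 1)
      y[is.na(y)] <- 0
      y
    }
    dep0 <- if (length(w_sd)) {
      y <- stats::filter(st, w_sd, method = "convolution", sides = 1)
      y[is.na(y)] <- 0
      # sides-1 filter of length L uses x(t-.)..x(t-L+1) with w[1] on x(t)
      y
    } else matrix(0, Tn, ncol(r))
    out$D <- t(p$V * (1 + dep0))
    out$G <- t(1 / (1 + acc(r, w_gc)))
  }
  class(out) <- "adapted_response"
  out
}

# Plain-R oracle with the same summation order as the compiled core.
adapt_reference <- function(st, V, w_sd, w_gc) {
  Tn <- nrow(st); Cn <- ncol(st)
  nsd <- length(w_sd); ngc <- length(w_gc)
  r <- matrix(0, Tn, Cn)
  for (c in seq_len(Cn)) {
    for (t in seq_len(Tn)) {
      dep <- 0
      n <- 0L
      while (n < nsd) {
        tt <- t - n
        if (tt < 1L) break
        dep <- dep + st[tt, c] * w_sd[n + 1L]
        n <- n + 1L
      }
      D <- V * (1 + dep)
      g <- 0
      n <- 1L
      while (n <= ngc) {
        tt <- t - n
        if (tt < 1L) break
        g <- g + r[tt, c] * w_gc[n]
        n <- n + 1L
      }
      G <- 1 / (1 + g)
      x <- st[t, c] - D
      r[t, c] <- (if (x > 0) x else 0) * G
    }
  }
  r
}

#' @export
print.adapted_response <- function(x, ...) {
  cat(sprintf("<adapted_response> %d channels x %d frames (V = %g)\n",
              nrow(x$r), ncol(x$r), x$params$V))
  invisible(x)
}

#' Grid of adaptation parameters
#'
#' The simulation-mode grid of the model: `V` from 0.05 to 0.95 in steps of
#' 0.05 and both window widths from 50 to 450 ms in steps of 50 ms.
#'
#' @param V,tau_sd,tau_gc Candidate values.
#' @return A tibble with one row per parameter combination.
#' @export
adaptation_grid <- function(V = seq(0.05, 0.95, by = 0.05),
                            tau_sd = seq(50, 450, by = 50),
                            tau_gc = seq(50, 450, by = 50)) {
  g <- tidyr::expand_grid(V = V, tau_sd = tau_sd, tau_gc = tau_gc)
  if (nrow(g) == 0L) stop("empty grid", call. = FALSE)
  g
}

#' Fit adaptation parameters by exhaustive grid search
#'
#' Maximizes the Pearson correlation between the summed adapted response
#' (resampled to the envelope rate) and the direct-sound envelope, averaged
#' over the supplied sessions (the study averaged over its 4 echoic
#' conditions). Ties are broken lexicographically toward the smallest
#' `(V, tau_sd, tau_gc)`.
#'
#' @param sessions List of sessions, each a list with `spec` (echoic
#'   `aud_spectrogram`) and `direct` (direct-sound `envelope_track`).
#' @param grid A tibble from [adaptation_grid()].
#' @return An [adaptation_params()] with attribute `"scores"`, the grid
#'   tibble augmented with the mean correlation per combination.
#' @export
fit_adaptation_params <- function(sessions, grid = adaptation_grid()) {
  stopifnot(length(sessions) >= 1, nrow(grid) >= 1)
  score_one <- function(V, tau_sd, tau_gc) {
    p <- adaptation_params(V, tau_sd, tau_gc)
    mean(vapply(sessions, function(ss) {
      ar <- adapt(ss$spec, p)
      env <- resample_track(ar$envelope, track_rate(ss$direct))
      nn <- min(track_length(env), track_length(ss$direct))
      stats::cor(env$values[seq_len(nn)], ss$direct$values[seq_len(nn)])
    }, numeric(1)))
  }
  scores <- purrr::pmap_dbl(grid, score_one)
  ord <- order(-scores, grid$V, grid$tau_sd, grid$tau_gc)
  best <- grid[ord[1], ]
  out <- adaptation_params(best$V, best$tau_sd, best$tau_gc)
  attr(out, "scores") <- dplyr::mutate(grid, score = scores)
  out
}

#' Coherence spectrum of the adapted response
#'
#' Runs the adaptation model on a session's echoic spectrogram and computes
#' the phase coherence between the summed adapted response and the
#' direct-sound envelope at the analysis rate.
#'
#' @param session List with `spec` (echoic `aud_spectrogram`) and `direct`
#'   (`envelope_track`).
#' @param p An [adaptation_params()].
#' @param epoch_len_s Epoch length in seconds.
#' @param type Coherence form, see [coherence()].
#' @return A `coherence_spectrum` tibble.
#' @export
adapted_coherence_spectrum <- function(session, p, epoch_len_s = 2,
                                       type = c("squared", "resultant")) {
  type <- match.arg(type)
  ar <- adapt(session$spec, p)
  env <- resample_track(ar$envelope, track_rate(session$direct))
  nn <- min(track_length(env), track_length(session$direct))
  phase_coherence(
    envelope_track(session$direct$values[seq_len(nn)], track_rate(session$direct)),
    env$values[seq_len(nn)], epoch_len_s = epoch_len_s, type = type)
}
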