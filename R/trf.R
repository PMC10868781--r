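#' Lag-expanded TRF design from one or more sessions
#'
#' Builds the lagged predictor block for one of the three encoding models:
#' `mixture` uses the echoic-mixture envelope, `streaming` uses the direct
#' and echo envelopes with separate kernels, and `idealized` uses the direct
#' envelope only. Lags run from 1 to `n_lags` samples (10 ms to 1 s at the
#' 100 Hz analysis rate with the default `n_lags = 100`). Sessions (e.g.,
#' the two echo-delay conditions, which must be pooled to make the
#' streaming model identifiable) are stacked in time; rows whose lag window
#' would cross a session boundary are dropped.
#'
#' @param sessions A `synth_session`, or a list of them (or of lists with
#'   elements `streams` -- named envelope tracks or numeric vectors -- and
#'   `response`, a `recording` or channels x time matrix).
#' @param kind `"mixture"`, `"streaming"`, or `"idealized"`.
#' @param n_lags Number of lags `D` (default 100).
#' @return A `trf_design`: list with `X` (rows x `n_lags * n_streams`), `Y`
#'   (rows x channels), `kind`, `streams`, `n_lags`, `session` (row labels)
#'   and `diag`, a list with the minimum-to-maximum singular-value ratio
#'   and condition number of the centered design. A near-zero ratio with a
#'   single fixed-delay streaming session triggers a warning: the direct
#'   and echo streams are then identical up to a shift.
#' @export
build_design <- function(sessions, kind = c("mixture", "streaming", "idealized"),
                         n_lags = 100) {
  kind <- match.arg(kind)
  sessions <- as_trf_sessions(sessions)
  streams <- switch(kind,
    mixture = "mixture",
    streaming = c("direct", "echo"),
    idealized = "direct")
  Xs <- list(); Ys <- list(); ids <- list()
  for (i in seq_along(sessions)) {
    ss <- sessions[[i]]
    miss <- setdiff(streams, names(ss$streams))
    if (length(miss)) {
      stop(sprintf("session %d lacks stream(s): %s", i, paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    resp <- ss$response
    n <- ncol(resp)
    sv <- lapply(ss$streams[streams], function(s) {
      v <- if (is.numeric(s)) s else track_values(s)
      stopifnot(length(v) >= n)
      v[seq_len(n)]
    })
    if (n <= n_lags) stop("session shorter than the lag window", call. = FALSE)
    Xi <- do.call(cbind, lapply(sv, function(v) stats::embed(v, n_lags + 1)[, -1, drop = FALSE]))
    Xs[[i]] <- Xi
    Ys[[i]] <- t(resp[, (n_lags + 1):n, drop = FALSE])
    ids[[i]] <- rep(i, nrow(Xi))
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  Gc <- stats::cov(X)
  ev <- eigen(Gc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ratio <- sqrt(ev[length(ev)] / ev[1])
  diag <- list(sv_ratio = ratio, condition = 1 / max(ratio, .Machine$double.eps))
  if (kind == "streaming" && ratio < 1e-7) {
    warning(paste("streaming design is rank-deficient (direct and echo streams",
                  "identical up to a shift); pool conditions with different",
                  "echo delays"), call. = FALSE)
  }
  structure(list(X = X, Y = Y, kind = kind, streams = streams,
                 n_lags = n_lags, session = unlist(ids), diag = diag),
            class = "trf_design")
}

as_trf_sessions <- function(sessions) {
  one <- function(s) {
    if (inherits(s, "synth_session")) {
      list(streams = s$streams, response = s$recording$data,
           rate = s$recording$rate)
    } else {
      resp <- if (inherits(s$response, "recording")) s$response$data else as.matrix(s$response)
      list(streams = s$streams, response = resp, rate = s$rate)
    }
  }
  if (inherits(sessions, "synth_session") ||
      (!is.null(names(sessions)) && "streams" %in% names(sessions))) {
    sessions <- list(sessions)
  }
  lapply(sessions, one)
}

#' @export
print.trf_design <- function(x, ...) {
  cat(sprintf("<trf_design> %s: %d rows x %d cols, %d channel(s), sv ratio %.2e\n",
              x$kind, nrow(x$X), ncol(x$X), ncol(x$Y), x$diag$sv_ratio))
  invisible(x)
}

#' Fit a TRF by ridge regression (closed form)
#'
#' Per response channel, kernels minimize `||y - X w||^2 + lambda ||w||^2`;
#' the intercept is handled by mean-centering the predictors and response.
#'
#' @param design A `trf_design`.
#' @param lambda Ridge strength (>= 0).
#' @return An `echo_trf`: per-channel kernels (array lags x streams x
#'   channels), `lambda`, `kind`, residual variance per channel, and the
#'   centering means.
#' @export
fit_ridge <- function(design, lambda) {
  stopifnot(inherits(design, "trf_design"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  X <- design$X; Y <- design$Y
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
  G <- crossprod(Xc)
  W <- solve(G + diag(lambda, ncol(X)), crossprod(Xc, Yc))
  res <- Yc - Xc %*% W
  new_echo_trf(W, design, lambda,
               mu_x = mu_x, mu_y = mu_y,
               sigma2 = colMeans(res^2))
}

new_echo_trf <- function(W, design, lambda, mu_x, mu_y, sigma2 = NULL) {
  D <- design$n_lags
  ns <- length(design$streams)
  kern <- array(W, dim = c(D, ns, ncol(W)),
                dimnames = list(NULL, design$streams, colnames(W)))
  structure(list(kernels = kern, W = W, lambda = lambda, kind = design$kind,
                 streams = design$streams, n_lags = D,
                 mu_x = mu_x, mu_y = mu_y, sigma2 = sigma2),
            class = "echo_trf")
}

#' @export
print.echo_trf <- function(x, ...) {
  cat(sprintf("<echo_trf> %s model: %d lags x %d stream(s) x %d channel(s), lambda = %.3g\n",
              x$kind, x$n_lags, length(x$streams), dim(x$kernels)[3], x$lambda))
  invisible(x)
}

#' Predict responses from a fitted TRF
#'
#' @param object An `echo_trf`.
#' @param design A `trf_design` with the same predictor layout.
#' @param ... Unused.
#' @return Matrix of predictions (rows x channels).
#' @export
predict.echo_trf <- function(object, design, ...) {
  Xc <- sweep(design$X, 2, object$mu_x)
  sweep(Xc %*% object$W, 2, object$mu_y, `+`)
}

# ---- sufficient statistics for fast fold-wise ridge ----------------------

fold_stats <- function(design, n_folds) {
  X <- design$X; Y <- design$Y
  n <- nrow(X)
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  lapply(seq_len(n_folds), function(f) {
    idx <- (bounds[f] + 1):bounds[f + 1]
    Xf <- X[idx, , drop = FALSE]; Yf <- Y[idx, , drop = FALSE]
    list(n = length(idx), Sx = colSums(Xf), Sy = colSums(Yf),
         G = crossprod(Xf), B = crossprod(Xf, Yf), Syy = colSums(Yf^2),
         idx = idx)
  })
}

combine_stats <- function(stats_list) {
  Reduce(function(a, b) list(
    n = a$n + b$n, Sx = a$Sx + b$Sx, Sy = a$Sy + b$Sy,
    G = a$G + b$G, B = a$B + b$B, Syy = a$Syy + b$Syy
  ), stats_list)
}

ridge_from_stats <- function(tr, lambda) {
  mu_x <- tr$Sx / tr$n; mu_y <- tr$Sy / tr$n
  Gc <- tr$G - tr$n * tcrossprod(mu_x)
  Bc <- tr$B - tr$n * outer(mu_x, mu_y)
  W <- solve(Gc + diag(lambda, length(mu_x)), Bc)
  a <- mu_y - drop(crossprod(W, mu_x))
  list(W = W, a = a, mu_x = mu_x, mu_y = mu_y)
}

# Per-channel correlation between predictions and held-out responses,
# computed from the validation fold's sufficient statistics.
power_from_stats <- function(fit, va) {
  W <- fit$W; a <- fit$a
  n <- va$n
  WtSx <- drop(crossprod(W, va$Sx))
  sum_yy_hat <- colSums(W * (va$G %*% W)) + 2 * a * WtSx + n * a^2
  sum_y_hat <- WtSx + n * a
  sum_xy <- colSums(W * va$B) + a * va$Sy
  num <- sum_xy - sum_y_hat * va$Sy / n
  den2_hat <- sum_yy_hat - sum_y_hat^2 / n
  den2_y <- va$Syy - va$Sy^2 / n
  den <- sqrt(pmax(den2_hat, 0) * pmax(den2_y, 0))
  r <- ifelse(den > 1e-12 * n, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Cross-validated TRF predictive power
#'
#' The response is divided into 10 contiguous folds; for each fold the TRF
#' is fit on the other nine and the per-channel Pearson correlation between
#' prediction and held-out response (the predictive power) is recorded. The
#' ridge strength is selected per fold by nested cross-validation on the
#' training folds only, from a grid of `10^(0:6)` times the mean predictor
#' column variance (which makes the selection invariant to predictor
#' scaling).
#'
#' @param design A `trf_design`.
#' @param lambda_grid Optional vector of candidate ridge strengths.
#' @param n_folds Number of outer folds (default 10).
#' @param inner_folds Contiguous groups used for the nested selection.
#' @return A `trf_cv`: list with `folds` (tibble fold x channel power and
#'   selected lambda), `power` (grand mean), `by_channel`, `lambda`
#'   (per-fold), and `model`, the final fit on all data at the median
#'   selected lambda.
#' @export
cross_validate <- function(design, lambda_grid = NULL, n_folds = 10,
                           inner_folds = 3) {
  stopifnot(inherits(design, "trf_design"))
  if (nrow(design$X) < n_folds * design$n_lags) {
    stop("session too short for cross-validation", call. = FALSE)
  }
  fs <- fold_stats(design, n_folds)
  if (is.null(lambda_grid)) {
    tot <- combine_stats(fs)
    mean_var <- mean(diag(tot$G) / tot$n - (tot$Sx / tot$n)^2)
    lambda_grid <- 10^(0:6) * mean_var
  }
  sel <- numeric(n_folds)
  fold_rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_ids <- setdiff(seq_len(n_folds), f)
    if (length(lambda_grid) > 1L) {
      groups <- split(train_ids, cut(seq_along(train_ids), inner_folds, labels = FALSE))
      score <- vapply(lambda_grid, function(lam) {
        mean(vapply(groups, function(g) {
          tr <- combine_stats(fs[setdiff(train_ids, g)])
          va <- combine_stats(fs[g])
          mean(power_from_stats(ridge_from_stats(tr, lam), va))
        }, numeric(1)))
      }, numeric(1))
      lam <- lambda_grid[which.max(score)]
    } else lam <- lambda_grid
    sel[f] <- lam
    tr <- combine_stats(fs[train_ids])
    fit <- ridge_from_stats(tr, lam)
    r <- power_from_stats(fit, fs[[f]])
    fold_rows[[f]] <- tibble::tibble(fold = f, lambda = lam,
                                     channel = seq_along(r), power = r)
  }
  folds <- dplyr::bind_rows(fold_rows)
  tot <- combine_stats(fs)
  lam_final <- stats::median(sel)
  fit_all <- ridge_from_stats(tot, lam_final)
  model <- new_echo_trf(fit_all$W, design, lam_final,
                        mu_x = fit_all$mu_x, mu_y = fit_all$mu_y)
  structure(list(folds = folds,
                 power = mean(folds$power),
                 by_channel = dplyr::summarise(
                   dplyr::group_by(folds, channel),
                   power = mean(power), .groups = "drop"),
                 lambda = sel, kind = design$kind, model = model),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %s model: mean predictive power %.4f over %d folds x %d channels\n",
              x$kind, x$power, max(x$folds$fold), max(x$folds$channel)))
  invisible(x)
}

#' Compare the three TRF encoding models on the same sessions
#'
#' Convenience wrapper running [build_design()] + [cross_validate()] for
#' the mixture, streaming and idealized models.
#'
#' @param sessions As in [build_design()].
#' @param kinds Models to compare.
#' @param ... Passed to [cross_validate()].
#' @param n_lags Number of lags.
#' @return A tibble with one row per model: `kind`, `power`, and the fitted
#'   `trf_cv` objects in a list-column `cv`.
#' @export
compare_trf_models <- function(sessions, kinds = c("mixture", "streaming", "idealized"),
                               n_lags = 100, ...) {
  rows <- lapply(kinds, function(k) {
    cv <- cross_validate(build_design(sessions, k, n_lags = n_lags), ...)
    tibble::tibble(kind = k, power = cv$power, cv = list(cv))
  })
  dplyr::bind_rows(rows)
}

# ---- adapted TRF ---------------------------------------------------------

#' TRF with a neural-adaptation front end
#'
#' Each predictor stream is passed through the synaptic-depression +
#' gain-control model (on a spectrogram built from the stream's 200 Hz
#' envelope) before lag expansion; the adaptation parameters are chosen on
#' a grid to maximize the cross-validated predictive power, separately per
#' model. The mixture model's adapted input uses the mixture's own
#' spectrogram. The default grid is the study's TRF-mode grid: `V` in steps
#' of 0.05, `tau_sd` below 800 ms and `tau_gc` below 1400 ms in steps of
#' 200 ms.
#'
#' @param sessions `synth_session` objects (need 200 Hz stream envelopes).
#' @param kind Encoding model.
#' @param grid Tibble of candidate `V`, `tau_sd`, `tau_gc`.
#' @param n_channels_spec Channels of the synthetic spectrogram front end.
#' @param n_lags,lambda_grid,n_folds,inner_folds Passed to the TRF stage.
#' @return List with `cv` (best `trf_cv`), `params` (best
#'   [adaptation_params()]), and `scores` (grid with mean power).
#' @export
fit_adapted_trf <- function(sessions, kind = c("mixture", "streaming", "idealized"),
                            grid = adaptation_grid(tau_sd = seq(200, 600, by = 200),
                                                   tau_gc = seq(200, 1200, by = 200)),
                            n_channels_spec = 32, n_lags = 100,
                            lambda_grid = NULL, n_folds = 10, inner_folds = 3) {
  kind <- match.arg(kind)
  if (inherits(sessions, "synth_session")) sessions <- list(sessions)
  streams <- switch(kind, mixture = "mixture",
                    streaming = c("direct", "echo"), idealized = "direct")
  specs <- lapply(sessions, function(ss) {
    lapply(ss$streams_200[streams], envelope_to_spectrogram,
           n_channels = n_channels_spec)
  })
  # one normalization constant across the pooled sessions, so the threshold
  # V means the same thing in every condition entering one TRF
  q95 <- stats::quantile(unlist(lapply(specs, function(sl) {
    lapply(sl, function(sp) as.vector(sp$values))
  })), 0.95, names = FALSE)
  if (q95 > 0) {
    specs <- lapply(specs, function(sl) lapply(sl, function(sp) {
      sp$values <- sp$values / q95
      sp
    }))
  }
  run_one <- function(V, tau_sd, tau_gc) {
    p <- adaptation_params(V, tau_sd, tau_gc)
    adapted <- lapply(seq_along(sessions), function(i) {
      ss <- sessions[[i]]
      new_streams <- lapply(specs[[i]], function(sp) {
        env <- adapt(sp, p, normalize = FALSE)$envelope
        resample_track(env, ss$recording$rate)
      })
      list(streams = new_streams, response = ss$recording$data)
    })
    cross_validate(build_design(adapted, kind, n_lags = n_lags),
                   lambda_grid = lambda_grid, n_folds = n_folds,
                   inner_folds = inner_folds)
  }
  cvs <- purrr::pmap(grid, run_one)
  scores <- dplyr::mutate(grid, power = vapply(cvs, `[[`, numeric(1), "power"))
  best <- order(-scores$power, grid$V, grid$tau_sd, grid$tau_gc)[1]
  list(cv = cvs[[best]],
       params = adaptation_params(grid$V[best], grid$tau_sd[best], grid$tau_gc[best]),
       scores = scores)
}

#' Band-limited TRF analysis
#'
#' Responses and predictor streams are band-pass filtered (zero-phase
#' fourth-order Butterworth) before the standard TRF pipeline, allowing the
#' model comparison to be run separately in, e.g., the 0.8-5 Hz and 5-10 Hz
#' bands.
#'
#' @param sessions As in [build_design()].
#' @param band Length-2 numeric, `(lo, hi)` in Hz within the 0.8-10 Hz
#'   analysis band.
#' @param kind Encoding model.
#' @param ... Passed to [cross_validate()].
#' @param n_lags Number of lags.
#' @return A `trf_cv`.
#' @export
bandlimited_trf <- function(sessions, band, kind = c("mixture", "streaming", "idealized"),
                            n_lags = 100, ...) {
  kind <- match.arg(kind)
  stopifnot(length(band) == 2)
  if (band[1] >= band[2]) stop("inverted band", call. = FALSE)
  sessions <- as_trf_sessions(sessions)
  filt <- lapply(sessions, function(ss) {
    rate <- if (!is.null(ss$rate)) ss$rate else 100
    bf <- signal::butter(4, band / (rate / 2), type = "pass")
    bp <- function(v) as.numeric(signal::filtfilt(bf, v))
    streams <- lapply(ss$streams, function(s) {
      bp(if (is.numeric(s)) s else track_values(s))
    })
    resp <- t(apply(ss$response, 1, bp))
    list(streams = streams, response = resp, rate = rate)
  })
  cross_validate(build_design(filt, kind, n_lags = n_lags), ...)
}
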