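#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted TRF
#'
#' @param x An `echo_trf`.
#' @param ... Unused.
#' @return A tibble with columns `lag` (samples), `lag_s` (assuming the
#'   100 Hz analysis rate unless a `rate` attribute is present), `stream`,
#'   `channel`, `weight`.
#' @method tidy echo_trf
#' @export
tidy.echo_trf <- function(x, ...) {
  d <- dim(x$kernels)
  rate <- attr(x, "rate") %||% 100
  tibble::tibble(
    lag = rep(seq_len(d[1]), times = d[2] * d[3]),
    lag_s = rep(seq_len(d[1]), times = d[2] * d[3]) / rate,
    stream = rep(rep(x$streams, each = d[1]), times = d[3]),
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    weight = as.vector(x$kernels)
  )
}

#' Glance at a fitted TRF
#'
#' @param x An `echo_trf`.
#' @param ... Unused.
#' @return One-row tibble: model kind, lag count, stream and channel
#'   counts, ridge strength, mean residual variance.
#' @method glance echo_trf
#' @export
glance.echo_trf <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_lags = x$n_lags,
                 n_streams = length(x$streams),
                 n_channels = dim(x$kernels)[3], lambda = x$lambda,
                 sigma2 = if (is.null(x$sigma2)) NA_real_ else mean(x$sigma2))
}

#' Tidy cross-validated predictive power
#'
#' @param x A `trf_cv`.
#' @param ... Unused.
#' @return The per-fold, per-channel power tibble.
#' @method tidy trf_cv
#' @export
tidy.trf_cv <- function(x, ...) x$folds

#' Glance at cross-validated predictive power
#'
#' @param x A `trf_cv`.
#' @param ... Unused.
#' @return One-row tibble: kind, mean power, fold count, median lambda.
#' @method glance trf_cv
#' @export
glance.trf_cv <- function(x, ...) {
  tibble::tibble(kind = x$kind, power = x$power,
                 n_folds = max(x$folds$fold),
                 lambda = stats::median(x$lambda))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
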