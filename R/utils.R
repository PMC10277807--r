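#' @import data.table
#' @importFrom stats quantile rnorm rlnorm runif sd var cor lm coef median
#'   setNames aggregate dnorm qnorm rWishart complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior draw summary (median and 95% uncertainty interval)
#'
#' Summarizes a vector of posterior draws by its 50th, 2.5th and 97.5th
#' percentiles. Percentiles use linear interpolation between order statistics
#' with plotting position `k / (n + 1)` (`stats::quantile` type 6); the same
#' convention is applied everywhere draws are summarized in this package.
#'
#' @param draws numeric vector of posterior draws.
#' @return named numeric vector with elements `median`, `ui_low`, `ui_high`.
#' @examples
#' draw_summary(1:4000 / 100)
#' @export
draw_summary <- function(draws) {
  stopifnot(is.numeric(draws), length(draws) >= 1L, !anyNA(draws))
  q <- stats::quantile(draws, c(0.5, 0.025, 0.975), type = 6, names = FALSE)
  c(median = q[1], ui_low = q[2], ui_high = q[3])
}

## row-wise type-6 quantiles of a draws matrix (strata x draws)
.row_quantiles <- function(m, probs = c(0.5, 0.025, 0.975)) {
  t(apply(m, 1L, stats::quantile, probs = probs, type = 6, names = FALSE))
}

#' Weighted quantiles of a discrete distribution
#'
#' Quantile of a weighted sample, defined as the smallest observed value whose
#' cumulative normalized weight reaches `p`. With equal weights on `n` points
#' this returns an observed value (no interpolation), which is the convention
#' used for population-weighted cutpoints: the weighted median of
#' \{10 (w = 0.9), 100 (w = 0.1)\} is 10.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

## deterministic per-stage seed streams below 2^31
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

## draws-per-object contract: the pipeline carries exactly 4000 retained draws
N_DRAWS <- 4000L

assert_draw_count <- function(n, where) {
  if (n != N_DRAWS) {
    stop(sprintf("%s: expected exactly %d posterior draws, got %d",
                 where, N_DRAWS, n), call. = FALSE)
  }
}
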