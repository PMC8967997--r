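#' Split an amount over weights with exact largest-remainder cent rounding
#'
#' Divides `total` proportionally to `weights`, rounding every share to whole
#' cents so that the rounded shares sum to `total` exactly. Cents left over
#' after truncation go to the shares with the largest fractional remainders
#' (ties broken by position). Used wherever monetary conservation must hold
#' to the cent.
#'
#' @param total Amount in euros (non-negative, at most 2 decimals meaningful).
#' @param weights Non-negative numeric weights, at least one positive.
#' @return Numeric vector of euro amounts, `length(weights)` long, summing to
#'   `round(total, 2)` exactly.
#' @export
#' @examples
#' split_amount(100, c(1, 1, 1))  # 33.34 33.33 33.33
split_amount <- function(total, weights) {
  stopifnot(is.numeric(total), length(total) == 1L, total >= 0)
  if (length(weights) == 0L) stop("no weights to split over")
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- sum(weights)
  if (w <= 0) stop("all weights are zero; cannot allocate")
  total_cents <- round(total * 100)
  raw <- total_cents * weights / w
  base <- floor(raw)
  short <- round(total_cents - sum(base))
  if (short > 0) {
    frac <- raw - base
    take <- order(-frac, seq_along(frac))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  base / 100
}

#' Relative difference of two quantities
#'
#' `pct_diff(a, b)` is `(a - b) / b`: the relative excess of `a` over the
#' reference `b`, as a fraction (multiply by 100 for percent).
#'
#' @param a,b Numeric; `b` must be non-zero.
#' @return `(a - b) / b`.
#' @export
pct_diff <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), all(b != 0))
  (a - b) / b
}

# Log-normal meanlog/sdlog from an arithmetic mean and sd (moment matching).
lnorm_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Log-normal meanlog/sdlog from a median and interquartile range.
lnorm_from_quartiles <- function(median, q25, q75) {
  stopifnot(q25 > 0, q25 <= median, median <= q75)
  z75 <- stats::qnorm(0.75)
  list(meanlog = log(median), sdlog = (log(q75) - log(q25)) / (2 * z75))
}

# internal: stable per-patient RNG substream seed below 2^31
substream_seed <- function(seed, i) {
  as.integer(((seed %% 65011) * 33013 + i * 48271) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_day <- function(x) as.integer(as.Date(x))
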