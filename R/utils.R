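#' Round half away from zero
#'
#' Printed reference tables round half away from zero (so 0.0039 at three
#' decimals prints as 0.004), unlike [base::round()]'s banker's rounding.
#' Internal computation always keeps full precision; this is applied only at
#' presentation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.0039, 3)
#' round_half_up(22.815, 1)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Weighted empirical quantile with linear interpolation
#'
#' Survey-weighted analogue of `stats::quantile(type = 7)`: plotting positions
#' are the left-cumulative weight share, so with equal weights the result is
#' identical to type 7. Used for the 95th-percentile truncation of apparent
#' food consumption.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in \[0, 1\].
#' @param weights Positive weights, recycled to `length(x)`; default equal.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, probs, weights = NULL) {
  stopifnot(all(probs >= 0 & probs <= 1))
  keep <- !is.na(x)
  x <- x[keep]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  if (is.null(weights)) weights <- rep(1, length(x)) else {
    weights <- rep_len(weights, length(keep))[keep]
    stopifnot(all(weights > 0))
  }
  ord <- order(x)
  x <- x[ord]; w <- weights[ord]
  cw <- cumsum(w)
  denom <- cw[length(cw)] - w[length(w)]
  if (denom <= 0) return(rep(x[1], length(probs)))
  pp <- (cw - w) / denom  # equal weights: (i-1)/(n-1), i.e. type 7
  vapply(probs, function(p) stats::approx(pp, x, xout = p, rule = 2)$y, 0)
}

#' Survey-weighted prevalence of a condition
#'
#' @param indicator Logical (or 0/1) vector, one observation per unit.
#' @param weights Positive survey weights.
#' @return Prevalence in percent (0-100).
#' @export
weighted_prevalence <- function(indicator, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(indicator))
  stopifnot(length(indicator) == length(weights))
  tw <- sum(weights)
  if (tw <= 0) stop("total survey weight must be positive")
  100 * sum(weights * as.numeric(indicator)) / tw
}

# Percentile bootstrap over units (households or persons). `values` may be a
# vector (indicator or per-unit risk in [0,1]); the statistic is the weighted
# mean x 100. Returns a one-row tibble with the replicate vector attached as
# attr "boot" so post-stratification can combine replicates correctly.
boot_prevalence <- function(values, weights, n_boot = 500, conf = 0.95,
                            seed = NULL) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  tw <- sum(weights)
  if (tw <= 0) stop("total survey weight must be positive")
  point <- 100 * sum(weights * values) / tw
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    reps <- apply(idx, 1L, function(i) {
      100 * sum(weights[i] * values[i]) / sum(weights[i])
    })
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
    ci_low <- min(qs[1], point)
    ci_high <- max(qs[2], point)
  } else {
    reps <- numeric(0)
    ci_low <- point
    ci_high <- point
  }
  out <- tibble::tibble(point = point, ci_low = ci_low, ci_high = ci_high,
                        n_effective = n)
  attr(out, "boot") <- reps
  out
}

#' Convert ages in years to months
#'
#' Input files may report ages in whole years; internally all ages are months.
#' Year `y` maps to the start of the half-open band `[12y, 12y + 12)`.
#'
#' @param years Numeric vector of ages in years.
#' @return Ages in months.
#' @export
years_to_months <- function(years) {
  stopifnot(all(years >= 0, na.rm = TRUE))
  12 * years
}

# deterministic child seed: fold a label into a base seed, kept < 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
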