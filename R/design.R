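#' Cumulative probability of at least k positive replicates out of n
#'
#' Binomial tail P(X >= k), X ~ Binomial(n, p): the probability that a
#' k-of-n positive-calling rule declares an occupied site positive when each
#' water replicate independently detects with probability p.
#'
#' @param p per-replicate detection probability in \[0, 1\] (vectorized).
#' @param n number of water replicates.
#' @param k positive replicates required (1 <= k <= n).
#' @return probability.
#' @examples
#' cumulativeDetection(0.7564, 3, 1)  # 0.9855...
#' cumulativeDetection(0.9, 3, 2)     # 0.972
#' @export
cumulativeDetection <- function(p, n, k = 1) {
  if (k > n) stop("k must not exceed n")
  if (k < 1) stop("k must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' False-positive probability of a k-of-n calling rule
#'
#' Probability that an unoccupied site is called positive by a rule
#' requiring at least k of n replicates positive, when each replicate
#' produces a false positive independently with probability p10.  The same
#' binomial tail as [cumulativeDetection()], evaluated at p10; raising k
#' suppresses the rule-level false-positive rate far faster than it costs
#' detection.
#'
#' @param p10 per-replicate false-positive probability.
#' @param n number of replicates.
#' @param k positive replicates required.
#' @return probability.
#' @examples
#' ruleFalsePositive(0.091, 3, 1)  # 1 - (1 - 0.091)^3
#' ruleFalsePositive(0.091, 3, 2)  # 0.02284...
#' @export
ruleFalsePositive <- function(p10, n, k = 1) {
  cumulativeDetection(p10, n, k)
}

#' Smallest number of replicates achieving a target detection probability
#'
#' Smallest n >= k with [cumulativeDetection()]`(p, n, k) >= target`.  For
#' k = 1 this is the closed form ceiling(log(1 - target) / log(1 - p)).
#'
#' @param p per-replicate detection probability.
#' @param target cumulative detection probability to reach.
#' @param k positive replicates required.
#' @param nMax search ceiling; `NA` is returned (with a warning) if the
#'   target is unreachable within it, and immediately if p = 0.
#' @return integer replicate count, or `NA`.
#' @examples
#' minReplicates(0.7564, 0.95)  # 3
#' minReplicates(0.9744, 0.95)  # 1
#' @export
minReplicates <- function(p, target = 0.95, k = 1, nMax = 1000L) {
  if (p <= 0) {
    warning("p = 0: no finite number of replicates reaches the target")
    return(NA_integer_)
  }
  if (p >= 1) return(as.integer(k))
  if (k == 1) {
    n <- as.integer(ceiling(log(1 - target) / log(1 - p)))
    return(max(n, 1L))
  }
  for (n in seq.int(k, nMax))
    if (cumulativeDetection(p, n, k) >= target) return(as.integer(n))
  warning("target not reached within nMax = ", nMax)
  NA_integer_
}

#' Replicate-number design curve with propagated confidence limits
#'
#' Pushes a per-replicate detection estimate and its confidence interval
#' through the k-of-n binomial tail for n = k..nMax.  Because the tail is
#' monotone increasing in p, transforming the interval endpoints gives exact
#' interval endpoints for the cumulative probability.  When a false-positive
#' probability is supplied, the rule-level false-positive probability is
#' tabulated alongside.
#'
#' @param p per-replicate detection probability (point estimate).
#' @param lower,upper confidence limits for p (default: degenerate at p).
#' @param nMax largest replicate count tabulated.
#' @param k positive replicates required.
#' @param p10 optional per-replicate false-positive probability.
#' @return a [DesignCurve-class]; its `table` has columns `n`, `k`, `p`,
#'   `cumulative`, `lower`, `upper` and (if `p10` given) `fpRule`.
#' @examples
#' pr <- c(estimate = 0.7564, lower = 0.6511, upper = 0.8517)
#' designCurve(pr["estimate"], pr["lower"], pr["upper"], nMax = 5)
#' @export
designCurve <- function(p, lower = p, upper = p, nMax = 10, k = 1,
                        p10 = NULL) {
  stopifnot(lower >= 0, upper <= 1, lower <= upper)
  n <- seq.int(k, nMax)
  tab <- data.frame(
    n = n, k = k, p = unname(p),
    cumulative = vapply(n, function(nn) cumulativeDetection(p, nn, k), 0),
    lower = vapply(n, function(nn) cumulativeDetection(lower, nn, k), 0),
    upper = vapply(n, function(nn) cumulativeDetection(upper, nn, k), 0))
  if (!is.null(p10))
    tab$fpRule <- vapply(n, function(nn) ruleFalsePositive(p10, nn, k), 0)
  new("DesignCurve", table = tab, k = as.integer(k),
      p10 = if (is.null(p10)) NA_real_ else p10)
}

#' Design curve from a fitted model prediction
#'
#' Convenience wrapper: takes one row of [predictDetection()] output and
#' tabulates the replicate-design curve for it.
#'
#' @param prediction one-row `data.frame` with columns `estimate`, `lower`,
#'   `upper`.
#' @param nMax,k,p10 as in [designCurve()].
#' @return a [DesignCurve-class].
#' @export
designCurveFromFit <- function(prediction, nMax = 10, k = 1, p10 = NULL) {
  designCurve(prediction$estimate[1], prediction$lower[1],
              prediction$upper[1], nMax = nMax, k = k, p10 = p10)
}

setMethod("show", "DesignCurve", function(object) {
  cat(sprintf("DesignCurve: k = %d, per-replicate p = %.4f", object@k,
              object@table$p[1]))
  if (!is.na(object@p10)) cat(sprintf(", p10 = %.4g", object@p10))
  cat("\n")
  print(format(object@table, digits = 4), row.names = FALSE)
})

#' Tidy table of a design curve
#'
#' @param curve a [DesignCurve-class].
#' @return its `data.frame` (columns `n`, `k`, `p`, `cumulative`, `lower`,
#'   `upper`, optionally `fpRule`), suitable for writing to CSV or plotting.
#' @export
designTable <- function(curve) curve@table
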