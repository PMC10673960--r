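#' Power to detect a trait locus within a candidate interval
#'
#' Noncentral chi-square power for a one-degree-of-freedom dominant-genotype
#' contrast at a tested map position that may lie up to half the candidate
#' interval away from the true locus. The noncentrality is
#' \eqn{\delta = n (1-2r)^2 h^2/(1-h^2)}{delta = n (1-2r)^2 h2/(1-h2)},
#' where the recombination fraction comes from `haldane_r(interval_cm/2)`:
#' the full-information noncentrality attenuated by the squared genotype
#' correlation \eqn{(1-2r)^2}{(1-2r)^2}
#' across the marker-locus gap. Power is the upper tail of
#' `chisq(1, delta)` beyond the central `1 - alpha` quantile. `h2 = 1` is
#' the limit `delta -> Inf`, power 1. Power increases in `n` and `h2` and
#' decreases in `interval_cm` and in alpha stringency.
#'
#' @param n Offspring count (>= 2).
#' @param h2 Proportion of trait variance explained by the locus, in
#'   `[0, 1]`.
#' @param interval_cm Candidate-interval width in cM.
#' @param alpha Type-I error rate (default 0.01).
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' qtl_power(n = 75, h2 = 1, interval_cm = 5, alpha = 0.01)  # 1
#' qtl_power(n = 75, h2 = 0, interval_cm = 5, alpha = 0.01)  # = alpha
qtl_power <- function(n, h2, interval_cm, alpha = 0.01) {
  stopifnot(n >= 2, h2 >= 0, h2 <= 1, interval_cm >= 0,
            alpha > 0, alpha < 1)
  if (h2 >= 1) return(1)
  r <- haldane_r(interval_cm / 2)
  delta <- n * (1 - 2 * r)^2 * h2 / (1 - h2)
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = delta,
         lower.tail = FALSE)
}

#' Smallest trait variance reaching a target power
#'
#' Scans the proportion of trait variance explained on a 1\% grid (0-100\%)
#' and returns the smallest value at which power, rounded to the nearest
#' percent, reaches the target.
#'
#' @param n Offspring count.
#' @param interval_cm Candidate-interval width in cM.
#' @param alpha Type-I error rate.
#' @param power_target Target power in `[0, 1]` (compared after rounding
#'   both sides to the nearest percent).
#' @return The threshold as a percentage (integer), or `NA` with a message
#'   when the target is unattainable at `h2 = 100%`.
#' @export
#' @examples
#' power_threshold_h2(n = 75, interval_cm = 5, alpha = 0.01,
#'                    power_target = 0.95)
power_threshold_h2 <- function(n, interval_cm, alpha = 0.01,
                               power_target = 1) {
  stopifnot(power_target >= 0, power_target <= 1)
  target_pct <- round(100 * power_target)
  for (h in 0:100) {
    p <- round(100 * qtl_power(n, h / 100, interval_cm, alpha))
    if (p >= target_pct) return(h)
  }
  message("target power unattainable even at h2 = 100%")
  NA_integer_
}
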