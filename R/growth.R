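#' Relative growth rate between two sampling points
#'
#' Log-scale mass growth per unit time:
#' \deqn{RGR = \frac{\ln w_2 - \ln w_1}{t_2 - t_1}}
#' with \eqn{w_1, w_2} the mean fruit fresh weights (g) at times
#' \eqn{t_1 < t_2} (days). The rate is scale-invariant in the weights and
#' additive over adjacent intervals (the RGR over a union of intervals is
#' the duration-weighted mean of the per-interval rates).
#'
#' @param weight_1,weight_2 strictly positive fresh weights (g).
#' @param t1,t2 sampling times (days), \code{t2 > t1}.
#' @return growth rate in day^-1 (vectorized over its arguments).
#' @examples
#' relativeGrowthRate(10, 20, 0, 7)   # log(2)/7
#' @export
relativeGrowthRate <- function(weight_1, weight_2, t1, t2) {
  if (any(weight_1 <= 0) || any(weight_2 <= 0))
    stop("fruit weights must be strictly positive")
  if (any(t2 <= t1))
    stop("t2 must be later than t1")
  (log(weight_2) - log(weight_1)) / (t2 - t1)
}
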