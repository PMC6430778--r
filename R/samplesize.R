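#' Sample size for a proportion with finite-population correction
#'
#' The survey formula used to plan the study (as in OpenEpi's SSPropor):
#' \deqn{n = \frac{DEFF \cdot N p (1-p)}{\frac{d^2}{Z^2}(N-1) + p(1-p)}}
#' rounded up (conservative). `Z` is supplied directly (1.96 for 95%
#' confidence) rather than derived from a significance level, matching how
#' the calculators are used.
#'
#' @param N finite population size (>= 1)
#' @param p hypothesised proportion in `[0, 1]`
#' @param d absolute precision in (0, 1) (default 0.05)
#' @param Z standard-normal quantile for the confidence level (default 1.96)
#' @param deff design effect >= 1 (default 1)
#' @return integer required sample size
#' @examples
#' required_sample_size(N = 420, p = 0.5) # 201
#' @export
required_sample_size <- function(N, p, d = 0.05, Z = 1.96, deff = 1) {
  if (N < 1 || p < 0 || p > 1 || deff < 1) {
    stop_dentalage("need N >= 1, p in [0, 1], deff >= 1", "invalid_input")
  }
  if (d <= 0 || Z <= 0) {
    stop_dentalage("precision d and quantile Z must be positive", "invalid_input")
  }
  pq <- p * (1 - p)
  if (pq == 0) return(0L)
  as.integer(ceiling(deff * N * pq / ((d^2 / Z^2) * (N - 1) + pq)))
}
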