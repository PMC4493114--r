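#' Piecewise-linear regression splines
#'
#' A trajectory on the log scale is a piecewise-linear spline: a base slope
#' `beta[1]` and `k` slope increments `beta[2..k+1]`, each switching on at a
#' change-point year (knot) `theta[j]`:
#'
#'   f(t) = beta1 * t + sum_j beta[j+1] * I(t >= theta_j) * (t - theta_j)
#'
#' The function is continuous everywhere; only its slope jumps at knots.
#' Time `t` is the 1-based year index within the series.
#'
#' @param t numeric vector of year indices at which to evaluate.
#' @param beta numeric vector of length `k + 1`: base slope followed by the
#'   slope increments in the order of `theta`.
#' @param theta numeric vector of `k` distinct knot year indices (may be
#'   empty for a straight line).
#' @return Numeric vector of spline values at `t`.
#' @examples
#' evaluate_spline(41, beta = c(0.02, -0.06), theta = 20)  # 0.02*41 - 0.06*21
#' @export
evaluate_spline <- function(t, beta, theta = numeric(0)) {
  k <- length(theta)
  if (length(beta) != k + 1)
    stop("'beta' must have one more element than 'theta'")
  out <- beta[1] * t
  for (j in seq_len(k)) out <- out + beta[j + 1] * pmax(t - theta[j], 0)
  out
}

# Anchored spline: f(t) - f(t_mid).  The change-point model's data are
# log indices centred on the mid-year, so each trajectory enters the model
# mean anchored at zero in the mid-year; slopes and knots are unaffected.
evaluate_spline_anchored <- function(t, beta, theta, t_mid) {
  evaluate_spline(t, beta, theta) - evaluate_spline(t_mid, beta, theta)
}

# Anchored basis column for a single knot at theta (slope-increment basis).
knot_basis <- function(t, theta, t_mid) {
  pmax(t - theta, 0) - max(t_mid - theta, 0)
}

#' Per-year prior change-point probability
#'
#' With a Binomial(`k_max`, `p`) prior on the number of change points spread
#' uniformly over `n_candidate_years` candidate years, the prior probability
#' that any given year holds a change point is the expected knot count
#' divided evenly over the candidates: `(k_max * p) / n_candidate_years`.
#' With `k_max = 2`, `p = 0.5` and a 41-year series this is 1/41 = 0.024.
#'
#' @param k_max maximum number of change points allowed by the prior.
#' @param p Binomial success probability (0.5 by default everywhere here).
#' @param n_candidate_years number of years over which knots may fall.
#' @return A probability.
#' @export
prior_changepoint_probability <- function(k_max, p, n_candidate_years) {
  if (n_candidate_years < 1) stop("need at least one candidate year")
  if (k_max < 0 || k_max > n_candidate_years)
    stop("'k_max' must lie in [0, n_candidate_years]")
  (k_max * p) / n_candidate_years
}

#' Posterior-to-prior odds ratio
#'
#' The evidence measure for a change point in a given year:
#' `[p1/(1-p1)] / [p0/(1-p0)]`.  A ratio above 3 is treated as strong
#' evidence of a change point.
#'
#' @param p1 posterior probability (in `[0, 1]`; 1 maps to `Inf`).
#' @param p0 prior probability (in `(0, 1)`).
#' @return The odds ratio (vectorised over `p1`).
#' @export
odds_ratio <- function(p1, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("'p0' must be in (0, 1)")
  if (any(p1 < 0) || any(p1 > 1)) stop("'p1' must be in [0, 1]")
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}
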