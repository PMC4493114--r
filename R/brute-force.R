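#' Exact posterior over knot configurations by enumeration
#'
#' Independent oracle for the reversible-jump sampler on instances small
#' enough to enumerate: a single species, a single trajectory with at most
#' `k_max = 2` knots, and the process SD held fixed.  For every knot
#' configuration (every subset of candidate years up to size `k_max`) the
#' slope parameters are integrated analytically — the model is Gaussian and
#' the slope prior Normal(0, `slope_sd^2`), so the marginal likelihood is
#' the density of `z ~ N(0, slope_sd^2 X X' + V)` with `X` the anchored
#' spline design and `V` the diagonal of known-plus-process variances.
#' Combining with the truncated Binomial / uniform-subset configuration
#' prior gives the exact normalised posterior.
#'
#' @param data a `centered_index_data` with one species in one stratum and
#'   at most 15 years.
#' @param spec a [cp_model_spec()] whose only trajectory is the species
#'   trajectory (`M_s` with one species); `k_max` at most 2.
#' @param sigma_p_fixed fixed process SD (>= 0).
#' @return A list of class `brute_force_posterior`: `configs` (list of
#'   sorted knot-year vectors), `prob` (posterior probabilities summing to
#'   1), `log_marginal`, and `p_year` (per-candidate-year change-point
#'   probabilities).
#' @export
brute_force_posterior <- function(data, spec, sigma_p_fixed) {
  if (length(unique(data$species)) != 1 ||
      length(unique(data$stratum)) != 1)
    stop("enumeration oracle requires a single species in a single stratum")
  T <- max(data$t)
  if (T > 15) stop("instance too large to enumerate (T > 15)")
  if (length(spec$trajectories) != 1)
    stop("enumeration oracle requires a single trajectory")
  km <- spec$trajectories[[1]]$k_max
  if (km > 2) stop("instance too large to enumerate (k_max > 2)")
  t_mid <- ceiling(T / 2)
  cand <- spec$candidates
  tau <- spec$slope_sd
  z <- data$z
  V <- data$var + sigma_p_fixed^2
  configs <- list(integer(0))
  if (km >= 1) configs <- c(configs, as.list(cand))
  if (km >= 2 && length(cand) >= 2) {
    prs <- utils::combn(cand, 2, simplify = FALSE)
    configs <- c(configs, prs)
  }
  lml <- vapply(configs, function(th) {
    X <- cbind(data$t - t_mid,
               vapply(th, function(y) knot_basis(data$t, y, t_mid),
                      numeric(length(z))))
    Sg <- tau^2 * tcrossprod(X) + diag(V, length(z))
    U <- chol(Sg)
    -0.5 * (length(z) * log(2 * pi)) - sum(log(diag(U))) -
      0.5 * sum(backsolve(U, z, transpose = TRUE)^2)
  }, numeric(1))
  k <- lengths(configs)
  lprior <- stats::dbinom(k, km, 0.5, log = TRUE) -
    lchoose(length(cand), k)
  lpost <- lml + lprior
  prob <- exp(lpost - max(lpost))
  prob <- prob / sum(prob)
  p_year <- vapply(cand, function(y)
    sum(prob[vapply(configs, function(th) y %in% th, logical(1))]),
    numeric(1))
  structure(list(configs = configs, prob = prob, log_marginal = lml,
                 p_year = stats::setNames(p_year, cand)),
            class = "brute_force_posterior")
}
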