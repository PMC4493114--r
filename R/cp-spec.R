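#' Change-point model structures
#'
#' The five competing structures for the true log abundance
#' `H_{i,t,s}` of species `s` in year `t` within a stratum:
#'
#' * `M_s`:       `H = f_s(t)`                        (species-specific only)
#' * `M_AllAI`:   `H = f_s(t) + f_AllAI(t)`           (one shared group)
#' * `M_FC_SSN`:  `H = f_s(t) + f_FC(t)` or `+ f_SSN(t)` (each species gets
#'   its own group's trajectory)
#' * `M_FC`:      group trajectory for flycatchers only
#' * `M_SSN`:     group trajectory for swallows/swifts/nightjars only
#'
#' Knot-count priors are Binomial(2, 0.5) for group trajectories and for
#' species trajectories accompanied by a group trajectory, and
#' Binomial(4, 0.5) for species without one, so each species is allowed at
#' most four change points in total.  Candidate change-point years are the
#' interior year indices `2..T-1`: an endpoint knot would be unidentifiable
#' since its basis vanishes on all data.
#'
#' @param name one of `"M_s"`, `"M_AllAI"`, `"M_FC_SSN"`, `"M_FC"`,
#'   `"M_SSN"`.
#' @param species_groups data frame with columns `species`, `group`.
#' @param n_years length `T` of the series.
#' @param slope_sd prior SD of the base slope and of every slope increment
#'   (weakly informative; a fully diffuse slope prior would degenerate the
#'   across-dimension comparison).
#' @param species_k_max optional override of the species knot-count cap,
#'   used for restricted instances (e.g. validating the sampler against the
#'   enumeration oracle, which requires `k_max <= 2`).
#' @return A list of class `cp_model_spec` with one entry per trajectory
#'   (`id`, `type`, `members`, `k_max`) plus the candidate year set.
#' @export
cp_model_spec <- function(name, species_groups, n_years, slope_sd = 1,
                          species_k_max = NULL) {
  name <- match.arg(name, c("M_s", "M_AllAI", "M_FC_SSN", "M_FC", "M_SSN"))
  sp <- species_groups$species
  grp <- stats::setNames(species_groups$group, sp)
  group_defs <- switch(name,
    M_s = list(),
    M_AllAI = list(AllAI = sp),
    M_FC_SSN = list(FC = sp[grp == "FC"], SSN = sp[grp == "SSN"]),
    M_FC = list(FC = sp[grp == "FC"]),
    M_SSN = list(SSN = sp[grp == "SSN"]))
  group_defs <- group_defs[lengths(group_defs) > 0]
  in_group <- sp %in% unlist(group_defs)
  trajectories <- c(
    lapply(names(group_defs), function(g)
      list(id = g, type = "group", members = group_defs[[g]], k_max = 2L)),
    lapply(seq_along(sp), function(i)
      list(id = sp[i], type = "species", members = sp[i],
           k_max = if (!is.null(species_k_max)) as.integer(species_k_max)
                   else if (in_group[i]) 2L else 4L)))
  names(trajectories) <- vapply(trajectories, `[[`, "", "id")
  if (n_years < 4) stop("need at least 4 years for interior candidates")
  structure(list(name = name, trajectories = trajectories,
                 candidates = 2:(n_years - 1L), n_years = as.integer(n_years),
                 slope_sd = slope_sd, species = sp,
                 groups = grp),
            class = "cp_model_spec")
}

# Trajectory ids contributing to species s under this spec.
trajs_for_species <- function(spec, s) {
  ids <- s
  for (tr in spec$trajectories)
    if (tr$type == "group" && s %in% tr$members) ids <- c(tr$id, ids)
  ids
}

#' Model mean for one species and year
#'
#' The modelled true log abundance of species `s` at year index `t`: the
#' species' own spline plus, if the model structure includes one, the spline
#' of that species' group (and only that group).  Each trajectory enters
#' anchored at the mid-year (`f(t) - f(t_mid)`), matching the centring of
#' the data.
#'
#' @param spec a [cp_model_spec()].
#' @param states named list of spline states, one per trajectory id, each a
#'   list with `beta` (base slope then increments) and `theta` (knot years).
#' @param s species label.
#' @param t year index (vectorised).
#' @param t_mid mid-year index used for anchoring (default
#'   `ceiling(T / 2)`).
#' @return Numeric vector of model means at `t`.
#' @export
model_mean <- function(spec, states, s, t, t_mid = ceiling(spec$n_years / 2)) {
  ids <- trajs_for_species(spec, s)
  out <- numeric(length(t))
  for (id in ids) {
    st <- states[[id]]
    if (is.null(st)) stop("species ", s, " lacks a state for trajectory ", id)
    out <- out + evaluate_spline_anchored(t, st$beta, st$theta, t_mid)
  }
  out
}

#' Marginal Gaussian log-likelihood of the change-point model
#'
#' With the latent true abundances integrated out, each centred log index is
#' Normal with mean the model mean and variance `sigma_eta^2 + sigma_p^2`
#' (known observation variance plus process variance).
#'
#' @param spec a [cp_model_spec()].
#' @param states named list of spline states (see [model_mean()]).
#' @param data a `centered_index_data` for a single stratum.
#' @param sigma_p process SD.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(spec, states, data, sigma_p) {
  T <- max(data$t)
  t_mid <- ceiling(T / 2)
  v <- data$var + sigma_p^2
  m <- numeric(nrow(data))
  for (s in unique(data$species)) {
    rows <- which(data$species == s)
    m[rows] <- model_mean(spec, states, s, data$t[rows], t_mid)
  }
  if (any(!is.finite(m)) || any(!is.finite(v)))
    stop("non-finite model mean or variance")
  sum(stats::dnorm(data$z, m, sqrt(v), log = TRUE))
}

#' Sampler configuration for the change-point model
#'
#' @param n_iterations,burn_in,thinning MCMC schedule.
#' @param seed integer seed.
#' @param sigma_p_fixed if non-`NULL`, the process SD is held at this value
#'   instead of being sampled (used when validating against exact
#'   enumeration).
#' @param ig_shape,ig_scale inverse-gamma prior on `sigma_p^2`.
#' @param likelihood set `FALSE` to disable the likelihood entirely, so the
#'   sampler targets the prior (a prior-recovery check).
#' @return A list of class `cp_config`.
#' @export
cp_config <- function(n_iterations = 20000, burn_in = 4000, thinning = 1,
                      seed = 1L, sigma_p_fixed = NULL,
                      ig_shape = 0.001, ig_scale = 0.001,
                      likelihood = TRUE) {
  if (burn_in >= n_iterations) stop("'burn_in' must be below 'n_iterations'")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 sigma_p_fixed = sigma_p_fixed, ig_shape = ig_shape,
                 ig_scale = ig_scale, likelihood = isTRUE(likelihood)),
            class = "cp_config")
}
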