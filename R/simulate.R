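#' Simulate ground-truth trajectories and spatial year effects
#'
#' Builds the noiseless log-scale group and species trajectories by the same
#' piecewise-linear spline formula the change-point model fits, and a
#' zero-mean spatial year effect for every stratum and year.  The spatial
#' field is drawn as independent Normal(0, `sigma_gamma`) values per stratum
#' and re-centred to sum to exactly zero within each year: the intrinsic CAR
#' prior is improper, so any proper centred field is valid ground truth for
#' recovery experiments.
#'
#' @param config a [sim_config()].
#' @param graph a [stratum_graph()] covering the configured grid.
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `true_trajectories`: list with `years`
#'   (calendar labels), `t` (1-based year indices), `group_log_traj` and
#'   `species_log_traj` (named lists of length-`T` vectors),
#'   `true_knots` (named list of data frames `year,increment`), and
#'   `gamma_true` (strata x years matrix).
#' @export
simulate_trajectories <- function(config, graph, seed = config$seed) {
  T <- config$n_years
  tt <- seq_len(T)
  eval_ts <- function(ts) {
    check_knots(ts, T)
    evaluate_spline(tt, c(ts$base_slope, ts$knot_increments), ts$knot_years)
  }
  group_log_traj <- lapply(config$group_traj, eval_ts)
  species_log_traj <- lapply(config$species_traj, eval_ts)
  knots_of <- function(ts) data.frame(year = ts$knot_years,
                                      increment = ts$knot_increments)
  true_knots <- c(lapply(config$group_traj, knots_of),
                  lapply(config$species_traj, knots_of))
  S <- length(graph$strata)
  set.seed(seed)
  gamma <- matrix(0, S, T, dimnames = list(graph$strata, NULL))
  if (config$sigma_gamma > 0) {
    for (t in tt) {
      g <- stats::rnorm(S, 0, config$sigma_gamma)
      g <- g - mean(g)
      g[S] <- -sum(g[-S])       # exact zero sum
      gamma[, t] <- g
    }
  }
  structure(list(years = config$start_year + tt - 1L, t = tt,
                 group_log_traj = group_log_traj,
                 species_log_traj = species_log_traj,
                 true_knots = true_knots, gamma_true = gamma),
            class = "true_trajectories")
}

# Total log-scale year signal for one species: its group trajectory (if its
# group has one) plus its own species trajectory.
total_log_traj <- function(traj, config, species) {
  grp <- config$species$group[match(species, config$species$species)]
  if (is.na(grp)) stop("unknown species: ", species)
  out <- traj$species_log_traj[[species]]
  if (is.null(out)) out <- numeric(length(traj$t))
  if (!is.null(traj$group_log_traj[[grp]]))
    out <- out + traj$group_log_traj[[grp]]
  out
}

#' Simulate a route-level count dataset for one species
#'
#' Counts follow an overdispersed Poisson model: for stratum `i`, observer-
#' route pair `j`, year `t`,
#' `log(lambda) = s_i + mu_t + gamma_{i,t} + omega_{i,j} + zeta * I(j,t) +
#' eps_{i,j,t}`, where `s_i` is the log baseline abundance, `mu_t` the
#' species' total log trajectory, `gamma` the spatial year effect,
#' `omega` a route-by-observer effect, `I(j,t)` flags an observer's first
#' year on that route, and `eps` is log-normal overdispersion.  Observers
#' turn over with geometric tenure; routes outside the species' range (with
#' probability `p_never_detected`) record structural zeros.
#'
#' @param traj a [simulate_trajectories()] result.
#' @param config the [sim_config()] used for `traj`.
#' @param graph the matching [stratum_graph()].
#' @param species species label (defaults to the first configured species).
#' @param seed integer seed (defaults to `config$seed`).
#' @return A data frame of class `count_dataset` with columns
#'   `stratum, route, observer, year, count, first_year` and attributes
#'   `species` and `seed`.
#' @export
simulate_counts <- function(traj, config, graph,
                            species = config$species$species[1],
                            seed = config$seed) {
  T <- config$n_years
  if (length(traj$t) != T)
    stop("trajectories and config span different year ranges")
  mu <- total_log_traj(traj, config, species)
  strata <- graph$strata
  s_true <- log(rep_len(config$base_abundance, length(strata)))
  set.seed(seed)
  rows <- vector("list", length(strata) * config$n_routes)
  ri <- 0L
  for (i in seq_along(strata)) {
    for (r in seq_len(config$n_routes)) {
      ri <- ri + 1L
      route <- sprintf("%s_R%02d", strata[i], r)
      off_range <- stats::runif(1) < config$p_never_detected
      # observer tenure sequence covering the T years
      obs_idx <- integer(T); first <- integer(T)
      o <- 0L; t <- 1L
      while (t <= T) {
        o <- o + 1L
        tenure <- 1L + stats::rgeom(1, 1 / config$mean_tenure)
        span <- t:min(T, t + tenure - 1L)
        obs_idx[span] <- o
        first[span[1]] <- 1L
        t <- t + tenure
      }
      omega <- stats::rnorm(o, 0, config$sigma_omega)
      eps <- stats::rnorm(T, 0, config$sigma_eps)
      loglam <- s_true[i] + mu + traj$gamma_true[i, ] + omega[obs_idx] +
        config$zeta * first + eps
      count <- if (off_range) rep(0L, T) else stats::rpois(T, exp(loglam))
      rows[[ri]] <- data.frame(
        stratum = strata[i], route = route,
        observer = sprintf("%s_O%02d", route, obs_idx),
        year = config$start_year + traj$t - 1L,
        count = count, first_year = first)
    }
  }
  out <- do.call(rbind, rows)
  if (config$exclude_undetected) {
    seen <- tapply(out$count, out$route, function(x) any(x > 0))
    out <- out[seen[out$route], , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "species") <- species
  attr(out, "seed") <- seed
  class(out) <- c("count_dataset", "data.frame")
  out
}

#' Simulate annual-index tables directly from true trajectories
#'
#' Produces the stage-two input (per species x stratum x year log abundance
#' indices with known log-scale variances) directly from the configured
#' ground truth, bypassing the count stage.  Observed log indices are the
#' true total log trajectory (optionally plus the spatial year effect) with
#' added Normal(0, `sigma_eta`) observation error; the variance column
#' carries `sigma_eta^2` as known.  The mid-year value is generated without
#' error: the change-point stage centres every series on its mid-year, so
#' anchoring the noise there makes the centred series carry independent
#' errors with exactly the stated variance — the observation model the
#' change-point stage assumes.  (Without the anchor, centring would inject
#' a common offset `-eps(mid)` into every other year of the series.)
#'
#' @param traj a [simulate_trajectories()] result.
#' @param config the matching [sim_config()].
#' @param strata character vector of stratum labels to emit.
#' @param sigma_eta known observation SD of the log indices.
#' @param include_gamma add the stratum-year spatial effect to the truth
#'   (only for strata present in `traj$gamma_true`).
#' @param seed integer seed.
#' @return An `annual_index_set` data frame (see [annual_index_set()]).
#' @export
simulate_annual_indices <- function(traj, config, strata = "S01_01",
                                    sigma_eta = 0.05, include_gamma = FALSE,
                                    seed = config$seed) {
  T <- config$n_years
  set.seed(seed)
  out <- list()
  for (st in strata) {
    for (sp in config$species$species) {
      truth <- total_log_traj(traj, config, sp)
      if (include_gamma) truth <- truth + traj$gamma_true[st, ]
      eps <- stats::rnorm(T, 0, sigma_eta)
      eps[ceiling(T / 2)] <- 0           # mid-year anchor (see above)
      lg <- truth + eps
      out[[length(out) + 1L]] <- data.frame(
        species = sp, stratum = st, year = traj$years,
        index = exp(lg), log_index_mean = lg,
        log_index_var = sigma_eta^2, pi = 1)
    }
  }
  annual_index_set(do.call(rbind, out))
}
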