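# Shared fixture builders; everything is generated in code at test time.

# Tiny single-stratum, single-species instance small enough for the
# enumeration oracle (T = 12, k_max = 2).
oracle_instance <- function(seed = 3, sigma_eta = 0.1) {
  cfg <- sim_config(grid_rows = 1, grid_cols = 1, n_years = 12,
                    species = data.frame(species = "SP1", group = "FC"),
                    group_traj = list(FC = traj_spec(0.02, 6, -0.08)),
                    sigma_gamma = 0, seed = seed)
  g <- build_stratum_graph(1, 1)
  tr <- simulate_trajectories(cfg, g)
  idx <- simulate_annual_indices(tr, cfg, strata = "S01_01",
                                 sigma_eta = sigma_eta, seed = seed + 2)
  cen <- prepare_inputs(idx, cfg$species)
  spec <- cp_model_spec("M_s", cfg$species, 12, species_k_max = 2)
  list(config = cfg, data = cen, spec = spec)
}

# Five species sharing one strong group change point (year 20 of 41,
# increment -0.06) with small known observation error.
shared_knot_instance <- function(seed = 2, sigma_eta = 0.05) {
  cfg <- sim_config(grid_rows = 1, grid_cols = 1, n_years = 41,
                    species = data.frame(species = paste0("SP", 1:5),
                                         group = "SSN"),
                    group_traj = list(SSN = traj_spec(0.02, 20, -0.06)),
                    sigma_gamma = 0, seed = seed)
  g <- build_stratum_graph(1, 1)
  tr <- simulate_trajectories(cfg, g)
  idx <- simulate_annual_indices(tr, cfg, strata = "S01_01",
                                 sigma_eta = sigma_eta, seed = seed + 2)
  list(config = cfg, trajectories = tr,
       data = prepare_inputs(idx, cfg$species))
}

# Hand-built count dataset (for detection/offset unit tests).
manual_counts <- function(df, species = "SPX", seed = NA_integer_) {
  attr(df, "species") <- species
  attr(df, "seed") <- seed
  class(df) <- c("count_dataset", "data.frame")
  df
}

# Minimal cp_draws object built by hand, for summary-level unit tests.
manual_cp_draws <- function(theta, beta, years, k_max = 2,
                            id = "G", type = "group") {
  nd <- length(theta)
  T <- length(years)
  structure(list(
    trajectories = stats::setNames(list(list(
      id = id, type = type, members = "SP1", k_max = k_max,
      theta = theta, beta = beta)), id),
    sigma_p = rep(0.05, nd), loglik = rep(0, nd),
    mean_fit = numeric(0), n_draws = nd,
    data = NULL, spec = NULL, config = cp_config(n_iterations = 2,
                                                 burn_in = 1),
    t_mid = ceiling(T / 2), candidates = 2:(T - 1), years = years),
    class = "cp_draws")
}

# Total-variation distance between an empirical configuration table and an
# exact posterior from brute_force_posterior().
config_tv <- function(draws, exact) {
  key <- function(th) paste(th, collapse = ",")
  emp <- table(vapply(draws$trajectories[[1]]$theta, key, ""))
  emp <- emp / draws$n_draws
  ex <- stats::setNames(exact$prob, vapply(exact$configs, key, ""))
  keys <- union(names(emp), names(ex))
  e1 <- as.numeric(emp[keys]); e1[is.na(e1)] <- 0
  e2 <- as.numeric(ex[keys]); e2[is.na(e2)] <- 0
  0.5 * sum(abs(e1 - e2))
}
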