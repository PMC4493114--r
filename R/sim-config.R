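#' Trajectory specification for the generator
#'
#' Describes one piecewise-linear log-scale trajectory: a base slope and
#' optional slope increments at knot year indices.
#'
#' @param base_slope log-scale slope per year before any knot.
#' @param knot_years integer year indices (within `[2, T - 1]`) of the
#'   change points.
#' @param knot_increments slope increments applied at `knot_years`.
#' @return A list of class `traj_spec`.
#' @export
traj_spec <- function(base_slope = 0, knot_years = integer(0),
                      knot_increments = numeric(0)) {
  if (length(knot_years) != length(knot_increments))
    stop("'knot_years' and 'knot_increments' must have the same length")
  if (anyDuplicated(knot_years)) stop("knot years must be distinct")
  structure(list(base_slope = base_slope,
                 knot_years = as.numeric(knot_years),
                 knot_increments = as.numeric(knot_increments)),
            class = "traj_spec")
}

#' Simulation configuration
#'
#' Collects every generative quantity of the synthetic survey: grid layout,
#' time span, route and observer structure, the variance components and the
#' first-year observer effect of the count model, baseline abundance, and the
#' true group-level and species-specific trajectories.
#'
#' Defaults describe a moderately common aerial insectivore surveyed over 41
#' years (1970-2010, matching the per-year prior denominator of 41): mean
#' count 10 per route, observers serving a geometric mean tenure of 7 years,
#' a small negative first-year observer effect, modest overdispersion, and a
#' swallow-like group downturn (slope increment -0.06 at year 20) against a
#' flycatcher group with an upturn followed by a downturn.
#'
#' @param grid_rows,grid_cols stratum grid dimensions.
#' @param bcr_blocks column blocks for BCR labels.
#' @param n_years number of surveyed years `T` (>= 3).
#' @param start_year calendar label of the first year.
#' @param n_routes routes per stratum.
#' @param mean_tenure mean observer tenure in years (geometric; >= 1).
#' @param zeta first-year observer effect on the log scale.
#' @param sigma_omega SD of route-by-observer random effects.
#' @param sigma_eps SD of the log-normal overdispersion effects.
#' @param sigma_gamma per-year SD of the spatially correlated stratum
#'   effects (the CAR field's scale).
#' @param base_abundance expected count per route at baseline; scalar or one
#'   value per stratum.
#' @param species data frame with columns `species` and `group` (`"FC"` or
#'   `"SSN"`).
#' @param group_traj named list of [traj_spec()]s, one per group.
#' @param species_traj named list of [traj_spec()]s, one per species
#'   (defaults to flat zero trajectories).
#' @param p_never_detected probability a route lies outside the species'
#'   range and never detects it (all counts zero there).
#' @param exclude_undetected if `TRUE`, never-detecting routes are dropped
#'   from the generated dataset (the survey convention of excluding routes
#'   on which a species was never seen); if `FALSE` they are kept as zeros.
#' @param seed integer seed recorded with every artefact.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 3, grid_cols = 3, bcr_blocks = 2,
                       n_years = 41, start_year = 1970,
                       n_routes = 8, mean_tenure = 7,
                       zeta = -0.15, sigma_omega = 0.25, sigma_eps = 0.15,
                       sigma_gamma = 0.1, base_abundance = 10,
                       species = data.frame(
                         species = c("FC1", "FC2", "SSN1", "SSN2"),
                         group = c("FC", "FC", "SSN", "SSN")),
                       group_traj = list(
                         FC = traj_spec(0.0, c(12, 22), c(0.03, -0.05)),
                         SSN = traj_spec(0.01, 20, -0.06)),
                       species_traj = NULL,
                       p_never_detected = 0.15,
                       exclude_undetected = FALSE,
                       seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) stop("grid dimensions must be positive")
  if (n_years < 3) stop("'n_years' must be at least 3")
  if (mean_tenure < 1) stop("'mean_tenure' must be at least 1")
  for (s in c(sigma_omega, sigma_eps, sigma_gamma))
    if (s < 0) stop("standard deviations must be non-negative")
  if (p_never_detected < 0 || p_never_detected > 1)
    stop("'p_never_detected' must be a probability")
  if (!all(c("species", "group") %in% names(species)))
    stop("'species' must have columns species and group")
  if (is.null(species_traj)) {
    species_traj <- stats::setNames(
      rep(list(traj_spec(0)), nrow(species)), species$species)
  }
  if (!all(names(group_traj) %in% unique(species$group)) &&
      length(group_traj))
    group_traj <- group_traj[intersect(names(group_traj), species$group)]
  cfg <- structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols, bcr_blocks = bcr_blocks,
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_routes = as.integer(n_routes), mean_tenure = mean_tenure,
    zeta = zeta, sigma_omega = sigma_omega, sigma_eps = sigma_eps,
    sigma_gamma = sigma_gamma, base_abundance = base_abundance,
    species = species, group_traj = group_traj, species_traj = species_traj,
    p_never_detected = p_never_detected,
    exclude_undetected = isTRUE(exclude_undetected),
    seed = as.integer(seed)), class = "sim_config")
  for (ts in c(cfg$group_traj, cfg$species_traj)) check_knots(ts, n_years)
  cfg
}

check_knots <- function(ts, n_years) {
  ky <- ts$knot_years
  if (length(ky) && (any(ky < 2) || any(ky > n_years - 1)))
    stop("knot years must lie strictly inside the series, in [2, T - 1]")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$grid_rows, "x", x$grid_cols, " grid, T = ",
      x$n_years, " (", x$start_year, "-", x$start_year + x$n_years - 1,
      "), ", x$n_routes, " routes/stratum, ", nrow(x$species),
      " species, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
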