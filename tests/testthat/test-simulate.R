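test_that("true log-trajectories are piecewise linear with breaks only at knots", {
  g <- build_stratum_graph(2, 2)
  set.seed(42)
  for (rep in 1:5) {
    ky <- sort(sample(2:39, 2))
    ki <- stats::rnorm(2, 0, 0.05)
    cfg <- sim_config(grid_rows = 2, grid_cols = 2,
                      group_traj = list(FC = traj_spec(0.02, ky, ki),
                                        SSN = traj_spec(0)),
                      seed = rep)
    tr <- simulate_trajectories(cfg, g)
    f <- tr$group_log_traj$FC
    d2 <- diff(diff(f))
    # second difference at position j corresponds to year j + 1
    breaks <- which(abs(d2) > 1e-12) + 1
    expect_equal(sort(breaks), ky)
    expect_equal(unname(d2[ky - 1]), unname(ki))
  }
})

test_that("spline evaluation matches hand-computed values", {
  expect_equal(evaluate_spline(1:5, 0), rep(0, 5))
  # base slope 0.02, one knot at 20 with increment -0.06, t = 41
  expect_equal(evaluate_spline(41, c(0.02, -0.06), 20),
               0.02 * 41 - 0.06 * 21)
  # continuity at the knot: (t - theta) term is zero when t = theta
  expect_equal(evaluate_spline(20, c(0.02, -0.06), 20), 0.02 * 20)
  f <- evaluate_spline(seq(19, 21, by = 0.01), c(0.02, -0.06), 20)
  expect_lt(max(abs(diff(f))), 0.01)   # no jump in value
})

test_that("spatial year effects are centred, zero in the variance-zero limit", {
  g <- build_stratum_graph(3, 3)
  cfg <- sim_config(sigma_gamma = 0.2, seed = 5)
  tr <- simulate_trajectories(cfg, g)
  expect_equal(unname(colSums(tr$gamma_true)), rep(0, cfg$n_years))
  cfg0 <- sim_config(sigma_gamma = 0, seed = 5)
  tr0 <- simulate_trajectories(cfg0, g)
  expect_true(all(tr0$gamma_true == 0))
})

test_that("count generation has the configured Poisson moments", {
  g <- build_stratum_graph(2, 2)
  # all effects off, baseline 10: mean of >= 1e4 counts within 3 SE of 10
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_years = 41,
                    n_routes = 65, zeta = 0, sigma_omega = 0,
                    sigma_eps = 0, sigma_gamma = 0, base_abundance = 10,
                    group_traj = list(FC = traj_spec(0), SSN = traj_spec(0)),
                    p_never_detected = 0, seed = 8)
  tr <- simulate_trajectories(cfg, g)
  cnt <- simulate_counts(tr, cfg, g, species = "FC1", seed = 9)
  expect_gte(nrow(cnt), 1e4)
  se <- sqrt(10 / nrow(cnt))
  expect_lt(abs(mean(cnt$count) - 10), 3 * se)
  # pure Poisson: per-(stratum, year) variance tracks the mean
  per <- tapply(cnt$count, interaction(cnt$stratum, cnt$year),
                function(x) c(mean(x), stats::var(x)))
  per <- do.call(rbind, per)
  expect_lt(abs(mean(per[, 2] / per[, 1]) - 1), 0.15)
})

test_that("first-year observer effect scales first-year counts", {
  g <- build_stratum_graph(2, 2)
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_years = 41,
                    n_routes = 60, mean_tenure = 3, zeta = -0.5,
                    sigma_omega = 0, sigma_eps = 0, sigma_gamma = 0,
                    base_abundance = 20,
                    group_traj = list(FC = traj_spec(0), SSN = traj_spec(0)),
                    p_never_detected = 0, seed = 13)
  tr <- simulate_trajectories(cfg, g)
  cnt <- simulate_counts(tr, cfg, g, species = "FC1", seed = 14)
  ratio <- mean(cnt$count[cnt$first_year == 1]) /
    mean(cnt$count[cnt$first_year == 0])
  expect_lt(abs(ratio - exp(-0.5)), 0.05)
})

test_that("first_year flags exactly the first surveyed year of each pair", {
  g <- build_stratum_graph(1, 2)
  cfg <- sim_config(grid_rows = 1, grid_cols = 2, n_years = 15,
                    n_routes = 4, mean_tenure = 4, p_never_detected = 0,
                    group_traj = list(FC = traj_spec(0), SSN = traj_spec(0)),
                    seed = 21)
  tr <- simulate_trajectories(cfg, g)
  cnt <- simulate_counts(tr, cfg, g, seed = 22)
  per_pair <- split(cnt, interaction(cnt$route, cnt$observer, drop = TRUE))
  for (d in per_pair) {
    expect_equal(sum(d$first_year), 1)
    expect_equal(d$year[d$first_year == 1], min(d$year))
  }
})

test_that("identical seeds give byte-identical datasets", {
  g <- build_stratum_graph(2, 2)
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_years = 10,
                    n_routes = 3,
                    group_traj = list(FC = traj_spec(0), SSN = traj_spec(0)),
                    seed = 77)
  tr1 <- simulate_trajectories(cfg, g)
  tr2 <- simulate_trajectories(cfg, g)
  expect_identical(tr1, tr2)
  c1 <- simulate_counts(tr1, cfg, g, seed = 77)
  c2 <- simulate_counts(tr2, cfg, g, seed = 77)
  expect_identical(c1, c2)
  f1 <- tempfile(); f2 <- tempfile()
  write_counts(c1, f1); write_counts(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("count files round-trip losslessly and reject malformed input", {
  g <- build_stratum_graph(1, 1)
  cfg <- sim_config(grid_rows = 1, grid_cols = 1, n_years = 5,
                    n_routes = 1, seed = 3,
                    species = data.frame(species = "SP1", group = "FC"),
                    group_traj = list(FC = traj_spec(0.01)))
  tr <- simulate_trajectories(cfg, g)
  cnt <- simulate_counts(tr, cfg, g, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_counts(cnt, f)
  back <- read_counts(f)
  expect_equal(as.data.frame(back), as.data.frame(cnt))
  expect_equal(attr(back, "species"), attr(cnt, "species"))
  expect_equal(attr(back, "seed"), attr(cnt, "seed"))

  # missing observer column named in the error
  d <- utils::read.csv(f, comment.char = "#")
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(d[setdiff(names(d), "observer")], f2, row.names = FALSE)
  expect_error(read_counts(f2), "observer")

  # fractional counts rejected
  d$count[2] <- 3.5
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(d, f3, row.names = FALSE)
  expect_error(read_counts(f3), "non-negative integers")
})

test_that("off-range routes are all-zero and can be excluded", {
  g <- build_stratum_graph(2, 2)
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_years = 10,
                    n_routes = 12, p_never_detected = 0.5,
                    base_abundance = 20,
                    group_traj = list(FC = traj_spec(0), SSN = traj_spec(0)),
                    seed = 31)
  tr <- simulate_trajectories(cfg, g)
  cnt <- simulate_counts(tr, cfg, g, seed = 31)
  zero_routes <- tapply(cnt$count, cnt$route, function(x) all(x == 0))
  expect_gt(sum(zero_routes), 0)
  cfg$exclude_undetected <- TRUE
  cnt2 <- simulate_counts(tr, cfg, g, seed = 31)
  expect_true(all(tapply(cnt2$count, cnt2$route, function(x) any(x > 0))))
})
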