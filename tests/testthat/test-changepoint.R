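test_that("centred inputs are zero at the mid-year with variances carried", {
  idx <- annual_index_set(data.frame(
    species = "SP1", stratum = "A", year = 2001:2005,
    index = 5, log_index_mean = log(5), log_index_var = 0.01, pi = 1))
  groups <- data.frame(species = "SP1", group = "FC")
  cen <- prepare_inputs(idx, groups)
  expect_equal(cen$z, rep(0, 5))         # constant index centres to zero
  expect_equal(cen$var, rep(0.01, 5))

  # index doubling from mid-year to final year -> z_T = log 2
  idx2 <- idx
  idx2$index <- c(5, 5, 5, 7, 10)
  cen2 <- prepare_inputs(annual_index_set(idx2), groups)
  expect_equal(cen2$z[3], 0)
  expect_equal(cen2$z[5], log(2))

  # 41-year series centres on the 21st year
  idx3 <- annual_index_set(data.frame(
    species = "SP1", stratum = "A", year = 1970:2010,
    index = exp(seq(0, 2, length.out = 41)), log_index_mean = 0,
    log_index_var = 0.01, pi = 1))
  cen3 <- prepare_inputs(idx3, groups)
  expect_equal(cen3$z[21], 0)
  expect_equal(which(cen3$z == 0), 21L)

  idx_bad <- idx; idx_bad$index[2] <- 0
  expect_error(prepare_inputs(idx_bad, groups), "positive")
  expect_error(prepare_inputs(idx, data.frame(species = "X", group = "FC")),
               "group label")
})

test_that("per-year prior probability and odds ratios match their definitions", {
  expect_equal(round(prior_changepoint_probability(2, 0.5, 41), 3), 0.024)
  expect_equal(prior_changepoint_probability(4, 0.5, 41), 2 / 41)
  expect_equal(prior_changepoint_probability(0, 0.5, 41), 0)
  expect_error(prior_changepoint_probability(2, 0.5, 0), "candidate")

  expect_equal(odds_ratio(0.024, 0.024), 1)
  expect_equal(round(odds_ratio(0.0687, 0.024), 2), 3)
  p1 <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(odds_ratio(p1, 0.024)) > 0))
  expect_equal(odds_ratio(1, 0.024), Inf)
})

test_that("model means add each species' own group trajectory only", {
  groups <- data.frame(species = c("F1", "N1"), group = c("FC", "SSN"))
  states <- list(
    F1 = list(beta = c(0.01, 0.1), theta = 5),
    N1 = list(beta = 0.02, theta = integer(0)),
    FC = list(beta = c(0, -0.2), theta = 8),
    SSN = list(beta = 0.03, theta = integer(0)),
    AllAI = list(beta = 0.05, theta = integer(0)))
  tt <- 1:15; tm <- 8
  sp_only <- cp_model_spec("M_s", groups, 15)
  f1 <- evaluate_spline(tt, c(0.01, 0.1), 5) -
    evaluate_spline(tm, c(0.01, 0.1), 5)
  expect_equal(model_mean(sp_only, states, "F1", tt), f1)

  both <- cp_model_spec("M_FC_SSN", groups, 15)
  fc <- evaluate_spline(tt, c(0, -0.2), 8) -
    evaluate_spline(tm, c(0, -0.2), 8)
  expect_equal(model_mean(both, states, "F1", tt), f1 + fc)  # no SSN term
  ssn <- evaluate_spline(tt, 0.03) - evaluate_spline(tm, 0.03)
  n1 <- evaluate_spline(tt, 0.02) - evaluate_spline(tm, 0.02)
  expect_equal(model_mean(both, states, "N1", tt), n1 + ssn)

  zero <- list(F1 = list(beta = 0, theta = integer(0)),
               FC = list(beta = 0, theta = integer(0)))
  expect_equal(model_mean(cp_model_spec("M_FC", groups, 15), zero, "F1", tt),
               rep(0, 15))
})

test_that("the marginalised likelihood is a plain Gaussian sum", {
  groups <- data.frame(species = "F1", group = "FC")
  spec <- cp_model_spec("M_s", groups, 5)
  states <- list(F1 = list(beta = 0, theta = integer(0)))
  d <- structure(data.frame(species = "F1", stratum = "A", year = 1:5,
                            t = 1:5, z = 0, var = 1, group = "FC"),
                 class = c("centered_index_data", "data.frame"))
  # single datum with unit total variance and zero residual
  d1 <- d[3, ]
  expect_equal(log_likelihood(spec, states, d1, sigma_p = 0),
               -0.5 * log(2 * pi))
  # exchangeable in row order
  d$z <- stats::rnorm(5)
  expect_equal(log_likelihood(spec, states, d, 0.3),
               log_likelihood(spec, states, d[sample(5), ], 0.3))
  # matches dnorm directly
  expect_equal(log_likelihood(spec, states, d, 0.3),
               sum(stats::dnorm(d$z, 0, sqrt(1 + 0.09), log = TRUE)))
})

test_that("enumeration oracle normalises, prefers k = 0 on flat data, and is symmetric", {
  groups <- data.frame(species = "SP1", group = "FC")
  spec <- cp_model_spec("M_s", groups, 9, species_k_max = 2)
  flat <- structure(data.frame(species = "SP1", stratum = "A",
                               year = 1:9, t = 1:9, z = 0, var = 1e-4,
                               group = "FC"),
                    class = c("centered_index_data", "data.frame"))
  bf <- brute_force_posterior(flat, spec, sigma_p_fixed = 0)
  expect_equal(sum(bf$prob), 1)
  expect_equal(bf$configs[[which.max(bf$prob)]], integer(0))
  # mirror-symmetric data give per-year probabilities symmetric about mid
  sym <- flat
  sym$z <- abs(sym$t - 5) * 0.2          # V-shape centred on the mid-year
  bf2 <- brute_force_posterior(sym, spec, sigma_p_fixed = 0.01)
  expect_lt(max(abs(bf2$p_year - rev(bf2$p_year))), 1e-5)
})

test_that("rjmcmc is seed-deterministic and satisfies the counting identity", {
  inst <- oracle_instance()
  cfg <- cp_config(n_iterations = 3000, burn_in = 500, seed = 17,
                   sigma_p_fixed = 0.05)
  d1 <- rjmcmc_sample(inst$data, inst$spec, cfg)
  d2 <- rjmcmc_sample(inst$data, inst$spec, cfg)
  expect_identical(d1$trajectories, d2$trajectories)
  cp <- changepoint_probability(d1)
  # sum over years of p1 equals the mean knot count, exactly
  expect_equal(sum(cp$table$p_changepoint), unname(cp$E_k), tolerance = 1e-12)
  expect_equal(cp$table$p_negative + cp$table$p_positive,
               cp$table$p_changepoint)
})

test_that("change-point probabilities summarise constructed draws correctly", {
  years <- 1970:1979
  # every draw has a knot at t = 5 with a negative increment
  dr <- manual_cp_draws(theta = rep(list(5L), 4),
                        beta = rep(list(c(0.02, -0.06)), 4),
                        years = years)
  cp <- changepoint_probability(dr)
  row <- cp$table[cp$table$t == 5, ]
  expect_equal(row$p_changepoint, 1)
  expect_equal(row$p_negative, 1)
  expect_equal(unname(cp$E_k), 1)
  # no knots anywhere
  dr0 <- manual_cp_draws(theta = rep(list(integer(0)), 4),
                         beta = rep(list(0), 4), years = years)
  cp0 <- changepoint_probability(dr0)
  expect_true(all(cp0$table$p_changepoint == 0))
  expect_equal(unname(cp0$E_k), 0)
})

test_that("posterior mean trajectories are continuous in value", {
  inst <- shared_knot_instance()
  dr <- rjmcmc_sample(inst$data,
                      cp_model_spec("M_AllAI", inst$config$species, 41),
                      cp_config(n_iterations = 2000, burn_in = 500,
                                seed = 4))
  # reconstruct the posterior-mean group trajectory on a fine grid; a
  # piecewise-linear mixture must have bounded increments (no value jumps)
  tt <- seq(1, 41, by = 0.25)
  tr <- dr$trajectories$AllAI
  fbar <- rowMeans(vapply(seq_along(tr$theta), function(i)
    evaluate_spline(tt, tr$beta[[i]], tr$theta[[i]]),
    numeric(length(tt))))
  expect_lt(max(abs(diff(fbar))), 0.25 * 0.5)
})
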