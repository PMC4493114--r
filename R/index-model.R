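#' Stratum offsets for the index model
#'
#' The offset `s_i` is the log of the observed average count across all
#' routes and years in stratum `i`.  It is data, not an estimated
#' parameter: with it in place the year effects model annual variation
#' separately from among-stratum differences in abundance.  Strata in which
#' the species was never counted have no finite offset and are flagged
#' excluded.
#'
#' @param counts a `count_dataset`.
#' @return Named numeric vector of offsets for the retained strata, with
#'   attribute `excluded` listing all-zero strata.
#' @export
compute_offsets <- function(counts) {
  if (nrow(counts) == 0) stop("empty count dataset")
  m <- tapply(counts$count, counts$stratum, mean)
  excluded <- names(m)[m == 0]
  s <- stats::setNames(as.numeric(log(m[m > 0])), names(m)[m > 0])
  attr(s, "excluded") <- excluded
  s
}

#' Detection proportion per stratum
#'
#' The proportion `pi_i` of routes in a stratum on which the species was
#' observed at least once (in any year, by any observer).  Routes are
#' counted once regardless of how many observers surveyed them.
#'
#' @param counts a `count_dataset`.
#' @return Named numeric vector of proportions per stratum.
#' @export
detection_proportion <- function(counts) {
  seen <- tapply(counts$count, counts$route, function(x) any(x > 0))
  stratum_of <- tapply(counts$stratum, counts$route, function(x) x[1])
  n_routes <- table(stratum_of)
  n_seen <- tapply(as.numeric(seen), stratum_of, sum)
  out <- as.numeric(n_seen) / as.numeric(n_routes)
  stats::setNames(out, names(n_routes))
}

#' Intrinsic-CAR full conditional
#'
#' Under the first-order intrinsic CAR structure, the year effect of a
#' stratum, given its neighbours, is Normal with mean the arithmetic mean of
#' the neighbouring values and precision proportional to the neighbour
#' count: sd = `sigma_t / sqrt(N)`.
#'
#' @param values_of_neighbours numeric vector of neighbouring year effects.
#' @param sigma_t the year's CAR scale parameter (> 0).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
car_conditional <- function(values_of_neighbours, sigma_t) {
  N <- length(values_of_neighbours)
  if (N < 1) stop("empty neighbour set: resolve isolated strata first")
  if (sigma_t <= 0) stop("'sigma_t' must be positive")
  c(mean = mean(values_of_neighbours), sd = sigma_t / sqrt(N))
}

#' Configuration for the annual-index sampler
#'
#' Priors follow the standard diffuse choices: inverse gamma (shape and
#' scale 0.001) on all variances, Normal(0, 1e6) on the first-year effect
#' `zeta`, and a flat prior on the year means `mu_t` implemented as
#' Normal(0, 1e6) for numerical propriety.
#'
#' @param n_iterations total MCMC iterations per chain.
#' @param burn_in iterations discarded (and during which proposal scales
#'   adapt; adaptation is frozen afterwards).
#' @param thinning keep every `thinning`-th retained draw.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param ig_shape,ig_scale inverse-gamma prior parameters for variances.
#' @param zeta_var,mu_var prior variances for `zeta` and `mu_t`.
#' @param seed integer master seed; chain `c` uses `seed + c - 1`.
#' @return A list of class `index_model_config`.
#' @export
index_model_config <- function(n_iterations = 4000, burn_in = 1000,
                               thinning = 2, n_chains = 2,
                               ig_shape = 0.001, ig_scale = 0.001,
                               zeta_var = 1e6, mu_var = 1e6, seed = 1L) {
  if (burn_in >= n_iterations) stop("'burn_in' must be below 'n_iterations'")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains),
                 ig_shape = ig_shape, ig_scale = ig_scale,
                 zeta_var = zeta_var, mu_var = mu_var,
                 seed = as.integer(seed)),
            class = "index_model_config")
}

#' Fit the spatial CAR annual-index model
#'
#' Metropolis-within-Gibbs sampler for the overdispersed Poisson count model
#' with observer effects and intrinsic-CAR spatial year effects.  Counts are
#' Poisson with
#' `log(lambda) = s_i + mu_t + gamma_{i,t} + omega_{i,j} + zeta I(j,t) +
#' eps_{i,j,t}`; the `gamma_{.,t}` carry an intrinsic CAR prior with per-year
#' scale `sigma_t` and are re-centred to sum to zero within each year at
#' every iteration (the subtracted mean is absorbed into `mu_t`), the
#' standard way of handling the intrinsic CAR's impropriety.  Variances have
#' conjugate inverse-gamma updates; Poisson-likelihood blocks use adaptive
#' random-walk Metropolis, with adaptation frozen after burn-in.
#'
#' All-zero strata are excluded (no finite offset).  Strata isolated by the
#' exclusion are reconnected through [resolve_isolated_strata()].
#'
#' @param counts a `count_dataset`.
#' @param graph a [stratum_graph()] covering the count strata.
#' @param config an [index_model_config()].
#' @return An object of class `index_posterior`: retained draws of `mu`
#'   (draws x T), `gamma` (draws x strata*T), `omega`, `zeta`, `sigma_t`,
#'   `sigma_omega`, `sigma_eps`, posterior mean/sd of the overdispersion
#'   effects, offsets, convergence diagnostics, and bookkeeping.  A warning
#'   is issued if any monitored split R-hat exceeds 1.1.
#' @export
fit_index_model <- function(counts, graph, config = index_model_config()) {
  s <- compute_offsets(counts)
  excl <- attr(s, "excluded")
  if (length(excl)) {
    counts <- counts[!(counts$stratum %in% excl), , drop = FALSE]
    message("excluding all-zero strata: ", paste(excl, collapse = ", "))
  }
  strata <- names(s)
  if (!all(strata %in% graph$strata))
    stop("graph does not cover all count strata")
  g <- resolve_isolated_strata(graph, strata)
  strata <- g$strata
  s <- s[strata]
  years <- sort(unique(counts$year))
  T <- length(years); S <- length(strata)
  n <- nrow(counts)
  si <- match(counts$stratum, strata)
  ti <- match(counts$year, years)
  pair <- interaction(counts$route, counts$observer, drop = TRUE)
  oi <- as.integer(pair)
  J <- nlevels(pair)
  fy <- counts$first_year == 1
  cc <- counts$count
  nb_idx <- lapply(g$neighbours, function(v) match(v, strata))
  Ni <- lengths(nb_idx)
  edges <- do.call(rbind, lapply(seq_len(S), function(i) {
    j <- nb_idx[[i]]; j <- j[j > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  rows_by_stratum <- split(seq_len(n), si)
  chains <- lapply(seq_len(config$n_chains), function(ch)
    run_index_chain(ch, config, cc, si, ti, oi, fy, s, n, S, T, J,
                    nb_idx, Ni, edges, rows_by_stratum))
  draws <- list()
  for (nm in c("mu", "gamma", "omega", "sigma_t"))
    draws[[nm]] <- do.call(rbind, lapply(chains, `[[`, nm))
  for (nm in c("zeta", "sigma_omega", "sigma_eps"))
    draws[[nm]] <- unlist(lapply(chains, `[[`, nm))
  colnames(draws$mu) <- paste0("mu[", years, "]")
  colnames(draws$gamma) <- paste0("gamma[", rep(strata, T), ",",
                                  rep(years, each = S), "]")
  n_per_chain <- nrow(chains[[1]]$mu)
  chain_id <- rep(seq_along(chains), each = n_per_chain)
  eps_mean <- Reduce(`+`, lapply(chains, `[[`, "eps_sum")) /
    (length(chains) * n_per_chain)
  eps_m2 <- Reduce(`+`, lapply(chains, `[[`, "eps_sumsq")) /
    (length(chains) * n_per_chain)
  eps_sd <- sqrt(pmax(eps_m2 - eps_mean^2, 0))
  mon <- cbind(zeta = draws$zeta, sigma_omega = draws$sigma_omega,
               sigma_eps = draws$sigma_eps, draws$mu, draws$gamma)
  diag_tab <- mcmc_diagnostics(mon, chain_id)
  if (any(!diag_tab$pass))
    warning("possible non-convergence: split R-hat > 1.1 for ",
            sum(!diag_tab$pass), " monitored parameter(s)")
  structure(list(draws = draws, eps_mean = eps_mean, eps_sd = eps_sd,
                 offsets = s, strata = strata, years = years,
                 species = attr(counts, "species"), chain_id = chain_id,
                 diagnostics = diag_tab, config = config, graph = g),
            class = "index_posterior")
}

#' @export
print.index_posterior <- function(x, ...) {
  cat("Annual-index posterior: ", length(x$strata), " strata x ",
      length(x$years), " years, ", length(x$draws$zeta), " retained draws (",
      max(x$chain_id), " chains)\n", sep = "")
  cat("  zeta: mean ", signif(mean(x$draws$zeta), 3),
      ", 95% CrI [", paste(signif(stats::quantile(
        x$draws$zeta, c(0.025, 0.975)), 3), collapse = ", "), "]\n",
      sep = "")
  cat("  max split R-hat: ", signif(max(x$diagnostics$rhat, na.rm = TRUE),
                                    4), "\n", sep = "")
  invisible(x)
}

# One MCMC chain of the index model.  Dense bookkeeping; all Poisson
# likelihood evaluations are vectorised over records with rowsum() used for
# grouped acceptance sums.
run_index_chain <- function(chain, config, cc, si, ti, oi, fy, s, n, S, T, J,
                            nb_idx, Ni, edges, rows_by_stratum) {
  set.seed(config$seed + chain - 1L)
  mu <- numeric(T); gamma <- matrix(0, S, T); omega <- numeric(J)
  zeta <- 0; eps <- numeric(n)
  sigma_t <- rep(0.1, T); sigma_omega <- 0.1; sigma_eps <- 0.1
  cell <- (ti - 1L) * S + si             # index into gamma matrix
  loglam <- s[si] + mu[ti] + gamma[cell] + omega[oi] + zeta * fy + eps
  lam <- exp(loglam)
  step_eps <- 0.5; step_om <- 0.3; step_z <- 0.1; step_mu <- 0.1
  step_g <- rep(0.2, S)
  acc <- c(eps = 0, om = 0, z = 0, mu = 0); accg <- numeric(S)
  n_kept <- (config$n_iterations - config$burn_in) %/% config$thinning
  out <- list(mu = matrix(NA_real_, n_kept, T),
              gamma = matrix(NA_real_, n_kept, S * T),
              omega = matrix(NA_real_, n_kept, J),
              sigma_t = matrix(NA_real_, n_kept, T),
              zeta = numeric(n_kept), sigma_omega = numeric(n_kept),
              sigma_eps = numeric(n_kept),
              eps_sum = numeric(n), eps_sumsq = numeric(n))
  kept <- 0L
  a_ig <- config$ig_shape; b_ig <- config$ig_scale
  fy_rows <- which(fy)
  for (iter in seq_len(config$n_iterations)) {
    ## overdispersion effects, record-wise MH
    d <- stats::rnorm(n, 0, step_eps)
    lam2 <- lam * exp(d)
    logr <- cc * d - (lam2 - lam) -
      ((eps + d)^2 - eps^2) / (2 * sigma_eps^2)
    ok <- log(stats::runif(n)) < logr
    eps[ok] <- eps[ok] + d[ok]
    loglam[ok] <- loglam[ok] + d[ok]; lam[ok] <- lam2[ok]
    acc["eps"] <- acc["eps"] + mean(ok)
    ## observer-route effects, pair-wise MH
    d <- stats::rnorm(J, 0, step_om)
    dr <- d[oi]
    dll <- rowsum(cc * dr - lam * (exp(dr) - 1), oi, reorder = TRUE)[, 1]
    logr <- dll - ((omega + d)^2 - omega^2) / (2 * sigma_omega^2)
    okj <- log(stats::runif(J)) < logr
    omega[okj] <- omega[okj] + d[okj]
    okr <- okj[oi]
    loglam[okr] <- loglam[okr] + dr[okr]; lam[okr] <- lam[okr] * exp(dr[okr])
    acc["om"] <- acc["om"] + mean(okj)
    ## first-year observer effect
    if (length(fy_rows)) {
      d1 <- stats::rnorm(1, 0, step_z)
      dll <- sum(cc[fy_rows] * d1 - lam[fy_rows] * (exp(d1) - 1))
      logr <- dll - ((zeta + d1)^2 - zeta^2) / (2 * config$zeta_var)
      if (log(stats::runif(1)) < logr) {
        zeta <- zeta + d1
        loglam[fy_rows] <- loglam[fy_rows] + d1
        lam[fy_rows] <- lam[fy_rows] * exp(d1)
        acc["z"] <- acc["z"] + 1
      }
    }
    ## year means
    d <- stats::rnorm(T, 0, step_mu)
    dr <- d[ti]
    dll <- rowsum(cc * dr - lam * (exp(dr) - 1), ti, reorder = TRUE)[, 1]
    logr <- dll - ((mu + d)^2 - mu^2) / (2 * config$mu_var)
    okt <- log(stats::runif(T)) < logr
    mu[okt] <- mu[okt] + d[okt]
    okr <- okt[ti]
    loglam[okr] <- loglam[okr] + dr[okr]; lam[okr] <- lam[okr] * exp(dr[okr])
    acc["mu"] <- acc["mu"] + mean(okt)
    ## spatial year effects, stratum by stratum (CAR full conditional prior)
    if (S > 1) {
      for (i in seq_len(S)) {
        rows <- rows_by_stratum[[i]]
        d <- stats::rnorm(T, 0, step_g[i])
        dr <- d[ti[rows]]
        dll_part <- rowsum(cc[rows] * dr - lam[rows] * (exp(dr) - 1),
                           ti[rows], reorder = TRUE)
        dll <- numeric(T)
        dll[as.integer(rownames(dll_part))] <- dll_part[, 1]
        m_nb <- colMeans(gamma[nb_idx[[i]], , drop = FALSE])
        g_old <- gamma[i, ]; g_new <- g_old + d
        logr <- dll - Ni[i] * ((g_new - m_nb)^2 - (g_old - m_nb)^2) /
          (2 * sigma_t^2)
        okt <- log(stats::runif(T)) < logr
        gamma[i, okt] <- g_new[okt]
        okr <- okt[ti[rows]]
        rws <- rows[okr]
        loglam[rws] <- loglam[rws] + dr[okr]
        lam[rws] <- lam[rws] * exp(dr[okr])
        accg[i] <- accg[i] + mean(okt)
      }
      ## re-centre gamma within each year, absorbing the mean into mu
      m_t <- colMeans(gamma)
      gamma <- gamma - rep(m_t, each = S)
      gamma[S, ] <- -colSums(gamma[-S, , drop = FALSE])  # exact zero sum
      mu <- mu + m_t
      ## per-year CAR scale, conjugate given the pairwise differences
      ss <- colSums((gamma[edges[, 1], , drop = FALSE] -
                       gamma[edges[, 2], , drop = FALSE])^2)
      tau <- stats::rgamma(T, a_ig + (S - 1) / 2, rate = b_ig + ss / 2)
      sigma_t <- 1 / sqrt(tau)
    }
    ## variance components, conjugate
    sigma_omega <- 1 / sqrt(stats::rgamma(
      1, a_ig + J / 2, rate = b_ig + sum(omega^2) / 2))
    sigma_eps <- 1 / sqrt(stats::rgamma(
      1, a_ig + n / 2, rate = b_ig + sum(eps^2) / 2))
    ## proposal adaptation during burn-in
    if (iter %% 50 == 0 && iter <= config$burn_in) {
      tune <- function(step, rate) {
        pmin(pmax(step * exp(rate / 50 - 0.44), 1e-3), 5)
      }
      step_eps <- tune(step_eps, acc["eps"]); step_om <- tune(step_om, acc["om"])
      step_z <- tune(step_z, acc["z"]); step_mu <- tune(step_mu, acc["mu"])
      step_g <- tune(step_g, accg)
      acc[] <- 0; accg[] <- 0
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thinning == 0) {
      kept <- kept + 1L
      out$mu[kept, ] <- mu
      out$gamma[kept, ] <- gamma          # column-major: stratum fastest
      out$omega[kept, ] <- omega
      out$sigma_t[kept, ] <- sigma_t
      out$zeta[kept] <- zeta
      out$sigma_omega[kept] <- sigma_omega
      out$sigma_eps[kept] <- sigma_eps
      out$eps_sum <- out$eps_sum + eps
      out$eps_sumsq <- out$eps_sumsq + eps^2
    }
  }
  out
}
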