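#' Reversible-jump MCMC for the piecewise-linear change-point model
#'
#' Samples the joint posterior of every trajectory's knot count, knot years,
#' and slope parameters, together with the process SD `sigma_p`, for one
#' stratum.  Centred log indices are Normal around the summed trajectory
#' means with known variance plus `sigma_p^2` (the latent true abundances
#' are marginalised analytically, which leaves the same posterior with
#' better mixing).
#'
#' Each iteration applies, per trajectory, one dimension-changing move —
#' birth (insert a knot at a uniformly chosen unoccupied candidate year),
#' death (remove a uniformly chosen knot), or relocation of a knot to a
#' uniformly chosen free year — followed by, per group trajectory, a swap
#' move that exchanges a knot held simultaneously by every member species
#' for a single group knot at the same year (or the reverse), then a joint
#' conjugate Gibbs draw of all slope parameters and a random-walk update of
#' `sigma_p` on the log scale.  All proposed slope increments are drawn
#' from their full conditional (Gaussian) posteriors, with the proposal
#' density entering the acceptance ratio, so dimension changes remain
#' efficient even when the data are highly informative; the swap move is
#' what lets a change shared across species migrate into the group
#' trajectory it belongs to.  Knot-count priors are truncated Binomial,
#' knot years uniform over subsets of the candidate years; all acceptance
#' ratios preserve detailed balance, and infeasible proposals (beyond
#' `k_max`, or death at `k = 0`) are rejected outright.
#'
#' @param data a `centered_index_data` restricted to a single stratum.
#' @param spec a [cp_model_spec()].
#' @param config a [cp_config()].
#' @return An object of class `cp_draws`: per trajectory the retained knot
#'   years and aligned slope vectors (base slope first), plus draws of
#'   `sigma_p` and the log-likelihood, the running posterior-mean fitted
#'   values, and bookkeeping (`years`, `t_mid`, candidate set, spec,
#'   config).
#' @export
rjmcmc_sample <- function(data, spec, config = cp_config()) {
  if (length(unique(data$stratum)) != 1)
    stop("'data' must contain a single stratum; fit strata separately")
  z <- data$z; vr <- data$var
  n <- length(z)
  T <- max(data$t); t_mid <- ceiling(T / 2)
  cand <- spec$candidates
  if (length(cand) < max(vapply(spec$trajectories, `[[`, 0L, "k_max")))
    stop("candidate year set smaller than the maximum knot count")
  if (all(!is.finite(vr))) stop("all observation variances missing")
  trajs <- spec$trajectories
  nt <- length(trajs)
  rows <- lapply(trajs, function(tr) which(data$species %in% tr$members))
  tvals <- lapply(rows, function(tr) data$t[tr])
  kmax <- vapply(trajs, `[[`, 0L, "k_max")
  lpk <- lapply(kmax, function(km) stats::dbinom(0:km, km, 0.5, log = TRUE))
  ncand <- length(cand)
  is_group <- vapply(trajs, function(tr) tr$type == "group", logical(1))
  members_of <- lapply(trajs, function(tr)
    which(vapply(trajs, function(x)
      x$type == "species" && x$id %in% tr$members, logical(1))))
  tau <- spec$slope_sd
  use_lik <- config$likelihood
  set.seed(config$seed)
  th <- rep(list(integer(0)), nt)        # knot years, unsorted
  be <- rep(list(0), nt)                 # base slope + parallel increments
  sigma_p <- if (is.null(config$sigma_p_fixed)) 0.05 else config$sigma_p_fixed
  v <- vr + sigma_p^2
  w <- if (use_lik) 1 / v else numeric(n)   # w = 0 turns the likelihood off
  m <- numeric(n)
  ldnorm <- function(x, mu, sd) stats::dnorm(x, mu, sd, log = TRUE)
  # conditional posterior moments of one increment with basis b on rows r,
  # given fitted values mm elsewhere (prior N(0, tau^2); with w = 0 this is
  # the prior itself)
  cond <- function(r, b, mm) {
    P <- sum(b * b * w[r]) + 1 / tau^2
    list(mu = sum(b * (z[r] - mm[r]) * w[r]) / P, sd = sqrt(1 / P))
  }
  dll_of <- function(r, mm_new) {
    -0.5 * sum(((z[r] - mm_new[r])^2 - (z[r] - m[r])^2) * w[r])
  }
  step_sp <- 0.4; acc_sp <- 0
  n_kept <- (config$n_iterations - config$burn_in) %/% config$thinning
  theta_draws <- lapply(seq_len(nt), function(i) vector("list", n_kept))
  beta_draws <- lapply(seq_len(nt), function(i) vector("list", n_kept))
  sp_draws <- numeric(n_kept); ll_draws <- numeric(n_kept)
  fit_sum <- numeric(n)
  kept <- 0L
  for (iter in seq_len(config$n_iterations)) {
    ## one reversible-jump move per trajectory
    for (j in seq_len(nt)) {
      k <- length(th[[j]])
      u <- stats::runif(1)
      r <- rows[[j]]; tv <- tvals[[j]]
      if (u < 0.35) {                    # birth
        if (k >= kmax[j]) next
        free <- cand[!(cand %in% th[[j]])]
        y <- free[sample.int(length(free), 1)]
        b <- knot_basis(tv, y, t_mid)
        cm <- cond(r, b, m)
        e <- stats::rnorm(1, cm$mu, cm$sd)
        mm <- m; mm[r] <- m[r] + e * b
        la <- dll_of(r, mm) + lpk[[j]][k + 2] - lpk[[j]][k + 1] +
          ldnorm(e, 0, tau) - ldnorm(e, cm$mu, cm$sd)
        if (log(stats::runif(1)) < la) {
          th[[j]] <- c(th[[j]], y); be[[j]] <- c(be[[j]], e)
          m <- mm
        }
      } else if (u < 0.7) {              # death
        if (k < 1) next
        i <- sample.int(k, 1)
        e <- be[[j]][i + 1]
        b <- knot_basis(tv, th[[j]][i], t_mid)
        mm <- m; mm[r] <- m[r] - e * b
        cm <- cond(r, b, mm)             # reverse-birth proposal density
        la <- dll_of(r, mm) + lpk[[j]][k] - lpk[[j]][k + 1] +
          ldnorm(e, cm$mu, cm$sd) - ldnorm(e, 0, tau)
        if (log(stats::runif(1)) < la) {
          th[[j]] <- th[[j]][-i]; be[[j]] <- be[[j]][-(i + 1)]
          m <- mm
        }
      } else {                           # relocate a knot, resampling its
        if (k < 1) next                  # increment
        free <- cand[!(cand %in% th[[j]])]
        if (!length(free)) next
        i <- sample.int(k, 1)
        y_new <- free[sample.int(length(free), 1)]
        e_old <- be[[j]][i + 1]
        b_old <- knot_basis(tv, th[[j]][i], t_mid)
        b_new <- knot_basis(tv, y_new, t_mid)
        m0 <- m; m0[r] <- m[r] - e_old * b_old
        cm_new <- cond(r, b_new, m0)
        e_new <- stats::rnorm(1, cm_new$mu, cm_new$sd)
        cm_old <- cond(r, b_old, m0)
        mm <- m0; mm[r] <- m0[r] + e_new * b_new
        la <- dll_of(r, mm) +
          ldnorm(e_new, 0, tau) - ldnorm(e_old, 0, tau) +
          ldnorm(e_old, cm_old$mu, cm_old$sd) -
          ldnorm(e_new, cm_new$mu, cm_new$sd)
        if (log(stats::runif(1)) < la) {
          th[[j]][i] <- y_new; be[[j]][i + 1] <- e_new
          m <- mm
        }
      }
    }
    ## swap moves: migrate a knot shared by all members into the group (or
    ## back out); proposal increments from their full conditionals
    for (gj in which(is_group)) {
      mems <- members_of[[gj]]
      if (!length(mems)) next
      rg <- rows[[gj]]; tg <- tvals[[gj]]
      kg <- length(th[[gj]])
      swap_sizes <- function(th_now) {
        # years eligible for species -> group and group -> species swaps
        shared <- Reduce(intersect, th_now[mems])
        to_g <- if (length(th_now[[gj]]) < kmax[gj])
          setdiff(shared, th_now[[gj]]) else integer(0)
        from_g <- th_now[[gj]][vapply(th_now[[gj]], function(y)
          all(vapply(mems, function(sj)
            !(y %in% th_now[[sj]]) && length(th_now[[sj]]) < kmax[sj],
            logical(1))), logical(1))]
        list(to_g = to_g, from_g = from_g)
      }
      el <- swap_sizes(th)
      if (stats::runif(1) < 0.5) {       # species -> group
        if (!length(el$to_g)) next
        y <- el$to_g[sample.int(length(el$to_g), 1)]
        m0 <- m
        e_sp <- numeric(0); lq_rev <- 0; lpri <- 0
        for (sj in mems) {
          i <- which(th[[sj]] == y)
          e <- be[[sj]][i + 1]
          bsj <- knot_basis(tvals[[sj]], y, t_mid)
          m0[rows[[sj]]] <- m0[rows[[sj]]] - e * bsj
          e_sp <- c(e_sp, e)
          ksj <- length(th[[sj]])
          lpri <- lpri + lpk[[sj]][ksj] - lpk[[sj]][ksj + 1] +
            lchoose(ncand, ksj) - lchoose(ncand, ksj - 1) -
            ldnorm(e, 0, tau)
        }
        for (ix in seq_along(mems)) {    # reverse proposal densities at m0
          sj <- mems[ix]
          bsj <- knot_basis(tvals[[sj]], y, t_mid)
          cm <- cond(rows[[sj]], bsj, m0)
          lq_rev <- lq_rev + ldnorm(e_sp[ix], cm$mu, cm$sd)
        }
        bg <- knot_basis(tg, y, t_mid)
        cmE <- cond(rg, bg, m0)
        E <- stats::rnorm(1, cmE$mu, cmE$sd)
        mm <- m0; mm[rg] <- m0[rg] + E * bg
        lpri <- lpri + lpk[[gj]][kg + 2] - lpk[[gj]][kg + 1] +
          lchoose(ncand, kg) - lchoose(ncand, kg + 1) + ldnorm(E, 0, tau)
        th_new <- th
        th_new[[gj]] <- c(th_new[[gj]], y)
        for (sj in mems) th_new[[sj]] <- setdiff(th_new[[sj]], y)
        el_new <- swap_sizes(th_new)
        la <- dll_of(rg, mm) + lpri +
          log(length(el$to_g)) - log(length(el_new$from_g)) +
          lq_rev - ldnorm(E, cmE$mu, cmE$sd)
        if (is.finite(la) && log(stats::runif(1)) < la) {
          for (sj in mems) {
            i <- which(th[[sj]] == y)
            th[[sj]] <- th[[sj]][-i]; be[[sj]] <- be[[sj]][-(i + 1)]
          }
          th[[gj]] <- c(th[[gj]], y); be[[gj]] <- c(be[[gj]], E)
          m <- mm
        }
      } else {                           # group -> species
        if (!length(el$from_g)) next
        y <- el$from_g[sample.int(length(el$from_g), 1)]
        i <- which(th[[gj]] == y)
        E <- be[[gj]][i + 1]
        bg <- knot_basis(tg, y, t_mid)
        m0 <- m; m0[rg] <- m[rg] - E * bg
        cmE <- cond(rg, bg, m0)
        lpri <- lpk[[gj]][kg] - lpk[[gj]][kg + 1] +
          lchoose(ncand, kg) - lchoose(ncand, kg - 1) - ldnorm(E, 0, tau)
        mm <- m0
        e_sp <- numeric(length(mems)); lq_fwd <- 0
        for (ix in seq_along(mems)) {
          sj <- mems[ix]
          bsj <- knot_basis(tvals[[sj]], y, t_mid)
          cm <- cond(rows[[sj]], bsj, m0)
          e <- stats::rnorm(1, cm$mu, cm$sd)
          e_sp[ix] <- e
          lq_fwd <- lq_fwd + ldnorm(e, cm$mu, cm$sd)
          mm[rows[[sj]]] <- mm[rows[[sj]]] + e * bsj
          ksj <- length(th[[sj]])
          lpri <- lpri + lpk[[sj]][ksj + 2] - lpk[[sj]][ksj + 1] +
            lchoose(ncand, ksj) - lchoose(ncand, ksj + 1) +
            ldnorm(e, 0, tau)
        }
        th_new <- th
        th_new[[gj]] <- setdiff(th_new[[gj]], y)
        for (sj in mems) th_new[[sj]] <- c(th_new[[sj]], y)
        el_new <- swap_sizes(th_new)
        la <- dll_of(rg, mm) + lpri +
          log(length(el$from_g)) - log(length(el_new$to_g)) +
          ldnorm(E, cmE$mu, cmE$sd) - lq_fwd
        if (is.finite(la) && log(stats::runif(1)) < la) {
          th[[gj]] <- th[[gj]][-i]; be[[gj]] <- be[[gj]][-(i + 1)]
          for (ix in seq_along(mems)) {
            sj <- mems[ix]
            th[[sj]] <- c(th[[sj]], y); be[[sj]] <- c(be[[sj]], e_sp[ix])
          }
          m <- mm
        }
      }
    }
    ## joint conjugate Gibbs draw of all slope parameters
    p <- sum(lengths(th)) + nt
    X <- matrix(0, n, p)
    col <- 0L
    for (j in seq_len(nt)) {
      col <- col + 1L
      X[rows[[j]], col] <- tvals[[j]] - t_mid
      for (i in seq_along(th[[j]])) {
        col <- col + 1L
        X[rows[[j]], col] <- knot_basis(tvals[[j]], th[[j]][i], t_mid)
      }
    }
    if (use_lik) {
      Xs <- X * sqrt(w)
      A <- crossprod(Xs) + diag(1 / tau^2, p)
      U <- chol(A)
      bvec <- crossprod(X, w * z)
      mpost <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
      beta_all <- mpost + backsolve(U, stats::rnorm(p))
    } else {
      beta_all <- stats::rnorm(p, 0, tau)
    }
    col <- 0L
    for (j in seq_len(nt)) {
      kj <- length(th[[j]])
      be[[j]] <- beta_all[col + seq_len(kj + 1)]
      col <- col + kj + 1L
    }
    m <- as.vector(X %*% beta_all)
    ## process SD
    if (is.null(config$sigma_p_fixed) && use_lik) {
      lsp2 <- log(sigma_p) + stats::rnorm(1, 0, step_sp)
      sp2 <- exp(lsp2)
      v2 <- vr + sp2^2
      lp <- function(sig, vv) {
        sum(stats::dnorm(z, m, sqrt(vv), log = TRUE)) -
          2 * config$ig_shape * log(sig) - config$ig_scale / sig^2
      }
      if (log(stats::runif(1)) < lp(sp2, v2) - lp(sigma_p, v)) {
        sigma_p <- sp2; v <- v2; w <- 1 / v
        acc_sp <- acc_sp + 1
      }
      if (iter %% 50 == 0 && iter <= config$burn_in) {
        step_sp <- min(max(step_sp * exp(acc_sp / 50 - 0.44), 1e-3), 5)
        acc_sp <- 0
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thinning == 0) {
      kept <- kept + 1L
      for (j in seq_len(nt)) {
        ord <- order(th[[j]])
        theta_draws[[j]][[kept]] <- th[[j]][ord]
        beta_draws[[j]][[kept]] <- c(be[[j]][1], be[[j]][1 + ord])
      }
      sp_draws[kept] <- sigma_p
      ll_draws[kept] <- if (use_lik)
        sum(stats::dnorm(z, m, sqrt(v), log = TRUE)) else 0
      fit_sum <- fit_sum + m
    }
  }
  traj_out <- lapply(seq_len(nt), function(j)
    list(id = trajs[[j]]$id, type = trajs[[j]]$type,
         members = trajs[[j]]$members, k_max = kmax[j],
         theta = theta_draws[[j]], beta = beta_draws[[j]]))
  names(traj_out) <- names(trajs)
  structure(list(trajectories = traj_out, sigma_p = sp_draws,
                 loglik = ll_draws, mean_fit = fit_sum / max(kept, 1),
                 n_draws = kept, data = data, spec = spec, config = config,
                 t_mid = t_mid, candidates = cand,
                 years = sort(unique(data$year))),
            class = "cp_draws")
}

#' @export
print.cp_draws <- function(x, ...) {
  ek <- vapply(x$trajectories, function(tr)
    mean(lengths(tr$theta)), numeric(1))
  cat("Change-point draws (", x$spec$name, "): ", x$n_draws,
      " retained draws, ", length(x$trajectories), " trajectories\n",
      sep = "")
  cat("  E[k | data]: ",
      paste(sprintf("%s=%.2f", names(ek), ek), collapse = ", "), "\n",
      sep = "")
  cat("  sigma_p: posterior mean ", signif(mean(x$sigma_p), 3), "\n",
      sep = "")
  invisible(x)
}
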