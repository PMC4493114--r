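#' Per-year change-point probabilities
#'
#' The posterior probability of a change point in year `t` is the fraction
#' of retained draws whose state contains a knot at that year (equivalently,
#' the summed posterior probability of all models with a change point
#' there).  Probabilities are split by the sign of the slope increment into
#' negative (downturn) and positive (upturn) parts, and compared with the
#' per-year prior probability through the posterior-to-prior
#' [odds_ratio()].  Because knots are distinct years within a draw, the
#' per-year probabilities sum exactly to the posterior mean knot count.
#'
#' @param draws a `cp_draws` object from [rjmcmc_sample()].
#' @return An object of class `changepoint_posterior`: a list with `table`
#'   (data frame `trajectory, year, t, p_changepoint, p_negative,
#'   p_positive, odds_ratio`), `E_k` and `p0` (named per trajectory), and
#'   the originating `draws`.
#' @export
changepoint_probability <- function(draws) {
  if (draws$n_draws < 1) stop("no retained draws")
  cand <- draws$candidates
  years <- draws$years
  tabs <- list(); E_k <- c(); p0 <- c()
  for (tr in draws$trajectories) {
    nd <- length(tr$theta)
    all_th <- unlist(tr$theta, use.names = FALSE)
    all_inc <- unlist(lapply(tr$beta, function(b) b[-1]), use.names = FALSE)
    cnt <- tabulate(all_th, nbins = max(cand))
    cnt_neg <- tabulate(all_th[all_inc < 0], nbins = max(cand))
    p1 <- cnt[cand] / nd
    p_neg <- cnt_neg[cand] / nd
    p_pos <- p1 - p_neg
    p0_tr <- prior_changepoint_probability(tr$k_max, 0.5, length(cand))
    tabs[[tr$id]] <- data.frame(
      trajectory = tr$id, year = years[cand], t = cand,
      p_changepoint = p1, p_negative = p_neg, p_positive = p_pos,
      odds_ratio = odds_ratio(p1, p0_tr))
    E_k[tr$id] <- length(all_th) / nd
    p0[tr$id] <- p0_tr
  }
  structure(list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
                 E_k = E_k, p0 = p0, draws = draws),
            class = "changepoint_posterior")
}

#' @export
print.changepoint_posterior <- function(x, ...) {
  cat("Change-point posterior over", length(x$E_k), "trajectories\n")
  strong <- x$table[x$table$odds_ratio > 3, , drop = FALSE]
  if (nrow(strong) == 0) {
    cat("  no year reaches posterior:prior odds ratio > 3\n")
  } else {
    for (id in unique(strong$trajectory)) {
      s <- strong[strong$trajectory == id, ]
      cat("  ", id, ": odds ratio > 3 in ",
          paste(s$year, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write the per-year probability table
#'
#' @param cp a `changepoint_posterior`.
#' @param file CSV path; columns
#'   `trajectory,year,p_changepoint,p_negative,p_positive,odds_ratio`.
#' @export
write_changepoint_table <- function(cp, file) {
  utils::write.csv(cp$table[, c("trajectory", "year", "p_changepoint",
                                "p_negative", "p_positive", "odds_ratio")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(cp)
}
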