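#' Direction of a change point
#'
#' A change point is negative if the slope of the trajectory decreases at
#' the knot (a downturn: increasing to stable, stable to decreasing, or
#' decreasing to more steeply decreasing) and positive if the slope
#' increases (an upturn).
#'
#' @param increment slope increment(s) at the knot; must be nonzero.
#' @return Character vector `"negative"` / `"positive"`.
#' @export
classify_changepoint <- function(increment) {
  if (any(increment == 0)) stop("zero increment has no direction")
  ifelse(increment < 0, "negative", "positive")
}

#' Log-scale slope as percent change per year
#'
#' @param slope log-scale per-year slope(s).
#' @return `100 * (exp(slope) - 1)`.
#' @export
trend_percent <- function(slope) {
  if (any(!is.finite(slope))) stop("'slope' must be finite")
  100 * (exp(slope) - 1)
}

#' Trends flanking a change point
#'
#' Posterior mean cumulative slope of one trajectory immediately before and
#' after a change-point year, converted to percent per year.  Only draws
#' whose state actually contains a knot at that year contribute: the
#' flanking slopes exist only in those draws.  The cumulative slope before
#' the year is the base slope plus all increments at earlier knots; the
#' slope after adds the increment at the year itself.
#'
#' @param draws a `cp_draws` object.
#' @param trajectory trajectory id.
#' @param year calendar year of the change point.
#' @return Named vector `c(before, after)` in percent per year, with
#'   attribute `n_draws` (number of contributing draws).
#' @export
segment_trends <- function(draws, trajectory, year) {
  tr <- draws$trajectories[[trajectory]]
  if (is.null(tr)) stop("unknown trajectory: ", trajectory)
  tj <- match(year, draws$years)
  if (is.na(tj)) stop("year ", year, " is outside the series")
  slopes <- vapply(seq_along(tr$theta), function(i) {
    th <- tr$theta[[i]]
    if (!(tj %in% th)) return(c(NA_real_, NA_real_))
    b <- tr$beta[[i]]
    before <- b[1] + sum(b[-1][th < tj])
    c(before, before + b[-1][th == tj])
  }, numeric(2))
  ok <- !is.na(slopes[1, ])
  if (!any(ok))
    stop("no retained draw has a change point in ", year,
         " for trajectory ", trajectory)
  out <- trend_percent(rowMeans(slopes[, ok, drop = FALSE]))
  names(out) <- c("before", "after")
  attr(out, "n_draws") <- sum(ok)
  out
}

#' Summarise well-supported change points
#'
#' For each trajectory and each direction (negative and positive handled
#' separately), finds maximal runs of consecutive years whose
#' direction-specific posterior probability gives a posterior:prior odds
#' ratio above the threshold (3 by default — the strong-evidence rule).
#' Each run is reported with its modal year (highest probability, ties
#' broken toward the earlier year), the run extent (the adjacent years that
#' also carry strong evidence, indexing timing uncertainty), the summed
#' posterior support over the run, and the posterior mean trends flanking
#' the modal year.  Strata or trajectories with no qualifying year yield no
#' rows: no well-supported change point.
#'
#' @param cp a `changepoint_posterior` from [changepoint_probability()].
#' @param threshold odds-ratio threshold (default 3).
#' @return Data frame with columns `trajectory, direction, modal_year,
#'   run_start, run_end, summed_support, trend_before_pct,
#'   trend_after_pct`, ordered by trajectory and year; zero rows if nothing
#'   qualifies.
#' @export
summarize_changepoints <- function(cp, threshold = 3) {
  out <- list()
  for (id in names(cp$E_k)) {
    tab <- cp$table[cp$table$trajectory == id, , drop = FALSE]
    tab <- tab[order(tab$t), ]
    for (dir in c("negative", "positive")) {
      pd <- if (dir == "negative") tab$p_negative else tab$p_positive
      qual <- odds_ratio(pd, cp$p0[id]) > threshold
      if (!any(qual)) next
      r <- rle(qual)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (b in which(r$values)) {
        ix <- starts[b]:ends[b]
        modal <- ix[which.max(pd[ix])]     # which.max takes the earliest tie
        trends <- segment_trends(cp$draws, id, tab$year[modal])
        out[[length(out) + 1L]] <- data.frame(
          trajectory = id, direction = dir,
          modal_year = tab$year[modal],
          run_start = tab$year[starts[b]], run_end = tab$year[ends[b]],
          summed_support = sum(pd[ix]),
          trend_before_pct = trends[["before"]],
          trend_after_pct = trends[["after"]])
      }
    }
  }
  if (!length(out))
    return(data.frame(trajectory = character(0), direction = character(0),
                      modal_year = integer(0), run_start = integer(0),
                      run_end = integer(0), summed_support = numeric(0),
                      trend_before_pct = numeric(0),
                      trend_after_pct = numeric(0)))
  out <- do.call(rbind, out)
  out <- out[order(out$trajectory, out$modal_year), ]
  rownames(out) <- NULL
  out
}

#' @rdname summarize_changepoints
#' @param summaries the data frame returned by `summarize_changepoints`.
#' @param file CSV path.
#' @export
write_summaries <- function(summaries, file) {
  utils::write.csv(summaries, file, row.names = FALSE, quote = FALSE)
  invisible(summaries)
}
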