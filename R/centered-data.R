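#' Prepare annual indices for the change-point model
#'
#' Log-transforms the annual indices and centres each species-by-stratum
#' series on its value in the mid-year of the time series (the year at
#' ordinal position `ceiling(T / 2)`), so that all species enter the
#' change-point model on a common scale.  The known log-scale variances are
#' carried through unchanged: centring subtracts a constant per series.
#'
#' @param indices an [annual_index_set()]; all retained indices must be
#'   strictly positive.
#' @param groups data frame with columns `species`, `group` (`"FC"` or
#'   `"SSN"`) covering every species in `indices`.
#' @return A data frame of class `centered_index_data` with columns
#'   `species, stratum, year, t, z, var, group`, where `t` is the 1-based
#'   year index within the series and `z` the centred log index.
#' @export
prepare_inputs <- function(indices, groups) {
  df <- as.data.frame(indices)
  df <- df[!is.na(df$index), , drop = FALSE]
  if (any(df$index <= 0))
    stop("all retained indices must be strictly positive")
  gi <- match(df$species, groups$species)
  if (anyNA(gi))
    stop("species without a group label: ",
         paste(unique(df$species[is.na(gi)]), collapse = ", "))
  df$group <- groups$group[gi]
  out <- lapply(split(df, list(df$species, df$stratum), drop = TRUE),
                function(d) {
    d <- d[order(d$year), ]
    T <- nrow(d)
    mid <- ceiling(T / 2)
    lg <- log(d$index)
    data.frame(species = d$species, stratum = d$stratum, year = d$year,
               t = seq_len(T), z = lg - lg[mid], var = d$log_index_var,
               group = d$group)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$var <= 0))
    stop("log-scale index variances must be positive")
  class(out) <- c("centered_index_data", "data.frame")
  out
}
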