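#' Write and read count datasets
#'
#' Counts are stored as plain CSV with columns
#' `stratum,route,observer,year,count,first_year`, preceded by `#`-prefixed
#' header comments recording the species label and generating seed so that a
#' round trip is lossless.
#'
#' @param dataset a `count_dataset` (see [simulate_counts()]).
#' @param file file path.
#' @return `write_counts` invisibly returns `dataset`; `read_counts` returns
#'   a `count_dataset`.
#' @export
write_counts <- function(dataset, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# species: ", attr(dataset, "species")),
               paste0("# seed: ", attr(dataset, "seed"))), con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE,
                   quote = FALSE)
  invisible(dataset)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  hdr <- readLines(file, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  pick <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA_character_
  }
  out <- utils::read.csv(file, comment.char = "#")
  need <- c("stratum", "route", "observer", "year", "count", "first_year")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("counts file is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("stratum", "route", "observer"))
    out[[col]] <- as.character(out[[col]])
  if (any(is.na(out$count)) || any(out$count < 0) ||
      any(out$count != round(out$count)))
    stop("'count' must contain non-negative integers")
  out$count <- as.integer(out$count)
  out$first_year <- as.integer(out$first_year)
  attr(out, "species") <- pick("species")
  sd <- pick("seed")
  attr(out, "seed") <- if (is.na(sd)) NA_integer_ else as.integer(sd)
  class(out) <- c("count_dataset", "data.frame")
  out
}

#' Annual index sets
#'
#' Container for stage-two input: per (species, stratum, year) the abundance
#' index, its log-scale posterior mean and variance, and the detection
#' proportion `pi` of the stratum.
#'
#' @param df data frame with columns
#'   `species,stratum,year,index,log_index_mean,log_index_var,pi`.
#' @return The validated data frame with class `annual_index_set`.
#' @export
annual_index_set <- function(df) {
  need <- c("species", "stratum", "year", "index", "log_index_mean",
            "log_index_var", "pi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annual index set is missing column(s): ",
         paste(miss, collapse = ", "))
  ok <- !is.na(df$index)
  if (any(df$index[ok] <= 0 & df$pi[ok] > 0))
    stop("indices must be positive wherever pi > 0")
  if (any(df$log_index_var < 0, na.rm = TRUE))
    stop("log-scale index variances must be non-negative")
  if (any(df$pi < 0 | df$pi > 1))
    stop("'pi' must lie in [0, 1]")
  rownames(df) <- NULL
  class(df) <- c("annual_index_set", "data.frame")
  df
}

#' @rdname annual_index_set
#' @param file file path.
#' @export
write_annual_indices <- function(df, file) {
  utils::write.csv(as.data.frame(df), file, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname annual_index_set
#' @export
read_annual_indices <- function(file) {
  annual_index_set(utils::read.csv(file, colClasses = c(
    species = "character", stratum = "character")))
}

#' Read a species-to-group mapping
#'
#' @param file CSV with columns `species,group`; groups are `FC`
#'   (flycatchers) or `SSN` (swallows, swifts, nightjars).
#' @return Data frame with columns `species`, `group`.
#' @export
read_groups <- function(file) {
  g <- utils::read.csv(file, colClasses = "character")
  if (!all(c("species", "group") %in% names(g)))
    stop("groups file must have columns species,group")
  bad <- setdiff(unique(g$group), c("FC", "SSN"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  g
}
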