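#' Stratum adjacency graphs
#'
#' A `stratum_graph` holds the spatial units ("strata") of an analysis, their
#' symmetric neighbour sets, a coarse regional label per stratum (a Bird
#' Conservation Region, "BCR", used only by the isolated-stratum fallback),
#' and planar centroid coordinates.  Strata that share a border are
#' neighbours; the intrinsic CAR structure of the annual-index model consumes
#' exactly this adjacency.
#'
#' @param strata character vector of stratum identifiers.
#' @param neighbours named list mapping each stratum to a character vector of
#'   neighbouring strata.  Must be symmetric and irreflexive.
#' @param bcr named character vector giving each stratum's BCR label.
#' @param centroid numeric matrix with one row per stratum (rownames set) and
#'   columns `x`, `y`.
#' @return An object of class `stratum_graph`.
#' @seealso [build_stratum_graph()], [resolve_isolated_strata()]
#' @export
stratum_graph <- function(strata, neighbours, bcr, centroid) {
  strata <- as.character(strata)
  if (anyDuplicated(strata)) stop("duplicated stratum identifiers")
  if (!setequal(names(neighbours), strata))
    stop("'neighbours' must be named by the strata")
  neighbours <- lapply(neighbours[strata], as.character)
  for (s in strata) {
    nb <- neighbours[[s]]
    if (s %in% nb) stop("neighbour relation must be irreflexive: ", s)
    if (!all(nb %in% strata)) stop("unknown neighbour of stratum ", s)
    for (n in nb) if (!(s %in% neighbours[[n]]))
      stop("neighbour relation must be symmetric: ", s, " -> ", n)
  }
  if (!setequal(names(bcr), strata)) stop("'bcr' must be named by the strata")
  centroid <- as.matrix(centroid)[strata, , drop = FALSE]
  colnames(centroid) <- c("x", "y")
  structure(list(strata = strata, neighbours = neighbours,
                 bcr = bcr[strata], centroid = centroid),
            class = "stratum_graph")
}

#' @export
print.stratum_graph <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat("Stratum graph: ", length(x$strata), " strata, ",
      sum(deg) / 2, " edges, ", length(unique(x$bcr)), " BCR group(s)\n",
      sep = "")
  if (any(deg == 0))
    cat("  isolated strata: ", paste(x$strata[deg == 0], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Build a rectangular-grid stratum graph
#'
#' Constructs a synthetic grid of strata with rook adjacency (strata sharing
#' an edge are neighbours), mirroring the "share a border" neighbour
#' definition without any GIS machinery.  BCR labels are assigned by blocks
#' of columns and centroids sit at the integer grid coordinates.
#'
#' @param n_rows,n_cols positive grid dimensions.
#' @param bcr_blocks number of column blocks to cut into BCR labels
#'   (default 2, capped at `n_cols`).
#' @return A [stratum_graph()].
#' @examples
#' g <- build_stratum_graph(3, 3)
#' lengths(g$neighbours)   # corners 2, edges 3, centre 4
#' @export
build_stratum_graph <- function(n_rows, n_cols, bcr_blocks = 2) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  bcr_blocks <- max(1L, min(as.integer(bcr_blocks), n_cols))
  rc <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  ids <- sprintf("S%02d_%02d", rc$row, rc$col)
  at <- function(r, c) sprintf("S%02d_%02d", r, c)
  neighbours <- vector("list", nrow(rc))
  names(neighbours) <- ids
  for (i in seq_len(nrow(rc))) {
    r <- rc$row[i]; c <- rc$col[i]
    nb <- character(0)
    if (r > 1)      nb <- c(nb, at(r - 1, c))
    if (r < n_rows) nb <- c(nb, at(r + 1, c))
    if (c > 1)      nb <- c(nb, at(r, c - 1))
    if (c < n_cols) nb <- c(nb, at(r, c + 1))
    neighbours[[i]] <- sort(nb)
  }
  block <- ceiling(rc$col / (n_cols / bcr_blocks))
  bcr <- stats::setNames(sprintf("BCR%d", block), ids)
  centroid <- cbind(x = rc$col, y = rc$row)
  rownames(centroid) <- ids
  stratum_graph(ids, neighbours, bcr, centroid)
}

#' Restrict a stratum graph and resolve isolated strata
#'
#' Restricts the graph to the strata actually included in an analysis.  A
#' stratum left with no neighbours (because intervening strata were dropped)
#' is reconnected to all included strata sharing its BCR label, or, failing
#' that, to the single included stratum with the smallest Euclidean centroid
#' distance (ties broken toward the lexicographically smallest stratum id).
#' Symmetry is restored so the result is again a valid `stratum_graph`.
#'
#' @param graph a [stratum_graph()].
#' @param included character vector of strata to keep; must be a subset of
#'   `graph$strata`.
#' @return A `stratum_graph` on `included` in which every stratum has at
#'   least one neighbour (unless only one stratum is included).
#' @export
resolve_isolated_strata <- function(graph, included) {
  included <- as.character(included)
  if (length(included) == 0) stop("'included' is empty")
  if (!all(included %in% graph$strata))
    stop("'included' contains unknown strata")
  included <- graph$strata[graph$strata %in% included]  # keep original order
  nb <- lapply(graph$neighbours[included],
               function(v) intersect(v, included))
  names(nb) <- included
  for (s in included) {
    if (length(nb[[s]]) > 0) next
    mates <- setdiff(included[graph$bcr[included] == graph$bcr[[s]]], s)
    if (length(mates) == 0 && length(included) > 1) {
      others <- setdiff(included, s)
      d <- sqrt(rowSums((graph$centroid[others, , drop = FALSE] -
                           matrix(graph$centroid[s, ], length(others), 2,
                                  byrow = TRUE))^2))
      # ties toward the lexicographically smallest id
      ord <- order(d, others)
      mates <- others[ord[1]]
    }
    nb[[s]] <- sort(mates)
    for (m in mates) nb[[m]] <- sort(union(nb[[m]], s))
  }
  stratum_graph(included, nb, graph$bcr[included],
                graph$centroid[included, , drop = FALSE])
}

#' Write / read a stratum graph as plain text
#'
#' The adjacency is stored as a tab-separated edge list
#' (`stratum_a<TAB>stratum_b`, each undirected edge once) and the stratum
#' metadata as a CSV with columns `stratum,bcr,x,y`.
#'
#' @param graph a [stratum_graph()].
#' @param edges_file,meta_file file paths.
#' @return `write_stratum_graph` invisibly returns `graph`;
#'   `read_stratum_graph` returns a `stratum_graph`.
#' @export
write_stratum_graph <- function(graph, edges_file, meta_file) {
  e <- do.call(rbind, lapply(graph$strata, function(s) {
    nb <- graph$neighbours[[s]]
    nb <- nb[nb > s]
    if (length(nb)) cbind(s, nb) else NULL
  }))
  if (is.null(e)) e <- matrix(character(0), 0, 2)
  utils::write.table(e, edges_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(stratum = graph$strata,
                     bcr = unname(graph$bcr),
                     x = graph$centroid[, "x"], y = graph$centroid[, "y"])
  utils::write.csv(meta, meta_file, row.names = FALSE, quote = FALSE)
  invisible(graph)
}

#' @rdname write_stratum_graph
#' @export
read_stratum_graph <- function(edges_file, meta_file) {
  meta <- utils::read.csv(meta_file, colClasses = c(stratum = "character",
                                                    bcr = "character"))
  need <- c("stratum", "bcr", "x", "y")
  if (!all(need %in% names(meta)))
    stop("strata metadata must have columns: ", paste(need, collapse = ", "))
  nb <- stats::setNames(rep(list(character(0)), nrow(meta)), meta$stratum)
  if (file.size(edges_file) > 0) {
    e <- utils::read.table(edges_file, sep = "\t",
                           colClasses = "character", col.names = c("a", "b"))
    for (i in seq_len(nrow(e))) {
      nb[[e$a[i]]] <- union(nb[[e$a[i]]], e$b[i])
      nb[[e$b[i]]] <- union(nb[[e$b[i]]], e$a[i])
    }
  }
  centroid <- cbind(x = meta$x, y = meta$y)
  rownames(centroid) <- meta$stratum
  stratum_graph(meta$stratum, nb, stats::setNames(meta$bcr, meta$stratum),
                centroid)
}
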