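#' Contact networks for epidemic simulation
#'
#' An `epi_network` is a simple undirected graph stored as an edge matrix
#' plus an adjacency list, the form consumed by the event-driven simulators.
#' Node ids are 1-based internally; edge-list files on disk use the common
#' 0-based whitespace-delimited convention.
#'
#' @param edges Two-column integer matrix of 1-based node ids, one row per
#'   undirected edge.
#' @param n Number of nodes (isolated nodes beyond the largest id are kept).
#' @return An object of class `epi_network` with fields `n`, `edges`, `adj`
#'   (list of integer neighbour vectors) and `kbar` (mean degree).
#' @export
epi_network <- function(edges, n = max(edges)) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoints out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    ii <- c(edges[, 1L], edges[, 2L])
    jj <- c(edges[, 2L], edges[, 1L])
    adj <- unname(split(jj, factor(ii, levels = seq_len(n))))
  } else {
    adj[] <- list(integer(0))
  }
  structure(
    list(n = as.integer(n), edges = edges, adj = adj,
         kbar = 2 * nrow(edges) / n),
    class = "epi_network"
  )
}

#' @export
print.epi_network <- function(x, ...) {
  cat(sprintf("<epi_network> %d nodes, %d edges, mean degree %.2f\n",
              x$n, nrow(x$edges), x$kbar))
  invisible(x)
}

#' Generate an Erdos-Renyi contact network
#'
#' Draws G(N, p) with edge probability `kbar / (N - 1)`, so the expected
#' mean degree is exactly `kbar`. This is the reference substrate for all
#' simulation experiments (default N = 5000, mean degree 15).
#'
#' @param n Number of nodes.
#' @param kbar Target mean degree, must be below `n - 1`.
#' @param seed Optional integer seed; the same seed yields the same network.
#' @return An `epi_network`.
#' @examples
#' net <- generate_er_network(200, 8, seed = 1)
#' net$kbar
#' @export
generate_er_network <- function(n, kbar, seed = NULL) {
  if (n < 2L) stop("`n` must be at least 2")
  if (kbar < 0 || kbar >= n - 1) stop("`kbar` must lie in [0, n - 1)")
  with_seed_(seed, {
    g <- igraph::sample_gnp(n, kbar / (n - 1))
    epi_network(igraph::as_edgelist(g, names = FALSE), n = n)
  })
}

#' Read / write a network as a plain edge list
#'
#' Files are whitespace-delimited pairs of 0-based integer node ids, one
#' undirected edge per line. Malformed lines, self-loops and duplicate
#' edges are rejected with the offending line number.
#'
#' @param path File path.
#' @param n Number of nodes; defaults to the largest id + 1.
#' @return `read_edge_list` returns an `epi_network`; `write_edge_list`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile()
#' write_edge_list(generate_er_network(50, 4, seed = 1), f)
#' net <- read_edge_list(f)
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge at line %d: expected two ids", keep[bad[1L]]))
  }
  ids <- suppressWarnings(vapply(fields, function(f) as.integer(f), integer(2)))
  nonint <- which(apply(is.na(ids), 2L, any))
  if (length(nonint)) {
    stop(sprintf("malformed edge at line %d: non-integer id", keep[nonint[1L]]))
  }
  loops <- which(ids[1L, ] == ids[2L, ])
  if (length(loops)) {
    stop(sprintf("self-loop at line %d", keep[loops[1L]]))
  }
  key <- paste(pmin(ids[1L, ], ids[2L, ]), pmax(ids[1L, ], ids[2L, ]))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate edge at line %d", keep[dup[1L]]))
  }
  edges <- t(ids) + 1L
  if (is.null(n)) n <- if (length(edges)) max(edges) else 0L
  epi_network(edges, n = n)
}

#' @rdname read_edge_list
#' @param network An `epi_network`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "epi_network"))
  e <- network$edges - 1L
  writeLines(paste(e[, 1L], e[, 2L]), path)
  invisible(path)
}
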