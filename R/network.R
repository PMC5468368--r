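#' Undirected simple network container
#'
#' An `sbm_network` is a light container for an undirected simple graph:
#' original vertex labels, a canonical edge table with `i < j`, and per-vertex
#' degrees. Self-loops and multi-edges are always removed on construction;
#' isolated vertices are retained (they still receive cluster marginals from
#' the non-edge field term during inference).
#'
#' @param pairs two-column matrix (or data.frame) of vertex indices, 1-based,
#'   possibly containing self-pairs and duplicates.
#' @param n number of vertices. Defaults to `max(pairs)`; may be larger to
#'   declare isolated vertices.
#' @param labels character vector of original vertex identifiers, length `n`.
#'
#' @return An object of class `sbm_network` with elements `labels`, `n`,
#'   `edges` (L x 2 integer matrix, `i < j`, sorted), `L`, and `degrees`.
#' @export
network_from_pairs <- function(pairs, n = NULL, labels = NULL) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(), ncol = 2L)
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
  storage.mode(pairs) <- "integer"
  if (is.null(n)) n <- if (nrow(pairs)) max(pairs) else 0L
  n <- as.integer(n)
  if (n < 1L) stop("empty vertex set")
  if (nrow(pairs) && (min(pairs) < 1L || max(pairs) > n))
    stop("vertex index out of range")
  edges <- simplify_pairs(pairs)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) stop("'labels' must have length n")
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  structure(
    list(labels = as.character(labels), n = n, edges = edges,
         L = nrow(edges), degrees = deg),
    class = "sbm_network"
  )
}

# Canonicalize a raw multiset of vertex pairs: drop self-pairs, store i < j,
# collapse duplicates, sort lexicographically.
simplify_pairs <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  i <- pmin(pairs[, 1L], pairs[, 2L])
  j <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  key <- unique(cbind(i, j))
  ord <- order(key[, 1L], key[, 2L])
  out <- key[ord, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.sbm_network <- function(x, ...) {
  cat(sprintf("sbm_network: N = %d vertices, L = %d edges, mean degree %.3f\n",
              x$n, x$L, if (x$n) 2 * x$L / x$n else 0))
  invisible(x)
}

#' Read an undirected edge list
#'
#' Each non-comment, non-blank line must contain exactly two whitespace
#' separated vertex tokens. Tokens are mapped to vertex indices in order of
#' first appearance; duplicate edges and self-loops are dropped.
#'
#' @param path path to the edge-list file.
#' @param comment_char lines starting with this character are ignored.
#' @return An [network_from_pairs()] `sbm_network`.
#' @export
read_edge_list <- function(path, comment_char = "#") {
  lines <- readLines(path, warn = FALSE)
  toks_i <- character(0); toks_j <- character(0)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (!nzchar(s)) next
    if (startsWith(s, comment_char)) next
    tk <- strsplit(s, "[[:space:]]+")[[1]]
    if (length(tk) != 2L)
      stop(sprintf("malformed line %d: expected 2 tokens, found %d",
                   ln, length(tk)))
    toks_i <- c(toks_i, tk[[1]]); toks_j <- c(toks_j, tk[[2]])
  }
  labels <- unique(as.vector(rbind(toks_i, toks_j)))
  if (length(labels) == 0L) stop("empty vertex set")
  pairs <- cbind(match(toks_i, labels), match(toks_j, labels))
  network_from_pairs(pairs, n = length(labels), labels = labels)
}

#' Write an undirected edge list
#'
#' @param network an `sbm_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  lab <- network$labels
  writeLines(paste(lab[network$edges[, 1L]], lab[network$edges[, 2L]]), path)
  invisible(path)
}

#' Read a network from a GML file
#'
#' Minimal GML dialect as used by the classic network repositories. A
#' `directed 1` flag is tolerated by symmetrizing with a warning; duplicate
#' edge entries are deduplicated with a warning.
#'
#' @param path path to the GML file.
#' @return An `sbm_network`. Vertex labels are taken from the GML `label`
#'   attribute when present, else from the node `id`.
#' @export
read_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  if (igraph::is_directed(g)) {
    warning("directed GML input symmetrized to an undirected network")
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    warning("duplicate edges and/or self-loops in GML input were dropped")
  va <- igraph::vertex_attr_names(g)
  labels <- if ("label" %in% va) {
    as.character(igraph::vertex_attr(g, "label"))
  } else if ("id" %in% va) {
    as.character(igraph::vertex_attr(g, "id"))
  } else as.character(seq_len(igraph::vcount(g)))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  el <- igraph::as_edgelist(g, names = FALSE)
  network_from_pairs(el, n = igraph::vcount(g), labels = labels)
}

#' Write a network to canonical GML
#'
#' @param network an `sbm_network`.
#' @param path output file path.
#' @export
write_gml <- function(network, path) {
  g <- igraph::make_empty_graph(n = network$n, directed = FALSE)
  g <- igraph::add_edges(g, t(network$edges))
  igraph::V(g)$label <- network$labels
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Convert an igraph object to an `sbm_network`
#'
#' @param g an igraph graph; directions, loops and multi-edges are dropped.
#' @return An `sbm_network`.
#' @export
as_sbm_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  labels <- if ("name" %in% igraph::vertex_attr_names(g)) {
    as.character(igraph::V(g)$name)
  } else as.character(seq_len(igraph::vcount(g)))
  network_from_pairs(igraph::as_edgelist(g, names = FALSE),
                     n = igraph::vcount(g), labels = labels)
}

# Directed-edge incidence arrays for the BP core. Directed edge e in 1..L is
# the message i->j for row e of the edge table; e + L is j->i. For each vertex
# the incoming message indices and corresponding source vertices are laid out
# contiguously (CSR-style).
network_incidence <- function(network) {
  L <- network$L; n <- network$n
  ei <- network$edges[, 1L]; ej <- network$edges[, 2L]
  # message m (1..2L): src[m] -> dst[m]
  src <- c(ei, ej); dst <- c(ej, ei)
  ord <- order(dst)
  ptr <- cumsum(c(0L, tabulate(dst, nbins = n)))
  list(src = src, dst = dst,
       in_msg = ord,          # messages sorted by destination vertex
       in_ptr = ptr)          # 0-based offsets, length n + 1
}
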