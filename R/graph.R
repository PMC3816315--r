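#' Overlap graphs
#'
#' An `overlap_graph` stores one node per read and one undirected edge per
#' accepted overlap, weighted by overlap (alignment) length. Adjacency is
#' kept in flat arrays (compressed sparse rows): a per-node offset array plus
#' destination and weight arrays in which each undirected edge appears once
#' per endpoint. Within each node's edge set, edges are sorted by descending
#' weight (ties by ascending destination id). Level-0 edges additionally
#' carry percent identity. All node ids are 0-based.
#'
#' @param n node count.
#' @param edges data frame with columns `src`, `dst`, `weight` and optionally
#'   `identity`, one row per unordered edge (no self-loops, no duplicate
#'   pairs).
#' @return an object of class `overlap_graph` with fields `n`, `m`,
#'   `offsets` (length `n+1`, 0-based, last entry `2m`), `dst`, `weight`,
#'   and optionally `identity`.
#' @export
new_overlap_graph <- function(n, edges) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  if (nrow(edges) == 0) {
    g <- structure(list(n = n, m = 0L,
                        offsets = integer(n + 1L),
                        dst = integer(0), weight = numeric(0),
                        identity = NULL),
                   class = "overlap_graph")
    return(g)
  }
  u <- as.integer(edges$src); v <- as.integer(edges$dst)
  w <- as.numeric(edges$weight)
  if (any(u == v)) stop("self-loop in edge list")
  if (any(u < 0 | u >= n | v < 0 | v >= n)) stop("node id out of range [0, n)")
  key <- pmin(u, v) * as.numeric(n) + pmax(u, v)
  if (anyDuplicated(key)) stop("duplicate unordered edge in edge list")
  has_id <- !is.null(edges$identity)
  m <- length(u)
  src2 <- c(u, v); dst2 <- c(v, u); w2 <- c(w, w)
  id2 <- if (has_id) rep(as.numeric(edges$identity), 2L) else NULL
  ord <- order(src2, -w2, dst2, method = "radix")
  deg <- tabulate(src2 + 1L, nbins = n)
  structure(list(n = n, m = m,
                 offsets = c(0L, cumsum(deg)),
                 dst = dst2[ord], weight = w2[ord],
                 identity = if (has_id) id2[ord] else NULL),
            class = "overlap_graph")
}

graph_src <- function(g) rep.int(0:(g$n - 1L), diff(g$offsets))

#' Unique-pair edge table of an overlap graph
#'
#' One row per undirected edge with `src < dst`, ordered by (`src` ascending,
#' `weight` descending, `dst` ascending).
#'
#' @param g an [new_overlap_graph()] object.
#' @return data frame with columns `src`, `dst`, `weight` and, when stored,
#'   `identity`.
#' @export
edge_table <- function(g) {
  stopifnot(inherits(g, "overlap_graph"))
  src <- graph_src(g)
  keep <- src < g$dst
  out <- data.frame(src = src[keep], dst = g$dst[keep],
                    weight = g$weight[keep])
  if (!is.null(g$identity)) out$identity <- g$identity[keep]
  out
}

#' Build the overlap graph from an overlap table
#'
#' The initial edge weight is the alignment overlap length. Duplicate records
#' for the same unordered pair are collapsed keeping the longest alignment
#' (ties: highest identity). Each node's edge set is sorted by descending
#' weight, ties by ascending destination id.
#'
#' @param n number of reads (nodes).
#' @param overlaps an [overlap_table()] (or data frame with the same
#'   columns).
#' @return an [new_overlap_graph()] object; level-0 identity is retained.
#' @export
build_graph <- function(n, overlaps) {
  n <- as.integer(n)
  if (nrow(overlaps) == 0)
    return(new_overlap_graph(n, data.frame(src = integer(0),
                                           dst = integer(0),
                                           weight = numeric(0))))
  q <- as.integer(overlaps$query_id); r <- as.integer(overlaps$ref_id)
  if (any(q < 0 | q >= n | r < 0 | r >= n))
    stop("read id out of range [0, n)")
  if (any(q == r)) stop("self-overlap in overlap table")
  u <- pmin(q, r); v <- pmax(q, r)
  len <- as.numeric(overlaps$alignment_length)
  ident <- if (!is.null(overlaps$identity)) as.numeric(overlaps$identity)
           else rep(NA_real_, length(u))
  ord <- order(u, v, -len, -ident, method = "radix")
  u <- u[ord]; v <- v[ord]; len <- len[ord]; ident <- ident[ord]
  first <- !duplicated(paste(u, v))
  edges <- data.frame(src = u[first], dst = v[first], weight = len[first])
  if (!all(is.na(ident))) edges$identity <- ident[first]
  new_overlap_graph(n, edges)
}

#' Neighbors of a node in stored (descending-weight) order
#'
#' @param g an [new_overlap_graph()] object.
#' @param u node id (0-based).
#' @return data frame with columns `dst` and `weight`, exactly the stored
#'   edge set of `u`, weights nonincreasing.
#' @export
graph_neighbors <- function(g, u) {
  stopifnot(inherits(g, "overlap_graph"))
  if (length(u) != 1 || u < 0 || u >= g$n)
    stop("node id out of range [0, n)")
  idx <- seq.int(g$offsets[u + 1L] + 1L, length.out =
                   g$offsets[u + 2L] - g$offsets[u + 1L])
  data.frame(dst = g$dst[idx], weight = g$weight[idx])
}

#' Merge parallel edges
#'
#' Collapses duplicate edges with the same unordered endpoints into one edge
#' whose weight is the sum of the merged weights (the rule applied when
#' contracted edges land on the same supernode pair). Self-loops must already
#' have been dropped and are rejected.
#'
#' @param edges data frame with columns `src`, `dst`, `weight`, possibly with
#'   duplicated unordered pairs.
#' @return data frame with one row per unordered pair (`src < dst`), weights
#'   summed, ordered by (`src`, `weight` descending, `dst`).
#' @export
merge_parallel_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  u <- pmin(edges$src, edges$dst); v <- pmax(edges$src, edges$dst)
  if (any(u == v)) stop("self-loop in edge list; drop self-loops first")
  w <- as.numeric(edges$weight)
  big <- as.numeric(max(v)) + 1
  key <- u * big + v
  ord <- order(key, method = "radix")
  key <- key[ord]; u <- u[ord]; v <- v[ord]; w <- w[ord]
  last <- c(key[-1] != key[-length(key)], TRUE)
  cw <- cumsum(w)[last]
  wsum <- c(cw[1], diff(cw))
  out <- data.frame(src = u[last], dst = v[last], weight = wsum)
  out[order(out$src, -out$weight, out$dst, method = "radix"), , drop = FALSE]
}

#' Total edge weight of a graph
#'
#' Sum of weights over undirected edges, each counted once.
#'
#' @param g an [new_overlap_graph()] object.
#' @return a number.
#' @export
total_edge_weight <- function(g) {
  stopifnot(inherits(g, "overlap_graph"))
  sum(g$weight) / 2
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat("overlap_graph with", x$n, "nodes and", x$m, "undirected edges\n")
  invisible(x)
}
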