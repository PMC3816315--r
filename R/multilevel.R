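#' Expand a supernode to its read ids
#'
#' Depth-first descent through the `node_map_inverse` arrays from `level`
#' down to 0, skipping `-1` sentinels; the level-0 labels are the read ids.
#'
#' @param hierarchy a [coarsen()] result.
#' @param level level index (0-based).
#' @param z supernode id at that level (0-based).
#' @return sorted integer vector of read ids.
#' @export
expand_to_reads <- function(hierarchy, level, z) {
  stopifnot(inherits(hierarchy, "coarsen_hierarchy"),
            level >= 0, level < hierarchy$n_levels)
  if (length(z) != 1 || z < 0 || z >= hierarchy$levels[[level + 1L]]$graph$n)
    stop("supernode id out of range at level ", level)
  cur <- as.integer(z)
  lev <- level
  while (lev > 0) {
    inv <- hierarchy$levels[[lev + 1L]]$node_map_inverse
    kids <- c(inv[2L * cur + 1L], inv[2L * cur + 2L])
    cur <- kids[kids >= 0L]
    lev <- lev - 1L
  }
  sort(cur)
}

#' Read clusters at a coarsening level
#'
#' Every supernode at `level` is expanded to its read ids; the clusters form
#' a partition of `0..n_reads-1` and cluster sizes equal the level's
#' `node_weights`. (Computed by composing the `node_map` arrays, which is
#' equivalent to per-supernode `node_map_inverse` descent.)
#'
#' @param hierarchy a [coarsen()] result.
#' @param level level index (0-based).
#' @return an object of class `cluster_set`: list with `level`, `assignment`
#'   (0-based supernode id per read), `clusters` (named list supernode id ->
#'   read ids) and `n_reads`.
#' @export
clusters_at <- function(hierarchy, level) {
  stopifnot(inherits(hierarchy, "coarsen_hierarchy"),
            level >= 0, level < hierarchy$n_levels)
  n0 <- hierarchy$levels[[1L]]$graph$n
  assignment <- 0:(n0 - 1L)
  for (j in seq_len(level))
    assignment <- hierarchy$levels[[j]]$node_map[assignment + 1L]
  clusters <- split(0:(n0 - 1L), assignment)
  structure(list(level = as.integer(level), assignment = assignment,
                 clusters = clusters, n_reads = n0),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("cluster_set at level", x$level, "-", length(x$clusters),
      "clusters over", x$n_reads, "reads (largest:", max(sizes), ")\n")
  invisible(x)
}

# per-(cluster, label) counts; returns the majority label per cluster id
majority_by_cluster <- function(assignment, truth) {
  n <- length(assignment)
  ord <- order(assignment, truth, method = "radix")
  a <- assignment[ord]; tr <- truth[ord]
  new_grp <- c(TRUE, a[-1] != a[-n] | tr[-1] != tr[-n])
  starts <- which(new_grp)
  cnt <- diff(c(starts, n + 1L))
  ga <- a[starts]; gt <- tr[starts]
  o2 <- order(ga, -cnt, gt, method = "radix")  # ties -> smallest label first
  keep <- !duplicated(ga[o2])
  setNames(gt[o2][keep], ga[o2][keep])
}

#' Majority-vote cluster labels
#'
#' Labels each cluster by the most frequent ground-truth label among its
#' reads; ties are broken by the lexicographically smallest label.
#'
#' @param clusters a [clusters_at()] result.
#' @param truth character vector of per-read ground-truth genome labels, in
#'   read-id order (no missing values).
#' @return named character vector: cluster (supernode) id -> majority label.
#' @export
majority_labels <- function(clusters, truth) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(truth) != clusters$n_reads || anyNA(truth))
    stop("a truth label is required for every read")
  majority_by_cluster(clusters$assignment, as.character(truth))
}

#' Majority-vote classification error rate
#'
#' Percentage of reads whose ground-truth label differs from their cluster's
#' majority label.
#'
#' @inheritParams majority_labels
#' @return error rate in percent.
#' @export
error_rate <- function(clusters, truth) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (clusters$n_reads == 0) stop("error_rate is undefined on an empty read set")
  if (length(truth) != clusters$n_reads || anyNA(truth))
    stop("a truth label is required for every read")
  truth <- as.character(truth)
  maj <- majority_by_cluster(clusters$assignment, truth)
  assigned <- maj[as.character(clusters$assignment)]
  100 * sum(assigned != truth) / clusters$n_reads
}

#' Read ordering from reduced-graph traversal
#'
#' Traverses the reduced graph at `level` (breadth-first by default;
#' depth-first behind a flag), seeding each component at the unvisited node
#' of largest node weight (ties: smallest id) and enqueueing neighbors in
#' stored descending-weight order; each visited supernode is expanded to its
#' reads via [expand_to_reads()]. The result is a permutation of the level-0
#' node ids usable for [relabel_edges()].
#'
#' @param hierarchy a [coarsen()] result.
#' @param level level index (0-based).
#' @param method `"bfs"` (default) or `"dfs"`.
#' @return integer permutation of `0..n_reads-1` (read ids in visit order).
#' @export
traversal_order <- function(hierarchy, level, method = c("bfs", "dfs")) {
  method <- match.arg(method)
  stopifnot(inherits(hierarchy, "coarsen_hierarchy"),
            level >= 0, level < hierarchy$n_levels)
  lv <- hierarchy$levels[[level + 1L]]
  g <- lv$graph
  n <- g$n
  nw <- lv$node_weights
  seed_rank <- order(-nw, 0:(n - 1L), method = "radix")  # 1-based node order
  visited <- logical(n)
  out <- vector("list", n)
  nxt <- 1L
  queue <- integer(n)
  for (s1 in seed_rank) {
    if (visited[s1]) next
    qh <- 1L; qt <- 1L
    queue[1L] <- s1 - 1L
    visited[s1] <- TRUE
    while (qh <= qt) {
      z <- if (method == "bfs") {
        x <- queue[qh]; qh <- qh + 1L; x
      } else {
        x <- queue[qt]; qt <- qt - 1L; x
      }
      out[[nxt]] <- expand_to_reads(hierarchy, level, z)
      nxt <- nxt + 1L
      idx <- seq.int(g$offsets[z + 1L] + 1L,
                     length.out = g$offsets[z + 2L] - g$offsets[z + 1L])
      nbr <- g$dst[idx]  # stored descending-weight order
      if (method == "dfs") nbr <- rev(nbr)
      for (v in nbr) {
        if (!visited[v + 1L]) {
          visited[v + 1L] <- TRUE
          if (method == "bfs") { qt <- qt + 1L; queue[qt] <- v }
          else { qt <- qt + 1L; queue[qt] <- v }
        }
      }
    }
  }
  unlist(out, use.names = FALSE)
}

#' Mean edge-endpoint distance
#'
#' Mean `|src - dst|` over undirected edges: the locality score that edge
#' relabeling aims to reduce (so edges with common endpoints sit close
#' together in the flat edge arrays).
#'
#' @param g an [new_overlap_graph()] object.
#' @return a number (`NA` for an edgeless graph).
#' @export
locality_score <- function(g) {
  et <- edge_table(g)
  if (!nrow(et)) return(NA_real_)
  mean(abs(et$src - et$dst))
}

#' Relabel graph nodes by a traversal order
#'
#' Maps every endpoint through the permutation (the node visited at position
#' `p` receives label `p`), regroups and re-sorts the edge sets. The result
#' is isomorphic to the input; attributes `locality_before` and
#' `locality_after` report the [locality_score()] on both sides.
#'
#' @param g the level-0 overlap graph.
#' @param order integer permutation of `0..n-1` (e.g. from
#'   [traversal_order()]).
#' @return the relabeled [new_overlap_graph()] object.
#' @export
relabel_edges <- function(g, order) {
  stopifnot(inherits(g, "overlap_graph"))
  order <- as.integer(order)
  if (length(order) != g$n || !identical(sort(order), 0:(g$n - 1L)))
    stop("order must be a permutation of 0..n-1")
  newid <- integer(g$n)
  newid[order + 1L] <- 0:(g$n - 1L)
  et <- edge_table(g)
  if (nrow(et)) {
    s2 <- newid[et$src + 1L]; d2 <- newid[et$dst + 1L]
    edges <- data.frame(src = pmin(s2, d2), dst = pmax(s2, d2),
                        weight = et$weight)
    if (!is.null(et$identity)) edges$identity <- et$identity
  } else {
    edges <- data.frame(src = integer(0), dst = integer(0),
                        weight = numeric(0))
  }
  g2 <- new_overlap_graph(g$n, edges)
  attr(g2, "locality_before") <- locality_score(g)
  attr(g2, "locality_after") <- locality_score(g2)
  g2
}
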