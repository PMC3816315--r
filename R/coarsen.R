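#' Coarsening parameters
#'
#' @param min_density minimum edge density a prospective supernode must
#'   exceed (strictly) for its pair to be matched; dimensionless (an average
#'   internal overlap length per node pair). Default 50.
#' @param min_match_ratio termination threshold: coarsening stops when the
#'   ratio of matched nodes to graph size falls (strictly) below this value.
#'   Default 0.01.
#' @param min_edge_weight weight floor during the neighbor scan: scanning a
#'   node's (descending-weight) edge set stops when the edge weight drops
#'   below this value. Default 0, so `min_density` is the binding constraint.
#' @param passes matching sweeps per iteration; later passes revisit only
#'   still-unmatched nodes with a fresh within-tier shuffle.
#' @param seed RNG seed for the visit-order shuffles.
#' @param max_iterations safety cap on coarsening iterations.
#' @return a list of class `coarsen_params`.
#' @export
coarsen_params <- function(min_density = 50, min_match_ratio = 0.01,
                           min_edge_weight = 0, passes = 1, seed = 1,
                           max_iterations = 50) {
  stopifnot(min_density >= 0, min_match_ratio > 0, min_match_ratio <= 1,
            min_edge_weight >= 0, passes >= 1, max_iterations >= 1)
  structure(list(min_density = as.numeric(min_density),
                 min_match_ratio = as.numeric(min_match_ratio),
                 min_edge_weight = as.numeric(min_edge_weight),
                 passes = as.integer(passes), seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations)),
            class = "coarsen_params")
}

#' Edge density of a prospective supernode
#'
#' For nodes `u`, `v` joined by an edge of weight `w`, the density of the
#' merged supernode is `2 * (ew_u + ew_v + w) / (s * (s - 1))` with
#' `s = nw_u + nw_v`: twice the internal edge weight divided by the number
#' of node pairs the supernode contains. For two singletons it equals `w`.
#' Symmetric in `u` and `v`; vectorized.
#'
#' @param nw_u,nw_v node weights (counts of level-0 descendants, >= 1).
#' @param ew_u,ew_v internal edge weights of the two nodes.
#' @param w weight of the connecting edge.
#' @return the density (dimensionless).
#' @export
edge_density <- function(nw_u, ew_u, nw_v, ew_v, w) {
  stopifnot(all(nw_u >= 1), all(nw_v >= 1))
  s <- nw_u + nw_v
  2 * (ew_u + ew_v + w) / (s * (s - 1))
}

#' Node visit order for Heavy Edge Matching
#'
#' Nodes are keyed by their heaviest incident edge weight (0 if isolated)
#' and visited in strictly descending key order; within equal keys the order
#' is a seeded-RNG shuffle (uses the current RNG state).
#'
#' @param g an [new_overlap_graph()] object.
#' @param restrict_to optional 0-based node ids to restrict the order to
#'   (used by later matching passes).
#' @return integer vector of 0-based node ids.
#' @export
visit_order <- function(g, restrict_to = NULL) {
  stopifnot(inherits(g, "overlap_graph"))
  key <- numeric(g$n)
  deg <- diff(g$offsets)
  nz <- which(deg > 0)
  key[nz] <- g$weight[g$offsets[nz] + 1L]  # first stored edge = heaviest
  nodes <- if (is.null(restrict_to)) 0:(g$n - 1L) else as.integer(restrict_to)
  if (length(nodes) && (min(nodes) < 0 || max(nodes) >= g$n))
    stop("restrict_to contains node ids out of range")
  tie <- runif(length(nodes))
  nodes[order(-key[nodes + 1L], tie, method = "radix")]
}

#' Heavy Edge Matching under density and weight constraints
#'
#' For each unmatched node `u` in visit order, its neighbors are scanned in
#' descending weight order; the scan stops when the edge weight falls below
#' `min_edge_weight`, skips neighbors that are already matched, and skips
#' neighbors for which the prospective supernode's [edge_density()] is not
#' strictly greater than `min_density` (density failures continue the scan:
#' density is not monotone in weight, whereas the weight floor is). `u` is
#' matched to the first surviving neighbor. The sweep repeats `passes` times
#' over still-unmatched nodes. The result is a valid matching, maximal with
#' respect to eligible edges after the final pass.
#'
#' @param g an [new_overlap_graph()] object.
#' @param node_weights,edge_weights per-node bookkeeping arrays (see
#'   [coarsen()]).
#' @param params a [coarsen_params()] object. Uses the current RNG state for
#'   the visit-order shuffles.
#' @return an object of class `hem_matching`: list with `pairs` (data frame
#'   `u`, `v`, `weight`, with `u < v`), `unmatched` (0-based ids) and
#'   `match` (0-based partner per node, -1 if unmatched).
#' @export
hem_match <- function(g, node_weights = rep(1, g$n),
                      edge_weights = rep(0, g$n),
                      params = coarsen_params()) {
  stopifnot(inherits(g, "overlap_graph"),
            length(node_weights) == g$n, length(edge_weights) == g$n)
  match <- rep.int(-1L, g$n)
  mweight <- numeric(g$n)
  for (p in seq_len(params$passes)) {
    unmatched <- which(match < 0L) - 1L
    if (!length(unmatched)) break
    ord <- visit_order(g, restrict_to = unmatched)
    res <- .hem_pass_cpp(g$offsets, g$dst, g$weight,
                         as.numeric(node_weights), as.numeric(edge_weights),
                         ord, match, mweight,
                         params$min_density, params$min_edge_weight)
    match <- res$match; mweight <- res$mweight
  }
  u_all <- which(match >= 0L) - 1L
  sel <- u_all[u_all < match[u_all + 1L]]
  structure(list(pairs = data.frame(u = sel, v = match[sel + 1L],
                                    weight = mweight[sel + 1L]),
                 unmatched = which(match < 0L) - 1L,
                 match = match),
            class = "hem_matching")
}

#' Matched-node ratio
#'
#' Ratio of the number of successfully matched nodes to graph size,
#' `2 * |pairs| / |V|`; the coarsening termination statistic.
#'
#' @param matching a [hem_match()] result.
#' @param g the graph the matching was computed on.
#' @return fraction in `[0, 1]`.
#' @export
match_ratio <- function(matching, g) {
  stopifnot(inherits(matching, "hem_matching"), inherits(g, "overlap_graph"))
  if (g$n == 0) stop("match_ratio is undefined on an empty graph")
  2 * nrow(matching$pairs) / g$n
}

#' Contract a matching into the next coarsening level
#'
#' Supernode ids are assigned by scanning old ids in ascending order,
#' allocating a new id at the first-seen member of each matched pair and at
#' each unmatched node. For a pair `(u, v)` with edge weight `w`, the new
#' supernode gets `nw = nw_u + nw_v` and `ew = ew_u + ew_v + w`; unmatched
#' nodes carry their values over. Old edges are relabeled through the node
#' map, edges whose endpoints collapse onto the same supernode are dropped,
#' parallel edges are merged with summed weights, and the new edge sets are
#' re-sorted. Identity scores are not propagated to coarse levels.
#'
#' @param g graph being contracted.
#' @param matching a [hem_match()] result on `g`.
#' @param node_weights,edge_weights bookkeeping arrays for `g`.
#' @return list with the new level's `graph`, `node_weights`,
#'   `edge_weights`, `node_map_inverse` (length `2 * |V_new|`, -1 sentinel
#'   for a missing second child), plus `node_map` giving each old node's
#'   supernode label (to be attached to the parent level).
#' @export
contract <- function(g, matching, node_weights = rep(1, g$n),
                     edge_weights = rep(0, g$n)) {
  stopifnot(inherits(g, "overlap_graph"), inherits(matching, "hem_matching"),
            length(matching$match) == g$n)
  n <- g$n
  match <- matching$match
  nodes0 <- 0:(n - 1L)
  ok <- which(match >= 0L)
  if (length(ok) &&
      (any(match[ok] == nodes0[ok]) ||
       any(match[match[ok] + 1L] != nodes0[ok])))
    stop("inconsistent matching: partner arrays disagree")
  first_seen <- match < 0L | match > nodes0
  node_map <- integer(n)
  node_map[first_seen] <- seq_len(sum(first_seen)) - 1L
  node_map[!first_seen] <- node_map[match[!first_seen] + 1L]
  n2 <- sum(first_seen)

  first_nodes <- nodes0[first_seen]
  nw2 <- as.numeric(node_weights[first_nodes + 1L])
  ew2 <- as.numeric(edge_weights[first_nodes + 1L])
  second_nodes <- nodes0[!first_seen]
  inv <- rep.int(-1L, 2L * n2)
  inv[2L * node_map[first_nodes + 1L] + 1L] <- first_nodes
  if (length(second_nodes)) {
    z2 <- node_map[second_nodes + 1L]
    nw2[z2 + 1L] <- nw2[z2 + 1L] + node_weights[second_nodes + 1L]
    # matched edge weight: mweight was stored per node in the matching pairs
    wvec <- numeric(n)
    wvec[matching$pairs$u + 1L] <- matching$pairs$weight
    wvec[matching$pairs$v + 1L] <- matching$pairs$weight
    ew2[z2 + 1L] <- ew2[z2 + 1L] + edge_weights[second_nodes + 1L] +
      wvec[second_nodes + 1L]
    inv[2L * z2 + 2L] <- second_nodes
  }

  et <- edge_table(g)
  if (nrow(et)) {
    mu <- node_map[et$src + 1L]; mv <- node_map[et$dst + 1L]
    keep <- mu != mv
    edges2 <- merge_parallel_edges(data.frame(src = mu[keep], dst = mv[keep],
                                              weight = et$weight[keep]))
  } else {
    edges2 <- data.frame(src = integer(0), dst = integer(0),
                         weight = numeric(0))
  }
  list(graph = new_overlap_graph(n2, edges2),
       node_weights = nw2, edge_weights = ew2,
       node_map = node_map, node_map_inverse = inv)
}

#' Multilevel graph coarsening by Heavy Edge Matching
#'
#' Iterates [hem_match()] and [contract()], producing a series of coarsened
#' graphs `G_0, G_1, ..., G_N` with per-level bookkeeping arrays
#' (`node_weights`, `edge_weights`, `node_map`, `node_map_inverse`).
#' Coarsening terminates when the [match_ratio()] falls below
#' `min_match_ratio` or after `max_iterations`. Deterministic given
#' `params$seed`.
#'
#' @param g0 the level-0 overlap graph (each node is one read: `nw = 1`,
#'   `ew = 0`).
#' @param params a [coarsen_params()] object.
#' @param out_dir optional directory; when given every level is persisted
#'   via [write_level()].
#' @return an object of class `coarsen_hierarchy`: list with `levels` (each
#'   a list `graph`, `node_weights`, `edge_weights`, `node_map`,
#'   `node_map_inverse`), `params`, `seed` and a per-level `stats` data
#'   frame (`level`, `nodes`, `edges`, `match_ratio`).
#' @export
coarsen <- function(g0, params = coarsen_params(), out_dir = NULL) {
  stopifnot(inherits(g0, "overlap_graph"), inherits(params, "coarsen_params"))
  set.seed(params$seed)
  levels <- list(list(graph = g0,
                      node_weights = rep.int(1, g0$n),
                      edge_weights = rep.int(0, g0$n),
                      node_map = NULL, node_map_inverse = NULL))
  ratios <- numeric(0)
  if (g0$n > 0) {
    for (it in seq_len(params$max_iterations)) {
      cur <- levels[[length(levels)]]
      m <- hem_match(cur$graph, cur$node_weights, cur$edge_weights, params)
      r <- match_ratio(m, cur$graph)
      if (r < params$min_match_ratio) break
      ratios <- c(ratios, r)
      ctr <- contract(cur$graph, m, cur$node_weights, cur$edge_weights)
      levels[[length(levels)]]$node_map <- ctr$node_map
      levels[[length(levels) + 1L]] <-
        list(graph = ctr$graph, node_weights = ctr$node_weights,
             edge_weights = ctr$edge_weights,
             node_map = NULL, node_map_inverse = ctr$node_map_inverse)
    }
  }
  nlev <- length(levels)
  stats <- data.frame(
    level = seq_len(nlev) - 1L,
    nodes = vapply(levels, function(l) l$graph$n, integer(1)),
    edges = vapply(levels, function(l) l$graph$m, integer(1)),
    match_ratio = c(ratios, rep(NA_real_, nlev - length(ratios))))
  h <- structure(list(levels = levels, params = params, seed = params$seed,
                      n_levels = nlev, stats = stats),
                 class = "coarsen_hierarchy")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nlev)) write_level(levels[[i]], out_dir, i - 1L)
  }
  h
}

#' Load a persisted hierarchy
#'
#' Reads consecutive `level_<i>/` directories written by [coarsen()] (or
#' [write_level()]) back into a `coarsen_hierarchy`.
#'
#' @param dir hierarchy directory.
#' @return a `coarsen_hierarchy` (with `params` unset).
#' @export
read_hierarchy <- function(dir) {
  levels <- list()
  i <- 0L
  while (dir.exists(level_dir(dir, i))) {
    levels[[i + 1L]] <- read_level(dir, i)
    i <- i + 1L
  }
  if (!length(levels)) stop("no level_0 directory under ", dir)
  stats <- data.frame(
    level = seq_along(levels) - 1L,
    nodes = vapply(levels, function(l) l$graph$n, integer(1)),
    edges = vapply(levels, function(l) l$graph$m, integer(1)),
    match_ratio = NA_real_)
  structure(list(levels = levels, params = NULL, seed = NA_integer_,
                 n_levels = length(levels), stats = stats),
            class = "coarsen_hierarchy")
}

#' @export
print.coarsen_hierarchy <- function(x, ...) {
  cat("coarsen_hierarchy with", x$n_levels, "levels",
      sprintf("(G_0: %d nodes, %d edges; G_%d: %d nodes, %d edges)\n",
              x$stats$nodes[1], x$stats$edges[1], x$n_levels - 1L,
              x$stats$nodes[x$n_levels], x$stats$edges[x$n_levels]))
  invisible(x)
}

#' @export
summary.coarsen_hierarchy <- function(object, ...) {
  cat("Multilevel overlap-graph coarsening\n")
  if (!is.null(object$params))
    cat(sprintf("  min_density = %g, min_match_ratio = %g, seed = %d\n",
                object$params$min_density, object$params$min_match_ratio,
                object$seed))
  cat(sprintf("  node fold-reduction: %.2f; edge fold-reduction: %.2f\n",
              object$stats$nodes[1] / object$stats$nodes[object$n_levels],
              if (object$stats$edges[object$n_levels] > 0)
                object$stats$edges[1] / object$stats$edges[object$n_levels]
              else NA_real_))
  print(object$stats, row.names = FALSE)
  invisible(object$stats)
}

#' @export
as.data.frame.coarsen_hierarchy <- function(x, ...) x$stats

#' @export
plot.coarsen_hierarchy <- function(x, ...) {
  s <- x$stats
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(s$level, s$nodes, type = "b", xlab = "coarsening iteration",
       ylab = "nodes", main = "Node counts", ...)
  plot(s$level, s$edges, type = "b", xlab = "coarsening iteration",
       ylab = "edges", main = "Edge counts", ...)
  invisible(x)
}
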