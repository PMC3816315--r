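toy_hierarchy <- function(n = 30, p = 0.25, seed = 2) {
  set.seed(seed)
  g0 <- random_graph(n, p = p)
  coarsen(g0, coarsen_params(min_density = 0, seed = seed))
}

test_that("supernode expansion descends the inverse maps to read ids", {
  h <- toy_hierarchy()
  expect_equal(expand_to_reads(h, 0, 7), 7L)   # level 0 is the identity
  expect_error(expand_to_reads(h, 0, 10000), "out of range")
  # hand-traced two-level descent
  g0 <- new_overlap_graph(3, data.frame(src = c(0L, 1L), dst = c(1L, 2L),
                                        weight = c(9, 5)))
  hh <- coarsen(g0, coarsen_params(min_density = 0, seed = 3))
  z_pair <- which(hh$levels[[2]]$node_weights == 2) - 1L
  kids <- hh$levels[[2]]$node_map_inverse[c(2 * z_pair + 1, 2 * z_pair + 2)]
  expect_equal(sort(expand_to_reads(hh, 1, z_pair)), sort(kids))

  # cluster sizes equal node weights at every level
  for (lv in seq_len(h$n_levels) - 1L) {
    nw <- h$levels[[lv + 1L]]$node_weights
    for (z in seq_along(nw) - 1L)
      expect_length(expand_to_reads(h, lv, z), nw[z + 1L])
  }
})

test_that("clusters form a partition consistent with both recovery routes", {
  h <- toy_hierarchy(n = 40, seed = 5)
  n0 <- h$levels[[1]]$graph$n
  for (lv in seq_len(h$n_levels) - 1L) {
    cs <- clusters_at(h, lv)
    expect_equal(sort(unlist(cs$clusters, use.names = FALSE)), 0:(n0 - 1L))
    expect_equal(unname(lengths(cs$clusters)[as.character(
      seq_along(h$levels[[lv + 1L]]$node_weights) - 1L)]),
      as.vector(h$levels[[lv + 1L]]$node_weights))
    # node_map composition agrees with node_map_inverse descent
    for (z in as.integer(names(cs$clusters)[1:min(5, length(cs$clusters))]))
      expect_equal(sort(cs$clusters[[as.character(z)]]),
                   expand_to_reads(h, lv, z))
  }
  expect_equal(length(clusters_at(h, 0)$clusters), n0)  # all singletons
})

test_that("majority voting labels clusters and scores the error rate", {
  fake <- function(assignment) {
    structure(list(level = 1L, assignment = assignment,
                   clusters = split(seq_along(assignment) - 1L, assignment),
                   n_reads = length(assignment)),
              class = "cluster_set")
  }
  cs <- fake(c(0L, 0L, 0L, 1L, 1L))
  expect_equal(majority_labels(cs, c("A", "A", "B", "C", "C")),
               c("0" = "A", "1" = "C"))
  expect_equal(error_rate(cs, c("A", "A", "B", "C", "C")), 20)
  # {A, A, B} in one cluster -> 1 of 3 misclassified
  expect_equal(error_rate(fake(c(0L, 0L, 0L)), c("A", "A", "B")), 100 / 3)
  # ties break to the lexicographically smallest label
  expect_equal(majority_labels(fake(c(0L, 0L)), c("B", "A")), c("0" = "A"))
  # singletons are always pure
  expect_equal(error_rate(fake(0:4), c("A", "B", "A", "C", "B")), 0)
  expect_error(majority_labels(cs, c("A", NA, "B", "C", "C")), "truth label")
})

test_that("pure coarse clusters stay pure at finer levels", {
  reads <- tiny_metagenome(n_genomes = 2, genome_length = 4000,
                           coverage = 10, seed = 17)
  ov <- overlap_all(reads)
  h <- coarsen(build_graph(reads$n_reads, ov), coarsen_params(seed = 18))
  errs <- vapply(seq_len(h$n_levels) - 1L, function(l)
    error_rate(clusters_at(h, l), reads$labels), numeric(1))
  # refinement safety: if the deepest level is pure, all finer ones are
  if (errs[h$n_levels] == 0) expect_true(all(errs == 0))
  expect_true(all(diff(errs) >= 0 | errs[-1] == 0))
})

test_that("reduced-graph traversal emits a permutation of the reads", {
  g0 <- path_graph(c(5, 4))
  h <- coarsen(g0, coarsen_params(min_density = 0, seed = 1,
                                  max_iterations = 1))
  expect_equal(traversal_order(h, 0), c(0L, 1L, 2L))

  h2 <- toy_hierarchy(n = 35, p = 0.1, seed = 7)  # likely disconnected
  for (lv in seq_len(h2$n_levels) - 1L) {
    ord <- traversal_order(h2, lv)
    expect_setequal(ord, 0:34)
    expect_length(ord, 35)
    ordd <- traversal_order(h2, lv, method = "dfs")
    expect_setequal(ordd, 0:34)
  }
})

test_that("relabeling preserves the graph and improves locality", {
  set.seed(21)
  g <- random_graph(30, p = 0.2)
  same <- relabel_edges(g, 0:29)
  expect_identical(edge_table(same)[, c("src", "dst", "weight")],
                   edge_table(g)[, c("src", "dst", "weight")])

  perm <- sample(0:29)
  rel <- relabel_edges(g, perm)
  expect_equal(sort(table(c(edge_table(rel)$src, edge_table(rel)$dst))),
               sort(table(c(edge_table(g)$src, edge_table(g)$dst))),
               ignore_attr = TRUE)
  expect_equal(total_edge_weight(rel), total_edge_weight(g))
  expect_error(relabel_edges(g, c(0:28, 28L)), "permutation")

  # on a two-genome metagenome, traversal relabeling does not hurt locality
  reads <- tiny_metagenome(n_genomes = 2, genome_length = 5000,
                           coverage = 10, seed = 23)
  ov <- overlap_all(reads)
  g0 <- build_graph(reads$n_reads, ov)
  h <- coarsen(g0, coarsen_params(seed = 24))
  ord <- traversal_order(h, h$n_levels - 1L)
  rel2 <- relabel_edges(g0, ord)
  expect_lte(attr(rel2, "locality_after"), attr(rel2, "locality_before"))
})
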