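# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: naive suffix sorting, quadratic full-matrix
# overlap DP, base-R edit distance, and brute-force graph checks.

# naive suffix array: radix (byte-order) sort of all suffixes
naive_suffix_array <- function(text) {
  n <- nchar(text)
  order(substring(text, 1:n, n), method = "radix") - 1L
}

random_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# full-matrix overlap (free end gap) alignment, unit scores, with traceback.
# Ties: diagonal > up > left; terminal cell scanned last column (ascending
# row) then last row (ascending column), first strict maximum kept --
# mirrors the documented convention so column counts are comparable.
overlap_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  S <- matrix(0, la + 1, lb + 1)
  for (i in seq_len(la) + 1L) {
    sub <- ifelse(A[i - 1] == B & A[i - 1] != "N", 1, -1)
    for (j in seq_len(lb) + 1L) {
      S[i, j] <- max(S[i - 1, j - 1] + sub[j - 1], S[i - 1, j] - 1,
                     S[i, j - 1] - 1)
    }
  }
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 1:(la + 1)) if (S[i, lb + 1] > best) {
    best <- S[i, lb + 1]; bi <- i - 1L; bj <- lb
  }
  for (j in 1:(lb + 1)) if (S[la + 1, j] > best) {
    best <- S[la + 1, j]; bi <- la; bj <- j - 1L
  }
  i <- bi; j <- bj; columns <- 0L; matches <- 0L
  while (i > 0 && j > 0) {
    diag_sc <- S[i, j] + (if (A[i] == B[j] && A[i] != "N") 1 else -1)
    if (S[i + 1, j + 1] == diag_sc) {
      columns <- columns + 1L
      if (A[i] == B[j] && A[i] != "N") matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 1) {
      columns <- columns + 1L; i <- i - 1L
    } else if (S[i + 1, j + 1] == S[i + 1, j] - 1) {
      columns <- columns + 1L; j <- j - 1L
    } else break  # free boundary (score did not come from a move)
  }
  list(score = best, columns = columns, matches = matches,
       identity = if (columns > 0) 100 * matches / columns else NA_real_)
}

# all k-mers of a string
kmer_set <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
}

shares_kmer <- function(a, b, k) length(intersect(kmer_set(a, k),
                                                  kmer_set(b, k))) > 0

# brute-force all-pairs overlap enumeration: full DP on every pair sharing
# an exact k-mer, thresholded on length and identity
naive_overlap_all <- function(seqs, k, min_len, min_id) {
  n <- length(seqs)
  out <- list()
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (!shares_kmer(seqs[u], seqs[v], k)) next
    r <- overlap_dp(seqs[u], seqs[v])
    if (r$columns >= min_len && r$identity >= min_id)
      out[[length(out) + 1L]] <- data.frame(
        query_id = u - 1L, ref_id = v - 1L,
        alignment_length = r$columns, identity = r$identity)
  }
  if (!length(out))
    return(data.frame(query_id = integer(0), ref_id = integer(0),
                      alignment_length = integer(0), identity = numeric(0)))
  do.call(rbind, out)
}

# random undirected weighted graph with distinct integer-ish weights
random_graph <- function(n, p = 0.08, wmax = 100) {
  pairs <- expand.grid(src = 0:(n - 1), dst = 0:(n - 1))
  pairs <- pairs[pairs$src < pairs$dst, ]
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  edges$weight <- sample.int(wmax, nrow(edges), replace = TRUE)
  new_overlap_graph(n, edges)
}

# structural invariants of the CSR overlap graph
expect_valid_graph <- function(g) {
  expect_true(all(diff(g$offsets) >= 0))
  expect_identical(g$offsets[length(g$offsets)], 2L * g$m)
  src <- rep.int(0:(g$n - 1L), diff(g$offsets))
  expect_false(any(src == g$dst))
  # sorted edge sets: weights nonincreasing within each node
  if (g$m > 0) {
    same <- src[-1] == src[-length(src)]
    expect_true(all(diff(g$weight)[same] <= 0))
  }
  # symmetry: each undirected edge appears once per endpoint, equal weights
  fw <- paste(pmin(src, g$dst), pmax(src, g$dst), g$weight)
  expect_true(all(table(fw) == 2))
}

# matching validity + constrained maximality (brute force)
expect_valid_matching <- function(m, g, nw, ew, params) {
  pr <- m$pairs
  nodes <- c(pr$u, pr$v)
  expect_false(any(duplicated(nodes)))             # no shared endpoints
  et <- edge_table(g)
  ek <- paste(et$src, et$dst)
  if (nrow(pr))
    expect_true(all(paste(pr$u, pr$v) %in% ek))    # pairs are edges
  # maximality: no eligible edge (weight >= floor, density > threshold)
  # with both endpoints unmatched
  matched <- rep(FALSE, g$n); matched[nodes + 1L] <- TRUE
  free <- !matched[et$src + 1L] & !matched[et$dst + 1L]
  if (any(free)) {
    fe <- et[free, , drop = FALSE]
    dens <- edge_density(nw[fe$src + 1L], ew[fe$src + 1L],
                         nw[fe$dst + 1L], ew[fe$dst + 1L], fe$weight)
    eligible <- fe$weight >= params$min_edge_weight &
      dens > params$min_density
    expect_false(any(eligible))
  }
  invisible(TRUE)
}

# path graph 0 - 1 - ... - n with the given consecutive edge weights
path_graph <- function(weights) {
  n <- length(weights) + 1L
  new_overlap_graph(n, data.frame(src = 0:(n - 2L), dst = 1:(n - 1L),
                                  weight = weights))
}

# small simulated metagenome shortcut used across tests
tiny_metagenome <- function(n_genomes = 2, genome_length = 5000,
                            coverage = 10, seed = 1, ...) {
  spec <- metagenome_spec(n_genomes = n_genomes,
                          genome_length = genome_length,
                          coverage = coverage, seed = seed, ...)
  simulate_reads(generate_genomes(spec), spec)
}

# hash all regular files under a directory (for byte-identity checks)
dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) paste(tools::md5sum(f)), character(1))
}
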