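test_that("suffix arrays match naive suffix sorting", {
  expect_equal(build_suffix_array("banana"), c(5L, 3L, 1L, 0L, 4L, 2L))
  expect_equal(build_suffix_array("AAA"), c(2L, 1L, 0L))
  expect_equal(build_suffix_array("G"), 0L)
  set.seed(2)
  for (rep in 1:50) {
    s <- random_string(sample(2:300, 1),
                       alphabet = c("A", "C", "G", "T", "N", "$"))
    expect_equal(build_suffix_array(s), naive_suffix_array(s))
  }
})

test_that("the read index inverts concatenation at every position", {
  idx <- build_index(read_set(c("AC", "GT")))
  expect_equal(idx$text, "AC$GT$")
  expect_equal(position_to_read(idx, 3)$read_id, 1L)
  expect_equal(position_to_read(idx, 3)$offset, 0L)
  expect_true(is.na(position_to_read(idx, 2)$read_id))  # sentinel

  one <- build_index(read_set("ACGTT"))
  expect_equal(position_to_read(one, 0:4)$offset, 0:4)

  set.seed(3)
  rs <- read_set(replicate(50, random_string(sample(20:60, 1))))
  idx <- build_index(rs)
  for (r in seq_len(50)) {
    for (o in c(0L, idx$read_len[r] - 1L)) {
      hit <- position_to_read(idx, idx$read_start[r] + o)
      expect_equal(hit$read_id, r - 1L)
      expect_equal(hit$offset, o)
    }
  }
  # every non-sentinel position round-trips
  all_pos <- position_to_read(idx, 0:(nchar(idx$text) - 1L))
  expect_equal(sum(!is.na(all_pos$read_id)), sum(idx$read_len))
})

test_that("seed hits agree with a brute-force substring scan", {
  ref <- "TTTTACGTACGGAATTCCGGAATT"
  q <- "ACGTACGG"
  idx <- build_index(read_set(c(q, ref)))
  hits <- find_seed_hits(idx, 0, k = 8)
  expect_true(nrow(hits) >= 1)
  expect_true(all(hits$ref_id == 1))
  expect_true(any(hits$query_offset == 0 & hits$diagonal == 4))

  idx_n <- build_index(read_set(c("NNNNNNNN", ref)))
  expect_equal(nrow(find_seed_hits(idx_n, 0, k = 8)), 0)

  # two identical reads: a hit on diagonal 0 for every component seed
  s <- random_string(30)
  idx2 <- build_index(read_set(c(s, s)))
  h2 <- find_seed_hits(idx2, 0, k = 4)
  d0 <- h2[h2$diagonal == 0, ]
  expect_setequal(d0$query_offset, 0:26)

  # brute-force cross-check on random reads
  set.seed(8)
  rs <- read_set(c(random_string(40), random_string(40), random_string(40)))
  idx3 <- build_index(rs)
  k <- 5
  h3 <- find_seed_hits(idx3, 0, k = k)
  got <- unique(h3[, c("ref_id", "query_offset", "diagonal")])
  want <- list()
  for (o in 0:(40 - k)) {
    pat <- substr(rs$sequences[1], o + 1, o + k)
    for (r in 2:3) {
      seq_r <- rs$sequences[r]
      for (ro in 0:(40 - k)) {
        if (substr(seq_r, ro + 1, ro + k) == pat)
          want[[length(want) + 1L]] <- data.frame(
            ref_id = r - 1L, query_offset = o, diagonal = ro - o)
      }
    }
  }
  want <- if (length(want)) unique(do.call(rbind, want)) else
    data.frame(ref_id = integer(0), query_offset = integer(0),
               diagonal = integer(0))
  expect_equal(got[order(got$ref_id, got$query_offset, got$diagonal), ],
               want[order(want$ref_id, want$query_offset, want$diagonal), ],
               ignore_attr = TRUE)
})

test_that("q-gram filter passes identical windows and rejects alien ones", {
  expect_true(qgram_pass("ACGTACGT", "ACGTACGT", 4, 0))
  expect_false(qgram_pass(strrep("A", 30), strrep("C", 30), 4, 1))
  # threshold <= 0 always passes
  expect_true(qgram_pass("AAAA", "CCCC", 4, 2))
})

test_that("q-gram filter is sound for pairs within the error budget", {
  set.seed(5)
  for (rep in 1:100) {
    w <- sample(40:90, 1)
    e <- sample(0:4, 1)
    a <- random_string(w)
    b <- a
    for (i in seq_len(e)) {   # apply up to e random substitutions
      pos <- sample(nchar(b), 1)
      substr(b, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    }
    d <- adist(a, b)[1, 1]
    expect_lte(d, e)
    expect_true(qgram_pass(a, b, 8, e))
  }
})

test_that("banded alignment reproduces the documented examples", {
  a <- random_string(50)
  al <- banded_overlap_align(a, a, 0, 4)
  expect_equal(al$identity, 100)
  expect_equal(al$alignment_length, 50L)

  al2 <- banded_overlap_align("ACGT", "ACGA", 0, 4)
  expect_equal(al2$alignment_length, 4L)
  expect_equal(al2$identity, 75)

  # suffix-prefix overlap found on its diagonal
  left <- random_string(60)
  right <- paste0(substr(left, 21, 60), random_string(20))
  al3 <- banded_overlap_align(left, right, -20, 4)
  expect_equal(al3$alignment_length, 40L)
  expect_equal(al3$identity, 100)
  expect_equal(al3$a_interval, c(20L, 60L))
  expect_equal(al3$b_interval, c(0L, 40L))
})

test_that("full-band banded alignment equals quadratic overlap DP", {
  set.seed(6)
  for (rep in 1:40) {
    la <- sample(30:80, 1); lb <- sample(30:80, 1)
    a <- random_string(la)
    b <- if (runif(1) < 0.5) {
      ov <- sample(10:min(la, lb), 1)  # plant a noisy suffix-prefix overlap
      paste0(apply_substitutions(substr(a, la - ov + 1, la), 0.05),
             random_string(lb - ov))
    } else random_string(lb)
    res <- banded_overlap_align(a, b, 0, max(la, lb))
    ref <- overlap_dp(a, b)
    expect_equal(res$score, ref$score)
    expect_equal(res$alignment_length, ref$columns)
    expect_equal(res$matches, ref$matches)
  }
})

test_that("overlap_all finds a planted suffix-prefix overlap exactly once", {
  set.seed(7)
  a <- random_string(100)
  b <- paste0(substr(a, 41, 100), random_string(40))
  ov <- overlap_all(read_set(c(a, b)), overlap_params())
  expect_equal(nrow(ov), 1)
  expect_equal(ov$alignment_length, 60L)
  expect_equal(ov$identity, 100)
  expect_setequal(c(ov$query_id, ov$ref_id), c(0L, 1L))

  # unrelated reads with no shared k-mer produce nothing
  ov2 <- overlap_all(read_set(c(random_string(100), random_string(100))),
                     overlap_params())
  expect_equal(nrow(ov2), 0)
})

test_that("the overlap set is invariant under read-file order reversal", {
  set.seed(10)
  reads <- tiny_metagenome(n_genomes = 1, genome_length = 2000,
                           coverage = 8, seed = 31,
                           substitution_rate = 0.002)
  fwd <- overlap_all(reads, overlap_params())
  rev_rs <- read_set(rev(reads$sequences))
  bwd <- overlap_all(rev_rs, overlap_params())
  n <- reads$n_reads
  canon <- function(tbl, remap = FALSE) {
    q <- tbl$query_id; r <- tbl$ref_id
    if (remap) { q <- n - 1L - q; r <- n - 1L - r }
    key <- paste(pmin(q, r), pmax(q, r), tbl$alignment_length)
    sort(key)
  }
  expect_equal(canon(fwd), canon(bwd, remap = TRUE))
})
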