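#' Simulated metagenome specification
#'
#' Describes a synthetic metagenome experiment: several reference genomes
#' with controllable pairwise homology, reads sampled at a target
#' fold-coverage with fixed length (Illumina-like, 100 bp) or Gaussian
#' length (454-like, ~440 bp mean), i.i.d. substitution errors, and per-read
#' ground-truth genome labels.
#'
#' @param n_genomes number of reference genomes.
#' @param genome_length genome length in bp (scalar, recycled, or one per
#'   genome).
#' @param homology_pairs optional list of 2-element integer vectors (1-based
#'   genome indices) that share an ancestral segment.
#' @param shared_fraction fraction in `[0, 1]` of each paired genome copied
#'   from a common ancestor segment.
#' @param divergence per-base substitution rate applied independently to each
#'   copy of the shared segment (each copy is mutated at `divergence/2`, so
#'   the expected pairwise divergence of the copies is about `divergence`).
#' @param coverage fold-coverage per genome (> 0).
#' @param read_length_model either `list(type = "fixed", length = 100)` or
#'   `list(type = "gaussian", mean = 440, sd = 40, min = 50)`.
#' @param substitution_rate per-base sequencing-error probability.
#' @param reverse_complement if `TRUE`, each read is reverse-complemented
#'   with probability 1/2 (off by default; forward strand only).
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   seed.
#' @return a list of class `metagenome_spec`.
#' @export
metagenome_spec <- function(n_genomes = 4, genome_length = 50000,
                            homology_pairs = NULL, shared_fraction = 0.1,
                            divergence = 0.05, coverage = 15,
                            read_length_model = list(type = "fixed",
                                                     length = 100),
                            substitution_rate = 0.005,
                            reverse_complement = FALSE, seed = 1) {
  stopifnot(n_genomes >= 1, coverage > 0,
            shared_fraction >= 0, shared_fraction <= 1,
            divergence >= 0, divergence <= 1,
            substitution_rate >= 0, substitution_rate <= 1)
  genome_length <- rep_len(as.integer(genome_length), n_genomes)
  rlm <- read_length_model
  if (!rlm$type %in% c("fixed", "gaussian"))
    stop("read_length_model$type must be 'fixed' or 'gaussian'")
  mean_len <- if (rlm$type == "fixed") rlm$length else rlm$mean
  if (any(genome_length < mean_len))
    stop("genome length must be at least the (mean) read length")
  if (!is.null(homology_pairs)) {
    for (p in homology_pairs)
      if (length(p) != 2 || any(p < 1) || any(p > n_genomes) || p[1] == p[2])
        stop("homology_pairs must be pairs of distinct genome indices in ",
             "1..n_genomes")
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = genome_length,
                 homology_pairs = homology_pairs,
                 shared_fraction = shared_fraction,
                 divergence = divergence,
                 coverage = coverage,
                 read_length_model = rlm,
                 substitution_rate = substitution_rate,
                 reverse_complement = reverse_complement,
                 seed = as.integer(seed)),
            class = "metagenome_spec")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Apply i.i.d. substitution errors
#'
#' Each base is independently replaced, with probability `rate`, by a
#' uniformly chosen different base (an `N` becomes one of `A`, `C`, `G`).
#' Lengths are preserved. Uses the current RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param sequences character vector of sequences.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return the mutated sequences.
#' @export
apply_substitutions <- function(sequences, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (!length(sequences) || rate == 0) return(sequences)
  lens <- nchar(sequences)
  chars <- strsplit(paste(sequences, collapse = ""), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",   # A -> C/G/T
                    "A", "G", "T",   # C
                    "A", "C", "T",   # G
                    "A", "C", "G",   # T
                    "A", "C", "G"),  # N
                  nrow = 5, byrow = TRUE)
    row <- match(chars[hit], c("A", "C", "G", "T", "N"))
    chars[hit] <- alt[cbind(row, sample.int(3, length(hit), replace = TRUE))]
  }
  big <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' Generate reference genomes
#'
#' Draws `n_genomes` i.i.d.-random A/C/G/T genomes. For each homology pair,
#' a common ancestor segment of length `shared_fraction * genome_length` is
#' generated and a copy is written into each genome of the pair at a random
#' position, after independent mutation at `divergence/2` per copy.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [metagenome_spec()].
#' @return named character vector of genome sequences
#'   (`genome_1`, `genome_2`, ...).
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "metagenome_spec"))
  set.seed(spec$seed)
  genomes <- vapply(spec$genome_length, random_dna, character(1))
  names(genomes) <- paste0("genome_", seq_len(spec$n_genomes))
  for (p in spec$homology_pairs) {
    li <- spec$genome_length[p[1]]; lj <- spec$genome_length[p[2]]
    seg_len <- floor(spec$shared_fraction * min(li, lj))
    if (seg_len == 0) next
    if (seg_len > li || seg_len > lj)
      stop("shared segment longer than genome")
    ancestor <- random_dna(seg_len)
    for (gi in p) {
      L <- spec$genome_length[gi]
      s <- sample.int(L - seg_len + 1L, 1L)
      copy <- apply_substitutions(ancestor, spec$divergence / 2)
      substr(genomes[gi], s, s + seg_len - 1L) <- copy
    }
  }
  genomes
}

#' Simulate reads from genomes
#'
#' Per genome `i`, `n_i = floor(coverage * L_i / mean_read_length)` reads are
#' drawn with uniform start positions and fixed or truncated-Gaussian
#' lengths; substitution errors are applied i.i.d. at `substitution_rate`;
#' each read carries its source genome as ground-truth label. Deterministic
#' given `spec$seed`.
#'
#' @param genomes named character vector from [generate_genomes()].
#' @param spec a [metagenome_spec()].
#' @return a [read_set()] with `labels` filled in.
#' @export
simulate_reads <- function(genomes, spec) {
  stopifnot(inherits(spec, "metagenome_spec"), length(genomes) >= 1)
  set.seed(spec$seed + 1L)
  rlm <- spec$read_length_model
  mean_len <- if (rlm$type == "fixed") rlm$length else rlm$mean
  all_reads <- character(0); all_labels <- character(0)
  for (gi in seq_along(genomes)) {
    L <- nchar(genomes[[gi]])
    n_i <- floor(spec$coverage * L / mean_len)
    if (n_i == 0) next
    if (rlm$type == "fixed") {
      if (rlm$length > L) stop("read longer than genome")
      lens <- rep.int(as.integer(rlm$length), n_i)
    } else {
      lens <- as.integer(round(rnorm(n_i, rlm$mean, rlm$sd)))
      lens <- pmax(as.integer(rlm$min), pmin(lens, L))
    }
    starts <- floor(runif(n_i) * (L - lens + 1)) + 1L
    all_reads <- c(all_reads, substring(genomes[[gi]], starts,
                                        starts + lens - 1L))
    all_labels <- c(all_labels,
                    rep.int(names(genomes)[gi] %||% as.character(gi), n_i))
  }
  if (spec$substitution_rate > 0)
    all_reads <- apply_substitutions(all_reads, spec$substitution_rate)
  if (isTRUE(spec$reverse_complement) && length(all_reads)) {
    flip <- runif(length(all_reads)) < 0.5
    if (any(flip))
      all_reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(all_reads[flip])))
  }
  read_set(all_reads, ids = paste0("read_", seq_along(all_reads) - 1L),
           labels = all_labels)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
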