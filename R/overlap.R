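#' Overlap detection parameters
#'
#' @param k exact-match seed length in bp.
#' @param q q-gram length for the pre-filter; `1 <= q <= k`.
#' @param band half-width of the alignment band, in diagonals around the seed
#'   diagonal.
#' @param min_overlap_length minimum accepted alignment length in bp.
#' @param min_identity minimum accepted percent identity in `[0, 100]`. The
#'   q-gram filter's error budget is derived from it as
#'   `ceil((1 - min_identity/100) * w)` for a window of length `w`.
#' @param stride seed stride; 1 enumerates all `l - k + 1` component k-mers
#'   of a length-`l` read, larger values seed more sparsely.
#' @return a list of class `overlap_params`.
#' @export
overlap_params <- function(k = 16, q = 8, band = 8, min_overlap_length = 50,
                           min_identity = 90, stride = 1) {
  stopifnot(k >= 1, q >= 1, q <= k, band >= 1, min_overlap_length >= 1,
            min_identity >= 0, min_identity <= 100, stride >= 1)
  structure(list(k = as.integer(k), q = as.integer(q),
                 band = as.integer(band),
                 min_overlap_length = as.integer(min_overlap_length),
                 min_identity = as.numeric(min_identity),
                 stride = as.integer(stride)),
            class = "overlap_params")
}

#' Suffix array construction
#'
#' Lexicographically sorted start positions of all suffixes of `text`
#' (0-based), comparing bytes in C-locale order. Prefix-doubling
#' construction, O(n log n).
#'
#' @param text a non-empty string.
#' @return integer vector of 0-based suffix start positions.
#' @export
build_suffix_array <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nchar(text) > 0)
  .sa_build_cpp(text)
}

#' Suffix-array read index
#'
#' Concatenates all reads into a single string with a sentinel `$` after
#' each read, indexes it with a suffix array, and keeps boundary arrays that
#' invert the concatenation (text position to read id and offset).
#'
#' @param reads a [read_set()] with at least one read.
#' @return an object of class `sa_index` with fields `text`, `sa`,
#'   `read_start` (0-based), `read_len` and `n_reads`.
#' @export
build_index <- function(reads) {
  stopifnot(inherits(reads, "read_set"), reads$n_reads >= 1)
  if (any(grepl("$", reads$sequences, fixed = TRUE)))
    stop("sentinel '$' must not occur inside a read")
  lens <- nchar(reads$sequences)
  text <- paste0(paste0(reads$sequences, collapse = "$"), "$")
  start <- c(0L, cumsum(lens[-length(lens)] + 1L))
  structure(list(text = text, sa = .sa_build_cpp(text),
                 read_start = as.integer(start), read_len = as.integer(lens),
                 n_reads = reads$n_reads),
            class = "sa_index")
}

#' Map a text position back to (read id, offset)
#'
#' @param index an [build_index()] object.
#' @param pos 0-based position(s) in the concatenated text.
#' @return data frame with columns `read_id` and `offset` (both 0-based);
#'   sentinel positions map to `NA`.
#' @export
position_to_read <- function(index, pos) {
  stopifnot(inherits(index, "sa_index"))
  rid <- findInterval(pos, index$read_start) - 1L
  off <- pos - index$read_start[rid + 1L]
  sentinel <- off >= index$read_len[rid + 1L] | pos < 0
  rid[sentinel] <- NA_integer_
  off[sentinel] <- NA_integer_
  data.frame(read_id = rid, offset = off)
}

#' Exact k-mer seed hits for one query read
#'
#' Binary-searches the suffix array for every component k-mer of the query;
#' each occurrence in a different read becomes a seed hit. K-mers containing
#' `N` (or spanning a sentinel) produce no hits; self-read hits are excluded.
#'
#' @param index an [build_index()] object.
#' @param query_id 0-based read id.
#' @param k seed length (`k <=` query length).
#' @param stride seed stride (default 1 = all component k-mers).
#' @return data frame with columns `query_id`, `ref_id`, `query_offset`,
#'   `ref_text_position`, `diagonal` (ref offset minus query offset).
#' @export
find_seed_hits <- function(index, query_id, k, stride = 1) {
  stopifnot(inherits(index, "sa_index"),
            query_id >= 0, query_id < index$n_reads,
            k >= 1, k <= index$read_len[query_id + 1L])
  hits <- .find_seed_hits_cpp(index$text, index$sa, index$read_start,
                              index$read_len, as.integer(query_id),
                              as.integer(k), as.integer(stride))
  cbind(data.frame(query_id = rep(as.integer(query_id), nrow(hits))), hits)
}

#' q-gram pre-filter
#'
#' Counts q-grams common to both windows (multiset intersection) and passes
#' iff the count reaches `w + 1 - q * (max_errors + 1)` with
#' `w = min(nchar(a), nchar(b))`; a threshold `<= 0` always passes. By the
#' q-gram lemma the filter never rejects a pair of windows within
#' `max_errors` edit operations.
#'
#' @param a,b candidate overlap windows (strings).
#' @param q q-gram length.
#' @param max_errors edit-operation budget.
#' @return `TRUE` if the pair passes the filter.
#' @export
qgram_pass <- function(a, b, q, max_errors) {
  stopifnot(length(a) == 1, length(b) == 1, q >= 1, max_errors >= 0)
  .qgram_pass_cpp(a, b, as.integer(q), as.integer(max_errors))
}

#' Banded overlap alignment
#'
#' Dynamic-programming alignment of `a` against `b` restricted to diagonals
#' within `band` of the seed `diagonal` (ref offset minus query offset), with
#' free end gaps (overlap-style: the unaligned prefix of one read and suffix
#' of the other are unpenalized) and unit scoring (match +1, mismatch -1,
#' gap -1; `N` never matches). With `band >= max(nchar(a), nchar(b))` the
#' result equals unrestricted overlap alignment.
#'
#' @param a,b read sequences.
#' @param diagonal seed diagonal.
#' @param band band half-width (>= 1).
#' @return `NULL` when the band admits no alignment or the overlap window is
#'   degenerate; otherwise a list with `score`, `alignment_length` (column
#'   count), `matches`, `identity` (percent), and 0-based half-open
#'   `a_interval` / `b_interval`.
#' @export
banded_overlap_align <- function(a, b, diagonal, band) {
  stopifnot(length(a) == 1, length(b) == 1, band >= 1)
  res <- .banded_overlap_cpp(a, b, as.integer(diagonal), as.integer(band))
  if (!length(res)) return(NULL)
  list(score = res[1], alignment_length = as.integer(res[2]),
       matches = as.integer(res[3]),
       identity = 100 * res[3] / res[2],
       a_interval = as.integer(res[4:5]), b_interval = as.integer(res[6:7]))
}

#' Detect all pairwise read overlaps
#'
#' For each read in succession: component k-mer seeds are searched in the
#' suffix array; candidate (reference, diagonal) pairs are deduplicated
#' (each unordered read pair is evaluated once); candidate overlap windows
#' pass through the q-gram filter; survivors are extended by banded overlap
#' alignment. An overlap is kept iff its alignment length is at least
#' `min_overlap_length` and its identity at least `min_identity`; the best
#' alignment is kept when several seed diagonal clusters hit the same pair.
#' Deterministic for fixed input.
#'
#' @param reads a [read_set()].
#' @param params an [overlap_params()] object.
#' @return an [overlap_table()]; attribute `n_candidates` carries the number
#'   of candidate pair/diagonal-cluster alignments attempted.
#' @export
overlap_all <- function(reads, params = overlap_params()) {
  stopifnot(inherits(reads, "read_set"), inherits(params, "overlap_params"))
  if (reads$n_reads < 2) {
    out <- overlap_table()
    attr(out, "n_candidates") <- 0
    return(out)
  }
  index <- build_index(reads)
  res <- .overlap_all_cpp(index$text, index$sa, index$read_start,
                          index$read_len, params$k, params$q, params$band,
                          params$min_overlap_length, params$min_identity,
                          params$stride)
  out <- overlap_table(res$query_id, res$ref_id, res$alignment_length,
                       res$identity)
  attr(out, "n_candidates") <- res$n_candidates
  out
}
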