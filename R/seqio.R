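#' Read sets
#'
#' A `read_set` holds uppercase read sequences over `{A,C,G,T,N}`, external
#' read names, optional per-read ground-truth genome labels and optional
#' Phred+33 quality strings. Internal read ids are `0..n_reads-1` in storage
#' order and correspond one-to-one with the node labels of the level-0
#' overlap graph.
#'
#' @param sequences character vector of read sequences (non-empty strings).
#' @param ids external read names; defaults to `read_0`, `read_1`, ...
#' @param labels optional per-read source-genome identifiers (ground truth).
#' @param qualities optional Phred+33 quality strings, same lengths as
#'   `sequences`.
#' @return an object of class `read_set` with fields `sequences`, `ids`,
#'   `labels`, `qualities` and `n_reads`.
#' @export
read_set <- function(sequences, ids = NULL, labels = NULL, qualities = NULL) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  bad <- which(!nzchar(sequences))
  if (length(bad))
    stop("empty sequence at record index ", bad[1])
  if (is.null(ids)) ids <- paste0("read_", seq_len(n) - 1L)
  if (length(ids) != n) stop("ids must have one entry per sequence")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per sequence")
  if (!is.null(qualities)) {
    if (length(qualities) != n)
      stop("qualities must have one entry per sequence")
    mism <- which(nchar(qualities) != nchar(sequences))
    if (length(mism))
      stop("quality length mismatch at record index ", mism[1])
  }
  structure(list(sequences = sequences, ids = as.character(ids),
                 labels = labels, qualities = qualities, n_reads = n),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", x$n_reads, "reads")
  if (x$n_reads > 0)
    cat("; lengths", min(nchar(x$sequences)), "-", max(nchar(x$sequences)))
  if (!is.null(x$labels))
    cat("; ", length(unique(x$labels)), " truth labels", sep = "")
  cat("\n")
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads get internal ids `0, 1, 2, ...` in file order; sequences are
#' uppercased. FASTQ qualities are interpreted as Phred+33 and kept on the
#' returned object. An empty file yields an empty `read_set`.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by file extension).
#' @return a [read_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0)
    return(read_set(character(0), ids = character(0)))
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("failed to parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
    read_set(as.character(x), ids = sub("\\s.*$", "", names(x)))
  } else {
    x <- tryCatch(suppressWarnings(
                    Biostrings::readQualityScaledDNAStringSet(path)),
                  error = function(e)
                    stop("failed to parse FASTQ file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
    read_set(as.character(x), ids = sub("\\s.*$", "", names(x)),
             qualities = as.character(Biostrings::quality(x)))
  }
}

#' Write a read set to FASTA or FASTQ
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires qualities; missing
#'   qualities are written as the maximum score `"I"`).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "read_set"))
  x <- Biostrings::DNAStringSet(reads$sequences)
  names(x) <- reads$ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  } else {
    qual <- reads$qualities
    if (is.null(qual))
      qual <- vapply(nchar(reads$sequences),
                     function(l) strrep("I", l), character(1))
    qx <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(qx, path)
  }
  invisible(path)
}

#' Trim low-quality read ends
#'
#' Removes the longest prefix and suffix such that both terminal bases of the
#' result have quality at least `min_quality`; interior bases are untouched.
#' May return an empty read.
#'
#' @param read a single sequence string.
#' @param qualities Phred quality values for `read`: either an integer vector
#'   or a Phred+33 encoded character string of the same length.
#' @param min_quality minimum terminal base quality (default 20).
#' @return the trimmed read (possibly `""`).
#' @export
trim_low_quality_ends <- function(read, qualities, min_quality = 20) {
  stopifnot(length(read) == 1, min_quality >= 0)
  if (is.character(qualities)) {
    stopifnot(length(qualities) == 1)
    qualities <- utf8ToInt(qualities) - 33L
  }
  if (length(qualities) != nchar(read))
    stop("qualities length (", length(qualities),
         ") does not match read length (", nchar(read), ")")
  ok <- which(qualities >= min_quality)
  if (!length(ok)) return("")
  substr(read, min(ok), max(ok))
}

#' Overlap tables
#'
#' An `overlap_table` records accepted pairwise overlaps: internal read ids
#' `query_id`/`ref_id` (0-based), alignment length in bp and percent identity.
#' Each unordered read pair appears at most once and self-overlaps are
#' rejected.
#'
#' @param query_id,ref_id integer read ids (0-based).
#' @param alignment_length alignment column counts (>= 1).
#' @param identity percent identities in `[0, 100]`.
#' @return a data frame of class `overlap_table`.
#' @export
overlap_table <- function(query_id = integer(0), ref_id = integer(0),
                          alignment_length = integer(0),
                          identity = numeric(0)) {
  tbl <- data.frame(query_id = as.integer(query_id),
                    ref_id = as.integer(ref_id),
                    alignment_length = as.integer(alignment_length),
                    identity = as.numeric(identity))
  validate_overlap_table(tbl)
  class(tbl) <- c("overlap_table", "data.frame")
  tbl
}

validate_overlap_table <- function(tbl) {
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (any(tbl$query_id == tbl$ref_id))
    stop("self-overlap (query_id == ref_id) at row ",
         which(tbl$query_id == tbl$ref_id)[1])
  if (any(tbl$alignment_length < 1))
    stop("alignment_length must be >= 1")
  if (any(tbl$identity < 0 | tbl$identity > 100))
    stop("identity must be within [0, 100]")
  key <- paste(pmin(tbl$query_id, tbl$ref_id),
               pmax(tbl$query_id, tbl$ref_id))
  if (anyDuplicated(key))
    stop("duplicate unordered read pair at row ", which(duplicated(key))[1])
  invisible(tbl)
}

#' Write / read an overlap edge list
#'
#' Tab-separated columns `query_id`, `ref_id`, `alignment_length`,
#' `identity`, with a `#`-prefixed header line. Identity is serialized as a
#' percentage with 2 decimal places; the round trip is lossless at that
#' precision.
#'
#' @param overlaps an [overlap_table()].
#' @param path file path.
#' @return `write_overlaps()` returns `path` invisibly; `read_overlaps()`
#'   returns an [overlap_table()].
#' @export
write_overlaps <- function(overlaps, path) {
  validate_overlap_table(overlaps)
  header <- "#query_id\tref_id\talignment_length\tidentity"
  if (nrow(overlaps) == 0) {
    writeLines(header, path)
  } else {
    rows <- sprintf("%d\t%d\t%d\t%.2f", overlaps$query_id, overlaps$ref_id,
                    overlaps$alignment_length, overlaps$identity)
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' @rdname write_overlaps
#' @export
read_overlaps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body_idx))
    return(overlap_table())
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4))
    stop("malformed overlap row at line ", body_idx[which(nf != 4)[1]],
         ": expected 4 tab-separated fields")
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  suppressWarnings({
    qv <- as.integer(m[, 1]); rv <- as.integer(m[, 2])
    lv <- as.integer(m[, 3]); iv <- as.numeric(m[, 4])
  })
  bad <- which(is.na(qv) | is.na(rv) | is.na(lv) | is.na(iv))
  if (length(bad))
    stop("malformed overlap row at line ", body_idx[bad[1]],
         ": non-numeric field")
  overlap_table(qv, rv, lv, iv)
}

#' Write / read ground-truth read labels
#'
#' Tab-separated `read_id` (0-based internal id) and `genome_id` with a
#' `#`-prefixed header.
#'
#' @param labels character vector of per-read genome labels, in read-id order.
#' @param path file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the character vector of labels in read-id order.
#' @export
write_truth <- function(labels, path) {
  writeLines(c("#read_id\tgenome_id",
               sprintf("%d\t%s", seq_along(labels) - 1L, labels)), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- as.integer(vapply(parts, `[[`, character(1), 1L))
  labs <- vapply(parts, `[[`, character(1), 2L)
  labs[order(ids)]
}

level_dir <- function(dir, i) file.path(dir, sprintf("level_%d", i))

write_int_column <- function(x, name, path) {
  writeLines(c(paste0("#", name),
               format(x, scientific = FALSE, trim = TRUE)), path)
}

read_int_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(numeric(0))
  as.numeric(lines)
}

#' Persist / load one coarsening level
#'
#' Each level is a directory `level_<i>/` holding a unique-pair edge list
#' (`edges.tsv`: src, dst, weight and, at level 0, identity) plus flat arrays
#' `node_weights.tsv`, `edge_weights.tsv`, and, where present, `node_map.tsv`
#' and `node_map_inverse.tsv`. The round trip is lossless (identity at 2
#' decimal places).
#'
#' @param level a list with fields `graph`, `node_weights`, `edge_weights`,
#'   and optionally `node_map`, `node_map_inverse` (as produced by
#'   [coarsen()]).
#' @param dir hierarchy directory.
#' @param i level index (0-based).
#' @return `write_level()` returns the level directory invisibly;
#'   `read_level()` returns the level list.
#' @export
write_level <- function(level, dir, i) {
  g <- level$graph
  n <- g$n
  stopifnot(length(level$node_weights) == n, length(level$edge_weights) == n)
  if (!is.null(level$node_map_inverse) &&
      length(level$node_map_inverse) != 2L * n)
    stop("node_map_inverse must have length 2*|V| (got ",
         length(level$node_map_inverse), ", |V| = ", n, ")")
  d <- level_dir(dir, i)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  et <- edge_table(g)
  if (!is.null(et$identity)) {
    writeLines(c("#src\tdst\tweight\tidentity",
                 sprintf("%d\t%d\t%s\t%.2f", et$src, et$dst,
                         format(et$weight, scientific = FALSE, trim = TRUE),
                         et$identity)),
               file.path(d, "edges.tsv"))
  } else {
    writeLines(c("#src\tdst\tweight",
                 sprintf("%d\t%d\t%s", et$src, et$dst,
                         format(et$weight, scientific = FALSE, trim = TRUE))),
               file.path(d, "edges.tsv"))
  }
  write_int_column(level$node_weights, "node_weights",
                   file.path(d, "node_weights.tsv"))
  write_int_column(level$edge_weights, "edge_weights",
                   file.path(d, "edge_weights.tsv"))
  if (!is.null(level$node_map))
    write_int_column(level$node_map, "node_map", file.path(d, "node_map.tsv"))
  if (!is.null(level$node_map_inverse))
    write_int_column(level$node_map_inverse, "node_map_inverse",
                     file.path(d, "node_map_inverse.tsv"))
  invisible(d)
}

#' @rdname write_level
#' @export
read_level <- function(dir, i) {
  d <- level_dir(dir, i)
  needed <- c("edges.tsv", "node_weights.tsv", "edge_weights.tsv")
  for (f in needed)
    if (!file.exists(file.path(d, f)))
      stop("missing level file: ", file.path(d, f))
  nw <- read_int_column(file.path(d, "node_weights.tsv"))
  ew <- read_int_column(file.path(d, "edge_weights.tsv"))
  n <- length(nw)
  lines <- readLines(file.path(d, "edges.tsv"))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop("malformed edge row in ", file.path(d, "edges.tsv"))
    m <- matrix(unlist(lapply(parts, `[`, 1:3)), ncol = 3, byrow = TRUE)
    edges <- data.frame(src = as.integer(m[, 1]), dst = as.integer(m[, 2]),
                        weight = as.numeric(m[, 3]))
    if (all(nf == 4))
      edges$identity <- as.numeric(vapply(parts, `[[`, character(1), 4L))
  } else {
    edges <- data.frame(src = integer(0), dst = integer(0),
                        weight = numeric(0))
  }
  level <- list(graph = new_overlap_graph(n, edges),
                node_weights = nw, edge_weights = ew,
                node_map = NULL, node_map_inverse = NULL)
  nm <- file.path(d, "node_map.tsv")
  if (file.exists(nm)) level$node_map <- as.integer(read_int_column(nm))
  nmi <- file.path(d, "node_map_inverse.tsv")
  if (file.exists(nmi)) {
    v <- as.integer(read_int_column(nmi))
    if (length(v) != 2L * n)
      stop("node_map_inverse in ", nmi, " must have length 2*|V| (got ",
           length(v), ", |V| = ", n, ")")
    level$node_map_inverse <- v
  }
  level
}
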