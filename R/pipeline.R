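#' Pipeline run configuration
#'
#' A flat configuration for the end-to-end workflow
#' (simulate -> overlap -> coarsen -> clusters -> eval). Either `reads`
#' points at an existing FASTA/FASTQ file (with optional `truth` labels), or
#' the simulated-metagenome generator is used with the `n_genomes` /
#' `genome_length` / `coverage` / `substitution_rate` fields. A single
#' global `seed` fans out to fixed per-stage seeds (simulation: `seed`,
#' coarsening: `seed + 1`) so stages are independently reproducible.
#'
#' @param out_dir run directory (created if needed).
#' @param seed global RNG seed.
#' @param reads,truth,overlaps optional input paths (FASTA/FASTQ, truth TSV,
#'   precomputed overlap TSV); when `reads` is `NULL` a metagenome is
#'   simulated.
#' @param n_genomes,genome_length,coverage,substitution_rate,read_length
#'   simulation settings (see [metagenome_spec()]); `read_length` is the
#'   fixed Illumina-like read length.
#' @param k,q,band,min_overlap_length,min_identity,stride overlap settings
#'   (see [overlap_params()]).
#' @param min_density,min_match_ratio,min_edge_weight,passes,max_iterations
#'   coarsening settings (see [coarsen_params()]).
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       reads = NULL, truth = NULL, overlaps = NULL,
                       n_genomes = 4, genome_length = 50000, coverage = 15,
                       substitution_rate = 0.005, read_length = 100,
                       k = 16, q = 8, band = 8, min_overlap_length = 50,
                       min_identity = 90, stride = 1,
                       min_density = 50, min_match_ratio = 0.01,
                       min_edge_weight = 0, passes = 1,
                       max_iterations = 50) {
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a flat key=value run configuration file
#'
#' @param path config file; one `key=value` per line, `#` comments allowed.
#' @param config a [run_config()].
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) < 2)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  cfg <- do.call(run_config, list(out_dir = "."))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    cfg[[k]] <- if (!is.na(num)) num else v
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- !vapply(config, is.null, logical(1))
  writeLines(paste0(names(config)[keep], "=",
                    vapply(config[keep], function(v)
                      format(v, scientific = FALSE, trim = TRUE),
                      character(1))), path)
  invisible(path)
}

#' Write / read a cluster table
#'
#' Tab-separated `read_id` (0-based) and `cluster_id` with a `#`-prefixed
#' header.
#'
#' @param clusters a [clusters_at()] result.
#' @param path file path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns the integer cluster assignment in read-id order.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  writeLines(c("#read_id\tcluster_id",
               sprintf("%d\t%d", seq_len(clusters$n_reads) - 1L,
                       clusters$assignment)), path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(integer(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- as.integer(vapply(parts, `[[`, character(1), 1L))
  cl <- as.integer(vapply(parts, `[[`, character(1), 2L))
  cl[order(ids)]
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Simulates (or loads) reads, detects overlaps, builds and coarsens the
#' overlap graph, extracts clusters at the final level, and writes a
#' per-iteration report with node counts, edge counts and - when truth
#' labels are available - majority-vote error rates. Fully deterministic
#' given the config seed.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress (default `TRUE`).
#' @return invisibly, a list with `reads`, `overlaps`, `graph`, `hierarchy`,
#'   `report` (data frame) and `dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  truth <- NULL
  reads <- run_stage("reads", {
    if (!is.null(config$reads)) {
      rs <- read_sequences(config$reads)
      if (!is.null(config$truth)) truth <- read_truth(config$truth)
      rs
    } else {
      spec <- metagenome_spec(
        n_genomes = config$n_genomes, genome_length = config$genome_length,
        coverage = config$coverage,
        read_length_model = list(type = "fixed",
                                 length = config$read_length),
        substitution_rate = config$substitution_rate, seed = config$seed)
      genomes <- generate_genomes(spec)
      rs <- simulate_reads(genomes, spec)
      truth <- rs$labels
      write_sequences(rs, file.path(config$out_dir, "reads.fasta"))
      write_truth(truth, file.path(config$out_dir, "truth.tsv"))
      rs
    }
  })
  say("reads: ", reads$n_reads)

  overlaps <- run_stage("overlap", {
    if (!is.null(config$overlaps)) read_overlaps(config$overlaps)
    else {
      ov <- overlap_all(reads, overlap_params(
        k = config$k, q = config$q, band = config$band,
        min_overlap_length = config$min_overlap_length,
        min_identity = config$min_identity, stride = config$stride))
      write_overlaps(ov, file.path(config$out_dir, "overlaps.tsv"))
      ov
    }
  })
  say("overlaps: ", nrow(overlaps), " accepted (",
      format(attr(overlaps, "n_candidates") %||% NA, trim = TRUE),
      " candidates)")

  g0 <- run_stage("graph", build_graph(reads$n_reads, overlaps))
  hierarchy <- run_stage("coarsen", coarsen(
    g0,
    coarsen_params(min_density = config$min_density,
                   min_match_ratio = config$min_match_ratio,
                   min_edge_weight = config$min_edge_weight,
                   passes = config$passes, seed = config$seed + 1,
                   max_iterations = config$max_iterations),
    out_dir = file.path(config$out_dir, "hierarchy")))
  for (i in seq_len(hierarchy$n_levels))
    say(sprintf("iteration %d: %d nodes, %d edges", i - 1L,
                hierarchy$stats$nodes[i], hierarchy$stats$edges[i]))

  report <- run_stage("clusters", {
    rep_df <- hierarchy$stats[, c("level", "nodes", "edges")]
    if (!is.null(truth) && length(truth) == reads$n_reads) {
      rep_df$error_rate <- vapply(rep_df$level, function(l)
        error_rate(clusters_at(hierarchy, l), truth), numeric(1))
    }
    final <- clusters_at(hierarchy, hierarchy$n_levels - 1L)
    write_clusters(final, file.path(config$out_dir, "clusters.tsv"))
    rep_df
  })
  run_stage("report", {
    out <- report
    if (!is.null(out$error_rate))
      out$error_rate <- sprintf("%.4f", out$error_rate)
    con <- file.path(config$out_dir, "report.tsv")
    writeLines(c(paste0("#", paste(names(out), collapse = "\t")),
                 do.call(paste, c(unname(as.list(out)), sep = "\t"))), con)
  })
  say("done: ", config$out_dir)
  invisible(list(reads = reads, overlaps = overlaps, graph = g0,
                 hierarchy = hierarchy, report = report,
                 dir = config$out_dir))
}
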