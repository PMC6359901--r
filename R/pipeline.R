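# End-to-end orchestration of the three phases, behind a run_config.

#' Pipeline run configuration
#'
#' @param forward,reverse IUPAC primer strings.
#' @param inputs character vector of read files (FASTA/FASTQ, optionally
#'   gzipped) or glob patterns.
#' @param output output FASTA path for the assembled amplicons.
#' @param k_min smallest k-mer length (>= 16; default 32).
#' @param k_step ladder increment (default 8).
#' @param min_count denoising count floor (default 2; use 1 for depth-1 data).
#' @param variant_ratio Hamming-1 dominance ratio for denoising (default 10).
#' @param max_mismatches primer-match mismatch tolerance (default 0).
#' @param max_amplicon_length,lookahead_budget,max_loop_visits,rng_seed see
#'   [extension_config()].
#' @param stats_path optional TSV path for the decision-statistics report.
#' @return object of class `run_config`.
#' @export
run_config <- function(forward, reverse, inputs, output,
                       k_min = 32L, k_step = 8L,
                       min_count = 2L, variant_ratio = 10,
                       max_mismatches = 0L,
                       max_amplicon_length = 5000L,
                       lookahead_budget = 500L,
                       max_loop_visits = 4L,
                       rng_seed = 1L,
                       stats_path = NULL) {
  if (missing(forward) || missing(reverse) ||
      !nzchar(forward) || !nzchar(reverse))
    stop("both a forward and a reverse primer are required", call. = FALSE)
  if (k_min < 16L) stop("k_min must be >= 16", call. = FALSE)
  structure(list(
    forward = forward, reverse = reverse,
    inputs = inputs, output = output,
    k_min = as.integer(k_min), k_step = as.integer(k_step),
    min_count = as.integer(min_count), variant_ratio = variant_ratio,
    max_mismatches = as.integer(max_mismatches),
    max_amplicon_length = as.integer(max_amplicon_length),
    lookahead_budget = as.integer(lookahead_budget),
    max_loop_visits = as.integer(max_loop_visits),
    rng_seed = as.integer(rng_seed),
    stats_path = stats_path
  ), class = "run_config")
}

# modal value of an integer vector (ties: smallest)
.modal <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Run the full pipeline
#'
#' Reads the inputs, selects and orients the reads covering the inter-primer
#' region (phase 1), builds and denoises the k-mer table ladder (phase 2),
#' extends every starting read (phase 3), and writes the terminated,
#' primer-trimmed amplicons as FASTA. Zero amplicons is a warning, not an
#' error.
#'
#' @param config a [run_config()].
#' @param reads optional named character vector of reads, bypassing file
#'   input (inputs are then ignored).
#' @return (invisibly) a list: `n_reads`, `n_region`, `n_starting`,
#'   `n_extended`, `n_abandoned`, `output`, `stats` (a `decision_stats`),
#'   `results` (per-read extension outcomes).
#' @export
run_pipeline <- function(config, reads = NULL) {
  stopifnot(inherits(config, "run_config"))
  ctx <- primer_pair_context(config$forward, config$reverse,
                             max_mismatches = config$max_mismatches)
  if (is.null(reads)) reads <- read_sequences(config$inputs)
  message(sprintf("phase 1: %d reads in, filtering on %d-mers",
                  length(reads), config$k_min))
  empty_summary <- function(stats = NULL) {
    write_fasta(character(0), config$output)
    warning("no amplicons assembled; wrote an empty FASTA", call. = FALSE)
    invisible(list(n_reads = length(reads), n_region = 0L, n_starting = 0L,
                   n_extended = 0L, n_abandoned = 0L,
                   output = config$output, stats = stats,
                   results = NULL))
  }
  if (!length(reads)) return(empty_summary())
  ph1 <- filter_region_reads(reads, ctx, k = config$k_min)
  region <- ph1$region_reads
  n_starting <- sum(region$is_starting)
  message(sprintf("phase 1: %d region reads (%d starting), %d filter rounds",
                  nrow(region), n_starting, ph1$rounds))
  if (!nrow(region) || !n_starting) return(empty_summary())
  ks <- k_values(.modal(nchar(region$bases)), config$k_min, config$k_step)
  if (!length(ks)) ks <- config$k_min  # all reads trimmed below k_min
  ladder <- build_ladder(region$bases, ks)
  ladder <- denoise_ladder(ladder, min_count = config$min_count,
                           variant_ratio = config$variant_ratio)
  message(sprintf("phase 2: ladder k = %s; denoised sizes = %s",
                  paste(ladder$ks, collapse = ","),
                  paste(vapply(ladder$tables, kt_size, integer(1)),
                        collapse = ",")))
  cfg <- extension_config(max_amplicon_length = config$max_amplicon_length,
                          lookahead_budget = config$lookahead_budget,
                          max_loop_visits = config$max_loop_visits,
                          rng_seed = config$rng_seed)
  ext <- extend_all(region, ladder, ctx, cfg)
  ok <- ext$results[ext$results$terminated, , drop = FALSE]
  message(sprintf("phase 3: %d/%d starting reads fully extended",
                  nrow(ok), n_starting))
  if (nrow(ok)) {
    out <- stats::setNames(ok$sequence,
                           sprintf("amplicon_%d source=%s length=%d",
                                   seq_len(nrow(ok)), ok$source_id,
                                   nchar(ok$sequence)))
    write_fasta(out, config$output)
  } else {
    write_fasta(character(0), config$output)
    warning("no amplicons assembled; wrote an empty FASTA", call. = FALSE)
  }
  if (!is.null(config$stats_path))
    utils::write.table(stats_table(ext$stats), config$stats_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(n_reads = length(reads), n_region = nrow(region),
                 n_starting = n_starting, n_extended = nrow(ok),
                 n_abandoned = ext$stats$abandoned,
                 output = config$output, stats = ext$stats,
                 results = ext$results))
}
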