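# Phase 1: iteratively grow the inter-primer 32-mer filter, then select,
# orient, trim and mark the reads that cover the primer-defined region.
#
# All retained reads are canonicalised into extension orientation (the
# forward strand of the amplicon); WGS reads are unstranded so both
# orientations of every read are considered throughout.

# Locate the starting primer in a read, trying extension orientation first.
# Returns NULL, or list(bases = oriented read, at = 0-based offset of the
# forward-primer match within it).
.orient_starting <- function(read, ctx) {
  off <- .first_primer_offset(read, ctx$start_fwd, ctx$max_mismatches)
  if (!is.na(off)) return(list(bases = read, at = off))
  # reverse strand: read ends with RC(F); flip it into extension orientation
  off <- .first_primer_offset(read, ctx$start_rc, ctx$max_mismatches)
  if (!is.na(off)) {
    rc <- reverse_complement(read)
    off <- .first_primer_offset(rc, ctx$start_fwd, ctx$max_mismatches)
    if (!is.na(off)) return(list(bases = rc, at = off))
  }
  NULL
}

# Same for the finishing primer (RC(R) in extension orientation, R on the
# reverse strand). Returns NULL or list(bases, at).
.orient_finishing <- function(read, ctx) {
  off <- .first_primer_offset(read, ctx$finish_fwd, ctx$max_mismatches)
  if (!is.na(off)) return(list(bases = read, at = off))
  off <- .first_primer_offset(read, ctx$finish_rc, ctx$max_mismatches)
  if (!is.na(off)) {
    rc <- reverse_complement(read)
    off <- .first_primer_offset(rc, ctx$finish_fwd, ctx$max_mismatches)
    if (!is.na(off)) return(list(bases = rc, at = off))
  }
  NULL
}

# Truncate an oriented read just after a finishing-primer match, if any.
# k-mers past the finishing primer must never enter the filter or the tables:
# extension has to stop at the primer.
.clip_after_finishing <- function(bases, ctx) {
  off <- .first_primer_offset(bases, ctx$finish_fwd, ctx$max_mismatches)
  if (is.na(off)) list(bases = bases, finished = FALSE)
  else list(bases = substr(bases, 1L, off + ctx$finish_fwd$length),
            finished = TRUE)
}

#' Seed the inter-primer k-mer filter
#'
#' Finds every read that carries the forward primer (on either strand),
#' reorients it into extension orientation, and adds all N-free `k`-windows of
#' the post-primer tail (clipped after any finishing-primer match) to the
#' filter.
#'
#' @param reads character vector of A/C/G/T/N reads.
#' @param ctx a [primer_pair_context()].
#' @param k filter k-mer length (default 32).
#' @return list with `filter` (k-mer hash set environment), `n_starting`
#'   (number of seeding reads) and `k`. An empty pool of primer-bearing reads
#'   yields an empty filter and `n_starting = 0`, not an error.
#' @export
seed_filter <- function(reads, ctx, k = 32L) {
  filter <- new_kmer_set()
  n_starting <- 0L
  for (read in reads) {
    o <- .orient_starting(read, ctx)
    if (is.null(o)) next
    n_starting <- n_starting + 1L
    tail <- substr(o$bases, o$at + ctx$start_fwd$length + 1L, nchar(o$bases))
    tail <- .clip_after_finishing(tail, ctx)$bases
    ks_add(filter, tile_windows(tail, k))
  }
  if (n_starting == 0L)
    warning("no read contains a starting primer; the region filter is empty",
            call. = FALSE)
  list(filter = filter, n_starting = n_starting, k = as.integer(k))
}

#' Grow the inter-primer filter to a fixed point
#'
#' Repeated passes over the read pool: any read whose first `k`-mer (in either
#' orientation) is already in the filter contributes all its `k`-windows
#' (clipped after a finishing-primer match). Passes repeat until no new k-mer
#' is added -- coverage of the whole inter-primer region is complete at the
#' fixed point -- with a hard cap on rounds.
#'
#' @param reads character vector of reads.
#' @param filter k-mer hash set from [seed_filter()] (its `filter` element).
#' @param ctx a [primer_pair_context()] (used to clip past finishing primers);
#'   `NULL` disables clipping.
#' @param k filter k-mer length.
#' @param max_rounds safety cap on passes (default 100).
#' @return the filter environment, with attributes `rounds` (passes executed,
#'   including the final no-change pass) and `reads_matched`.
#' @export
grow_filter <- function(reads, filter, ctx = NULL, k = 32L, max_rounds = 100L) {
  rc <- reverse_complement(reads)
  first_f <- substr(reads, 1L, k)
  first_r <- substr(rc, 1L, k)
  pending <- which(nchar(reads) >= k)
  matched <- 0L
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    before <- ks_size(filter)
    still <- integer(0)
    for (i in pending) {
      bases <- if (ks_has(filter, first_f[i])) reads[i]
               else if (ks_has(filter, first_r[i])) rc[i]
               else { still <- c(still, i); next }
      if (!is.null(ctx)) bases <- .clip_after_finishing(bases, ctx)$bases
      ks_add(filter, tile_windows(bases, k))
      matched <- matched + 1L
    }
    pending <- still
    added <- ks_size(filter) - before
    message(sprintf("filter round %d: +%d k-mers (%d total), %d reads matched",
                    rounds, added, ks_size(filter), matched))
    if (added == 0L) break
    if (rounds >= max_rounds) {
      warning("region filter did not reach a fixed point within ",
              max_rounds, " rounds", call. = FALSE)
      break
    }
  }
  attr(filter, "rounds") <- rounds
  attr(filter, "reads_matched") <- matched
  filter
}

#' Select, orient, trim and mark the region reads
#'
#' Retains reads whose first `k`-mer (either orientation) is in the filter, or
#' that carry a starting/finishing primer. Retained reads are reported in
#' extension orientation with primers trimmed: a starting read keeps the bases
#' strictly after the forward primer (`is_starting = TRUE` when that tail is
#' at least `k` long, so it can seed an extension); any read is clipped just
#' *after* a finishing-primer match, keeping the primer so the extender can
#' terminate on it (it is removed again from the final amplicons). Reads
#' shorter than `k` after trimming are kept only if they carry a finishing
#' primer.
#'
#' @param reads character vector of reads; names (if any) are carried through
#'   as `source_id`.
#' @param filter k-mer hash set from [grow_filter()].
#' @param ctx a [primer_pair_context()].
#' @param k filter k-mer length.
#' @return data.frame with columns `source_id`, `bases`, `is_starting`,
#'   `had_finishing_primer`.
#' @export
select_and_trim <- function(reads, filter, ctx, k = 32L) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  rows <- vector("list", length(reads))
  n <- 0L
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    o <- .orient_starting(read, ctx)
    if (!is.null(o)) {
      tail <- substr(o$bases, o$at + ctx$start_fwd$length + 1L, nchar(o$bases))
      cl <- .clip_after_finishing(tail, ctx)
      if (nchar(cl$bases) < k && !cl$finished) next  # too short to use
      n <- n + 1L
      rows[[n]] <- list(source_id = ids[i], bases = cl$bases,
                        is_starting = nchar(tail) >= k ||
                          (cl$finished && nchar(cl$bases) > 0L),
                        had_finishing_primer = cl$finished)
      next
    }
    o <- .orient_finishing(read, ctx)
    if (!is.null(o)) {
      bases <- substr(o$bases, 1L, o$at + ctx$finish_fwd$length)
      n <- n + 1L
      rows[[n]] <- list(source_id = ids[i], bases = bases,
                        is_starting = FALSE, had_finishing_primer = TRUE)
      next
    }
    if (nchar(read) < k) next
    bases <- if (ks_has(filter, substr(read, 1L, k))) read
             else {
               rc <- reverse_complement(read)
               if (ks_has(filter, substr(rc, 1L, k))) rc else NULL
             }
    if (is.null(bases)) next
    cl <- .clip_after_finishing(bases, ctx)
    if (nchar(cl$bases) < k && !cl$finished) next
    n <- n + 1L
    rows[[n]] <- list(source_id = ids[i], bases = cl$bases,
                      is_starting = FALSE, had_finishing_primer = cl$finished)
  }
  if (n == 0L)
    return(data.frame(source_id = character(0), bases = character(0),
                      is_starting = logical(0),
                      had_finishing_primer = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(rows[seq_len(n)], as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Run the whole phase-1 region filter
#'
#' Convenience wrapper: [seed_filter()], [grow_filter()], [select_and_trim()].
#'
#' @inheritParams select_and_trim
#' @param max_rounds cap on growth passes.
#' @return list with `region_reads` (data.frame from [select_and_trim()]),
#'   `filter`, `n_seeding`, `rounds`.
#' @export
filter_region_reads <- function(reads, ctx, k = 32L, max_rounds = 100L) {
  seeded <- seed_filter(reads, ctx, k = k)
  if (seeded$n_starting == 0L) {
    return(list(region_reads = select_and_trim(character(0), seeded$filter, ctx, k),
                filter = seeded$filter, n_seeding = 0L, rounds = 0L))
  }
  filter <- grow_filter(reads, seeded$filter, ctx = ctx, k = k,
                        max_rounds = max_rounds)
  list(region_reads = select_and_trim(reads, filter, ctx, k = k),
       filter = filter, n_seeding = seeded$n_starting,
       rounds = attr(filter, "rounds"))
}
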