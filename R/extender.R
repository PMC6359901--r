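# Phase 3: extend each starting read one base at a time until a finishing
# primer appears, disambiguating through the k-mer ladder, bounded recursive
# lookahead, and depth-proportional random tie-breaking.

#' Extension configuration
#'
#' @param max_amplicon_length hard cap on the extended length in bases
#'   (default 5000; amplicons are orders of magnitude shorter).
#' @param lookahead_budget bases a recursive downstream probe may add
#'   (default 500).
#' @param max_loop_visits times the same terminal k-mer may recur within one
#'   extension before it is abandoned as a tandem-repeat loop (default 4).
#' @param rng_seed seed for the tie-breaking draws (default 1).
#' @return object of class `extension_config`.
#' @export
extension_config <- function(max_amplicon_length = 5000L,
                             lookahead_budget = 500L,
                             max_loop_visits = 4L,
                             rng_seed = 1L) {
  cfg <- list(max_amplicon_length = as.integer(max_amplicon_length),
              lookahead_budget = as.integer(lookahead_budget),
              max_loop_visits = as.integer(max_loop_visits),
              rng_seed = as.integer(rng_seed))
  if (any(unlist(cfg) <= 0L)) stop("all config values must be positive",
                                   call. = FALSE)
  structure(cfg, class = "extension_config")
}

.BASES <- c("A", "C", "G", "T")

#' Viable single-base extensions at one k
#'
#' The bases `b` such that the last `k-1` bases of `seq` followed by `b` form
#' a k-mer present in the ladder's table at `k`.
#'
#' @param seq current extended sequence (`nchar(seq) >= k - 1`).
#' @param ladder a (denoised) `kmer_ladder`.
#' @param k which table to consult; must exist in the ladder.
#' @return character vector, a subset of `c("A","C","G","T")`.
#' @export
viable_extensions <- function(seq, ladder, k) {
  tbl <- ladder$tables[[as.character(k)]]
  if (is.null(tbl)) stop("no k-mer table at k = ", k, call. = FALSE)
  n <- nchar(seq)
  if (n < k - 1L) stop("sequence shorter than k - 1", call. = FALSE)
  prefix <- substr(seq, n - k + 2L, n)
  .BASES[vapply(.BASES, function(b) kt_has(tbl, paste0(prefix, b)),
                logical(1))]
}

#' Choose the next base, escalating through the k-mer ladder
#'
#' Starts at `k_min`; while more than one base is viable, the next (longer) k
#' is consulted, keeping only bases that were viable at every smaller k *and*
#' whose terminal k-mer exists at the longer k. If every candidate would
#' vanish at the longer k, the decision falls back to the survivors at the
#' previous k. Only k values with `nchar(seq) >= k - 1` are usable.
#'
#' @param seq current extended sequence.
#' @param ladder a denoised `kmer_ladder`.
#' @return a list: `kind` is `"single"` (with `base` and the deciding `k`),
#'   `"ambiguous"` (with `cands`, the surviving set), or `"dead_end"`.
#' @export
choose_next_base <- function(seq, ladder) {
  ks <- ladder$ks
  cands <- viable_extensions(seq, ladder, ks[1L])
  if (length(cands) == 0L) return(list(kind = "dead_end"))
  if (length(cands) == 1L)
    return(list(kind = "single", base = cands, k = ks[1L]))
  n <- nchar(seq)
  for (k in ks[-1L]) {
    if (n < k - 1L) break
    prefix <- substr(seq, n - k + 2L, n)
    tbl <- ladder$tables[[as.character(k)]]
    surv <- cands[vapply(cands, function(b) kt_has(tbl, paste0(prefix, b)),
                         logical(1))]
    if (length(surv) == 1L) return(list(kind = "single", base = surv, k = k))
    if (length(surv) == 0L) break  # longer k uninformative: keep previous set
    cands <- surv
  }
  list(kind = "ambiguous", cands = cands)
}

#' Depth-proportional random tie-break
#'
#' Samples one candidate base with probability proportional to the repetition
#' depth of its terminal k-mer: depths of 90 vs 10 pick the deeper branch 90%
#' of the time, so rarer strain variants stay represented in the output
#' instead of being subsumed.
#'
#' @param candidates non-empty character vector of bases.
#' @param depths named positive counts, at least covering `candidates`.
#' @return one element of `candidates`.
#' @export
choose_in_proportion <- function(candidates, depths) {
  if (length(candidates) == 1L) return(candidates)
  d <- as.numeric(depths[candidates])
  if (any(is.na(d) | d <= 0))
    stop("every candidate needs a positive depth", call. = FALSE)
  candidates[sample.int(length(candidates), 1L, prob = d)]
}

# --- decision statistics -----------------------------------------------------

.new_stats_env <- function(ks) {
  e <- new.env(parent = emptyenv())
  e$extension_checks <- 0
  e$single_choice_at_k <- stats::setNames(numeric(length(ks)),
                                          as.character(ks))
  e$looked_downstream <- 0
  e$single_good_downstream <- 0
  e$chose_in_proportion <- 0
  e$chose_longest_downstream <- 0
  e$starting_reads <- 0
  e$abandoned <- 0
  e$fully_extended <- 0
  e
}

.stats_as_list <- function(e) {
  structure(list(
    extension_checks = e$extension_checks,
    single_choice_at_k = e$single_choice_at_k,
    single_kmer_choice = sum(e$single_choice_at_k),
    looked_downstream = e$looked_downstream,
    single_good_downstream = e$single_good_downstream,
    chose_in_proportion = e$chose_in_proportion,
    chose_longest_downstream = e$chose_longest_downstream,
    starting_reads = e$starting_reads,
    abandoned = e$abandoned,
    fully_extended = e$fully_extended
  ), class = "decision_stats")
}

#' Decision statistics as a counter table
#'
#' One row per counter with its value and, for the per-decision counters, the
#' percentage of all extension checks it accounts for (starting-read counters
#' are expressed as a percentage of starting reads).
#'
#' @param stats a `decision_stats` list from [extend_all()].
#' @return data.frame with columns `counter`, `value`, `percent`.
#' @export
stats_table <- function(stats) {
  checks <- stats$extension_checks
  pct <- function(x, denom) if (denom > 0) round(100 * x / denom, 1) else NA_real_
  rows <- list(c("read extension checks", checks, NA))
  for (k in names(stats$single_choice_at_k))
    rows[[length(rows) + 1L]] <- c(sprintf("single choice at k = %s", k),
                                   stats$single_choice_at_k[[k]],
                                   pct(stats$single_choice_at_k[[k]], checks))
  add <- function(lbl, v, denom) rows[[length(rows) + 1L]] <<-
      c(lbl, v, pct(v, denom))
  add("single kMer choice", stats$single_kmer_choice, checks)
  add("looked downstream", stats$looked_downstream, checks)
  add("single good downstream", stats$single_good_downstream, checks)
  add("chose in proportion by depth", stats$chose_in_proportion, checks)
  add("chose longest downstream", stats$chose_longest_downstream, checks)
  rows[[length(rows) + 1L]] <- c("# of starting reads", stats$starting_reads, NA)
  add("# of reads abandoned", stats$abandoned, stats$starting_reads)
  add("# of fully extended reads", stats$fully_extended, stats$starting_reads)
  out <- data.frame(counter = vapply(rows, `[[`, character(1), 1L),
                    value = as.numeric(vapply(rows, `[`, character(1), 2L)),
                    percent = suppressWarnings(
                      as.numeric(vapply(rows, `[`, character(1), 3L))),
                    stringsAsFactors = FALSE)
  out
}

#' @export
print.decision_stats <- function(x, ...) {
  print(stats_table(x))
  invisible(x)
}

# --- the extension loop ------------------------------------------------------

# Bounded recursive probe: can `seq` be extended to a finishing primer within
# `budget` further bases? Returns list(reached, gained, soft) where `soft`
# marks a failure that might be a budget artefact (never memoised).
.lookahead <- function(seq, budget, ladder, ctx, memo) {
  fin <- ctx$finish_fwd
  k_min <- ladder$k_min
  gained <- 0L
  repeat {
    n <- nchar(seq)
    if (n >= fin$length &&
        primer_matches(substr(seq, n - fin$length + 1L, n), fin,
                       ctx$max_mismatches))
      return(list(reached = TRUE, gained = gained, soft = FALSE))
    if (gained >= budget)
      return(list(reached = FALSE, gained = gained, soft = TRUE))
    if (n < k_min - 1L)
      return(list(reached = FALSE, gained = gained, soft = FALSE))
    key <- substr(seq, n - k_min + 2L, n)
    if (exists(key, envir = memo, inherits = FALSE))
      return(list(reached = FALSE, gained = gained, soft = FALSE))
    d <- choose_next_base(seq, ladder)
    if (d$kind == "dead_end") {
      assign(key, TRUE, envir = memo)
      return(list(reached = FALSE, gained = gained, soft = FALSE))
    }
    if (d$kind == "single") {
      seq <- paste0(seq, d$base)
      gained <- gained + 1L
      next
    }
    # ambiguous: probe every branch
    reached <- FALSE; soft <- FALSE; best <- 0L
    for (b in d$cands) {
      r <- .lookahead(paste0(seq, b), budget - gained - 1L, ladder, ctx, memo)
      reached <- reached || r$reached
      soft <- soft || r$soft
      best <- max(best, 1L + r$gained)
      if (reached) break
    }
    if (!reached && !soft) assign(key, TRUE, envir = memo)
    return(list(reached = reached, gained = gained + best,
                soft = soft && !reached))
  }
}

#' Extend one starting read to a full-length amplicon
#'
#' Appends one base at a time. Each iteration first checks whether the read
#' now ends in a finishing-primer match (degenerate, per the context's
#' mismatch tolerance); the whole starting read is scanned once up front, and
#' thereafter only the freshly created terminal window needs checking. An
#' unambiguous next base is taken directly from the ladder
#' ([choose_next_base()]); when ambiguity survives the whole ladder, each
#' candidate branch is probed by bounded recursion: a single branch reaching a
#' finishing primer wins outright, several such branches are decided by
#' [choose_in_proportion()] on terminal k_min-mer depths, and if none finishes
#' the branch that got furthest is taken. Dead ends, runaway lengths and
#' k-mer loops abandon the read (`terminated = FALSE`); abandoned reads are
#' counted, never written out.
#'
#' @param start one region read: list or one-row data.frame with `bases` and
#'   `source_id` (as produced by [select_and_trim()]).
#' @param ladder denoised `kmer_ladder`.
#' @param ctx a [primer_pair_context()].
#' @param cfg an [extension_config()].
#' @param stats internal counter environment (created by [extend_all()];
#'   `NULL` for standalone calls).
#' @return list with `sequence` (inter-primer bases, primer-free when
#'   terminated), `terminated`, `bases_added`, `source_id`.
#' @export
extend_read <- function(start, ladder, ctx, cfg = extension_config(),
                        stats = NULL) {
  if (is.null(stats)) stats <- .new_stats_env(ladder$ks)
  seq <- start$bases
  source_id <- if (!is.null(start$source_id)) start$source_id else ""
  fin <- ctx$finish_fwd
  k_min <- ladder$k_min
  start_len <- nchar(seq)
  memo <- new.env(parent = emptyenv())
  visits <- new.env(parent = emptyenv())
  # a finishing primer may already sit inside the starting read
  init_off <- .first_primer_offset(seq, fin, ctx$max_mismatches)
  first <- TRUE
  finish <- function(terminated, at = NA_integer_) {
    sequence <- if (terminated) substr(seq, 1L, at) else seq
    if (terminated) stats$fully_extended <- stats$fully_extended + 1
    else stats$abandoned <- stats$abandoned + 1
    list(sequence = sequence, terminated = terminated,
         bases_added = nchar(seq) - start_len, source_id = source_id)
  }
  repeat {
    stats$extension_checks <- stats$extension_checks + 1
    n <- nchar(seq)
    if (first) {
      first <- FALSE
      if (!is.na(init_off)) return(finish(TRUE, at = init_off))
    } else if (n >= fin$length &&
               primer_matches(substr(seq, n - fin$length + 1L, n), fin,
                              ctx$max_mismatches)) {
      return(finish(TRUE, at = n - fin$length))
    }
    if (n >= cfg$max_amplicon_length) return(finish(FALSE))
    if (n < k_min - 1L) return(finish(FALSE))
    d <- choose_next_base(seq, ladder)
    if (d$kind == "dead_end") return(finish(FALSE))
    if (d$kind == "single") {
      k <- as.character(d$k)
      stats$single_choice_at_k[k] <- stats$single_choice_at_k[k] + 1
      base <- d$base
    } else {
      stats$looked_downstream <- stats$looked_downstream + 1
      probes <- lapply(d$cands, function(b) {
        .lookahead(paste0(seq, b), cfg$lookahead_budget, ladder, ctx, memo)
      })
      reached <- vapply(probes, `[[`, logical(1), "reached")
      good <- d$cands[reached]
      if (length(good) == 1L) {
        stats$single_good_downstream <- stats$single_good_downstream + 1
        base <- good
      } else {
        tbl <- ladder$tables[[as.character(k_min)]]
        prefix <- substr(seq, n - k_min + 2L, n)
        depth_of <- function(bs) stats::setNames(
          vapply(bs, function(b) kt_count(tbl, paste0(prefix, b)), integer(1)),
          bs)
        if (length(good) > 1L) {
          stats$chose_in_proportion <- stats$chose_in_proportion + 1
          base <- choose_in_proportion(good, depth_of(good))
        } else {
          # no branch finished within budget: take the longest extension
          stats$chose_longest_downstream <- stats$chose_longest_downstream + 1
          gains <- vapply(probes, `[[`, integer(1), "gained")
          best <- d$cands[gains == max(gains)]
          base <- choose_in_proportion(best, depth_of(best))
        }
      }
    }
    seq <- paste0(seq, base)
    n <- nchar(seq)
    tk <- substr(seq, n - k_min + 1L, n)
    seen <- if (exists(tk, envir = visits, inherits = FALSE))
      get(tk, envir = visits, inherits = FALSE) + 1L else 1L
    assign(tk, seen, envir = visits)
    if (seen > cfg$max_loop_visits) return(finish(FALSE))
  }
}

#' Extend every starting read
#'
#' Deterministic given `cfg$rng_seed` and the input order: a single seeded
#' generator feeds all tie-breaking draws, consumed in read order. The global
#' RNG state is restored afterwards.
#'
#' @param region_reads data.frame from [select_and_trim()]; only rows with
#'   `is_starting` are extended.
#' @param ladder denoised `kmer_ladder`.
#' @param ctx a [primer_pair_context()].
#' @param cfg an [extension_config()].
#' @return list with `results` (data.frame: `source_id`, `sequence`,
#'   `terminated`, `bases_added`) and `stats` (a `decision_stats` list;
#'   `fully_extended + abandoned == starting_reads` always holds).
#' @export
extend_all <- function(region_reads, ladder, ctx, cfg = extension_config()) {
  starting <- region_reads[region_reads$is_starting, , drop = FALSE]
  stats <- .new_stats_env(ladder$ks)
  stats$starting_reads <- nrow(starting)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$rng_seed)
  rows <- lapply(seq_len(nrow(starting)), function(i) {
    extend_read(as.list(starting[i, ]), ladder, ctx, cfg, stats)
  })
  results <- if (length(rows)) {
    data.frame(source_id = vapply(rows, `[[`, character(1), "source_id"),
               sequence = vapply(rows, `[[`, character(1), "sequence"),
               terminated = vapply(rows, `[[`, logical(1), "terminated"),
               bases_added = vapply(rows, `[[`, integer(1), "bases_added"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source_id = character(0), sequence = character(0),
               terminated = logical(0), bases_added = integer(0),
               stringsAsFactors = FALSE)
  }
  list(results = results, stats = .stats_as_list(stats))
}
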