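# Primer-pair context: the four primer texts that can occur in unstranded
# reads, organised around a single canonical "extension orientation".
#
# Extension orientation is the forward strand of the amplicon:
#   [forward primer site] [inter-primer region] [RC(reverse primer) site]
# A forward-strand read can therefore show the forward primer F (region
# start) or RC(R) (region end); a reverse-strand read shows R (at its 5' end,
# covering the region end) or RC(F) (at its 3' end, covering the region
# start). Reads are canonicalised into extension orientation before any
# k-mers are collected, so:
#   * starting signal  = F        (begins the region, extension orientation)
#   * finishing signal = RC(R)    (terminates extension)
# and the reverse-strand detectors are RC(F) (read ends with it -> starting
# after reverse complementing) and R (read is reverse strand covering the
# region end).

#' Build a primer-pair context
#'
#' @param forward,reverse IUPAC primer strings (or [degenerate_primer()]s),
#'   both written 5'->3' on their own strands, as in a PCR primer pair.
#' @param max_mismatches mismatch tolerance used for every primer match
#'   (default 0: strict degenerate matching; the degenerate codes already
#'   absorb designed variability).
#' @return object of class `primer_ctx` with compiled primers:
#'   `forward`, `reverse`, `start_fwd` (= forward), `start_rc` (= RC(forward),
#'   seen on reverse-strand reads), `finish_fwd` (= RC(reverse), the finishing
#'   signal in extension orientation), `finish_rc` (= reverse, seen on
#'   reverse-strand reads), plus `starting_set` and `finishing_set`, the two
#'   texts of each kind expressed in extension orientation.
#' @export
primer_pair_context <- function(forward, reverse, max_mismatches = 0L) {
  fwd <- .as_primer(forward, "forward")
  rev <- .as_primer(reverse, "reverse")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  fwd_rc <- degenerate_primer(reverse_complement(fwd$seq), "forward")
  rev_rc <- degenerate_primer(reverse_complement(rev$seq), "reverse")
  structure(list(
    forward = fwd,
    reverse = rev,
    start_fwd = fwd,       # read begins region with F
    start_rc = fwd_rc,     # read ends with RC(F): reverse strand, region start
    finish_fwd = rev_rc,   # RC(R): finishing signal in extension orientation
    finish_rc = rev,       # read contains R: reverse strand, region end
    starting_set = c(fwd$seq, rev_rc$seq),
    finishing_set = c(rev_rc$seq, fwd_rc$seq),
    max_mismatches = as.integer(max_mismatches)
  ), class = "primer_ctx")
}

#' @export
print.primer_ctx <- function(x, ...) {
  cat(sprintf("<primer_ctx F=%s R=%s (finishing site %s), max_mismatches=%d>\n",
              x$forward$seq, x$reverse$seq, x$finish_fwd$seq,
              x$max_mismatches))
  invisible(x)
}

#' Earth Microbiome Project 16S rRNA V4 primer pair
#'
#' The 515F/806R degenerate primers commonly used for the V4 region.
#'
#' @return named character vector with elements `forward` and `reverse`.
#' @export
emp_v4_primers <- function() {
  c(forward = "GTGYCAGCMGCCGCGGTAA", reverse = "GGACTACNVGGGTWTCTAAT")
}
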