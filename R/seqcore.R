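# Sequence primitives: IUPAC degenerate-base algebra, primer matching,
# FASTA/FASTQ input and FASTA output.

# The 15 IUPAC nucleotide codes and the base sets they denote.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# chartr() tables: complementing a code complements its base set
# (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W, N map to themselves).
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

# Bit encoding for degenerate matching. A/C/G/T get one bit each; an 'N' in a
# *read* gets its own bit so that it matches only a primer 'N' (an unknown
# base gives no evidence of matching a constrained primer position).
.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

.code_mask <- function(code) {
  m <- sum(.BASE_BITS[IUPAC_SETS[[code]]])
  if (code == "N") m <- m + .BASE_BITS[["N"]]
  as.integer(m)
}

IUPAC_MASKS <- vapply(IUPAC_CODES, .code_mask, integer(1))

# Lookup table indexed by raw character code, for fast window encoding.
.CHAR_BITS <- integer(256)
.CHAR_BITS[utf8ToInt("A")] <- 1L
.CHAR_BITS[utf8ToInt("C")] <- 2L
.CHAR_BITS[utf8ToInt("G")] <- 4L
.CHAR_BITS[utf8ToInt("T")] <- 8L
.CHAR_BITS[utf8ToInt("N")] <- 16L

# Regex character class per code, equivalent to the mask semantics above
# for reads over {A,C,G,T,N}: primer N matches any read base including N;
# every other code matches only its own base set.
IUPAC_REGEX <- vapply(IUPAC_CODES, function(code) {
  if (code == "N") return("[ACGTN]")
  s <- IUPAC_SETS[[code]]
  if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
}, character(1))

#' Validate an IUPAC string
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
assert_iupac <- function(x, what = "sequence") {
  bad <- regexpr(paste0("[^", IUPAC_FROM, "]"), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of %s",
                 substr(x[i], bad[i], bad[i]), bad[i], what), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of IUPAC-coded sequences
#'
#' Each degenerate code maps to the code of its complemented base set
#' (R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H, N<->N), and the string is
#' reversed. The operation is an involution.
#'
#' @param x character vector of IUPAC strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("GTGYCAGCMGCCGCGGTAA")
#' @export
reverse_complement <- function(x) {
  assert_iupac(x)
  vapply(chartr(IUPAC_FROM, IUPAC_TO, x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Compile a degenerate primer
#'
#' Precomputes per-position base-set bit masks and a regex form for fast
#' matching. The `role` is informational.
#'
#' @param seq IUPAC primer string.
#' @param role `"forward"` or `"reverse"`.
#' @return an object of class `degenerate_primer` with fields `seq`, `role`,
#'   `length`, `masks` (integer vector) and `regex`.
#' @export
degenerate_primer <- function(seq, role = c("forward", "reverse")) {
  role <- match.arg(role)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("primer must be a single non-empty string", call. = FALSE)
  seq <- toupper(chartr("U", "T", seq))
  assert_iupac(seq, what = paste(role, "primer"))
  codes <- strsplit(seq, "")[[1L]]
  structure(
    list(seq = seq, role = role, length = nchar(seq),
         masks = unname(IUPAC_MASKS[codes]),
         regex = paste(IUPAC_REGEX[codes], collapse = "")),
    class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer %s: %s (%d nt)>\n", x$role, x$seq, x$length))
  invisible(x)
}

.as_primer <- function(primer, role = "forward") {
  if (inherits(primer, "degenerate_primer")) primer
  else degenerate_primer(primer, role)
}

#' Does a window match a degenerate primer?
#'
#' A position mismatches when the window base is not in the primer code's base
#' set; `N` in the window matches nothing unless the primer code is `N`.
#'
#' @param window A/C/G/T/N string of the same length as the primer.
#' @param primer a [degenerate_primer()] or IUPAC string.
#' @param max_mismatches maximum number of mismatching positions tolerated.
#' @return logical scalar.
#' @export
primer_matches <- function(window, primer, max_mismatches = 0L) {
  primer <- .as_primer(primer)
  if (nchar(window) != primer$length)
    stop(sprintf("window length %d != primer length %d",
                 nchar(window), primer$length), call. = FALSE)
  wbits <- .CHAR_BITS[utf8ToInt(window)]
  sum(bitwAnd(wbits, primer$masks) == 0L) <= max_mismatches
}

#' Find all primer match offsets in a read
#'
#' Brute scan of every window of the read against each primer; overlapping
#' matches are all reported. With `max_mismatches = 0` a regex-lookahead fast
#' path is used.
#'
#' @param read A/C/G/T/N string.
#' @param primers a [degenerate_primer()], IUPAC string, or (possibly named)
#'   list of them.
#' @param max_mismatches mismatch tolerance per window.
#' @return data.frame with columns `offset` (0-based) and `primer` (name or
#'   index within `primers`); zero rows when nothing matches.
#' @export
scan_for_primer <- function(read, primers, max_mismatches = 0L) {
  if (inherits(primers, "degenerate_primer") || is.character(primers))
    primers <- list(primers)
  ids <- names(primers)
  if (is.null(ids)) ids <- as.character(seq_along(primers))
  out <- list()
  for (j in seq_along(primers)) {
    p <- .as_primer(primers[[j]])
    off <- .primer_offsets(read, p, max_mismatches)
    if (length(off))
      out[[length(out) + 1L]] <- data.frame(offset = off, primer = ids[j],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(offset = integer(0), primer = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$offset), , drop = FALSE]
}

# 0-based offsets at which `p` matches within `read`.
.primer_offsets <- function(read, p, max_mismatches) {
  n <- nchar(read)
  if (n < p$length) return(integer(0))
  if (max_mismatches == 0L) {
    m <- gregexpr(paste0("(?=", p$regex, ")"), read, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(integer(0))
    return(as.integer(m) - 1L)
  }
  wbits <- .CHAR_BITS[utf8ToInt(read)]
  offs <- integer(0)
  for (i in 0:(n - p$length)) {
    mm <- sum(bitwAnd(wbits[(i + 1):(i + p$length)], p$masks) == 0L)
    if (mm <= max_mismatches) offs <- c(offs, i)
  }
  offs
}

# First (leftmost) match offset or NA_integer_.
.first_primer_offset <- function(read, p, max_mismatches) {
  if (max_mismatches == 0L) {
    m <- regexpr(p$regex, read, perl = TRUE)
    return(if (m == -1L) NA_integer_ else as.integer(m) - 1L)
  }
  off <- .primer_offsets(read, p, max_mismatches)
  if (length(off)) off[1L] else NA_integer_
}

#' Read sequences from FASTA/FASTQ files
#'
#' Accepts file paths or glob patterns; format is auto-detected from the first
#' record character (`>` FASTA, `@` FASTQ) and gzip compression is handled
#' transparently. Qualities are discarded; bases are uppercased with `U -> T`.
#' Bases other than A/C/G/T/N are rejected with their position.
#'
#' @param paths character vector of file names or glob patterns.
#' @return named character vector of sequences (names are record ids).
#' @export
read_sequences <- function(paths) {
  files <- unlist(lapply(paths, function(p) {
    if (grepl("[*?\\[]", p)) {
      hits <- Sys.glob(p)
      if (!length(hits)) stop("no files match pattern: ", p, call. = FALSE)
      hits
    } else p
  }))
  seqs <- character(0)
  for (f in files) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    first <- .peek_first_char(f)
    if (is.na(first)) {
      warning("empty input file: ", f, call. = FALSE)
      next
    }
    fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                  stop(sprintf("file %s is neither FASTA nor FASTQ (starts with '%s')",
                               f, first), call. = FALSE))
    ss <- tryCatch(
      Biostrings::readBStringSet(f, format = fmt),
      error = function(e) stop(sprintf("malformed %s file %s: %s",
                                       fmt, f, conditionMessage(e)),
                               call. = FALSE))
    x <- chartr("U", "T", toupper(as.character(ss)))
    bad <- regexpr("[^ACGTN]", x)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop(sprintf("file %s, record %d (%s): invalid base '%s' at position %d",
                   f, i, names(x)[i], substr(x[i], bad[i], bad[i]), bad[i]),
           call. = FALSE)
    }
    seqs <- c(seqs, x)
  }
  seqs
}

.peek_first_char <- function(path) {
  con <- gzfile(path, "rt")  # gzfile reads plain text too
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) return(NA_character_)
    if (nzchar(trimws(line))) return(substr(trimws(line), 1L, 1L))
  }
}

#' Write sequences as FASTA
#'
#' Wraps at 80 columns; writes gzip output when `path` ends in `.gz`.
#'
#' @param seqs named character vector of A/C/G/T/N sequences.
#' @param path output file name.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
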