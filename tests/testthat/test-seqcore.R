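# Sequence primitives: IUPAC algebra, degenerate matching, FASTA/FASTQ I/O.

test_that("reverse_complement handles degenerate codes", {
  expect_equal(reverse_complement("GTGYCAGCMGCCGCGGTAA"), "TTACCGCGGCKGCTGRCAC")
  expect_equal(reverse_complement("GGACTACNVGGGTWTCTAAT"), "ATTAGAWACCCBNGTAGTCC")
  expect_equal(reverse_complement("A"), "T")
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement(c("AC", "GG")), c("GT", "CC"))
  expect_error(reverse_complement("ACXG"), "position 3")
})

test_that("reverse_complement is an involution and agrees with Biostrings", {
  codes <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  set.seed(101)
  for (i in 1:50) {
    s <- paste(sample(codes, sample(1:40, 1), replace = TRUE), collapse = "")
    rc <- reverse_complement(s)
    expect_identical(reverse_complement(rc), s)
    oracle <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(rc, oracle)
  }
})

test_that("primer_matches applies per-position base-set semantics", {
  rp <- "GGACTACNVGGGTWTCTAAT"
  expect_true(primer_matches("GGACTACAAGGGTATCTAAT", rp, 0))   # N>=A, V>=A, W>=A
  expect_false(primer_matches("GGACTACATGGGTATCTAAT", rp, 0))  # V = {A,C,G}, not T
  expect_true(primer_matches("GGACTACATGGGTATCTAAT", rp, 1))
  expect_true(primer_matches("AAAA", "NNNN", 0))
  # N in the window matches nothing except a primer N
  expect_false(primer_matches("AN", "AA", 0))
  expect_true(primer_matches("AN", "AN", 0))
  expect_error(primer_matches("AAA", "AAAA", 0), "length")
})

test_that("primer_matches is monotone in the mismatch allowance", {
  codes <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  set.seed(202)
  for (i in 1:40) {
    p <- paste(sample(codes, 12, replace = TRUE), collapse = "")
    w <- paste(sample(c("A", "C", "G", "T", "N"), 12, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    res <- vapply(0:12, function(m) primer_matches(w, p, m), logical(1))
    expect_true(all(diff(res) >= 0))  # once true, stays true
    expect_true(res[13])              # m = length always matches
  }
})

test_that("scan_for_primer finds all (overlapping) offsets", {
  fp <- emp_v4_primers()[["forward"]]
  read <- paste0(FP_SITE, "ACGTACGTACGT")
  hits <- scan_for_primer(read, fp)
  expect_equal(hits$offset, 0L)
  expect_equal(nrow(scan_for_primer("ACGTACGTACGTACGTACGTACG", fp)), 0L)
  read2 <- paste0(substr(rand_dna(60, 5), 1, 7), FP_SITE,
                  substr(rand_dna(60, 6), 1, 34))
  expect_true(7L %in% scan_for_primer(read2, fp)$offset)
  # overlapping matches are all reported
  expect_equal(scan_for_primer("AAAA", "AA")$offset, c(0L, 1L, 2L))
})

test_that("scan_for_primer agrees with a naive all-offsets oracle", {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))
  naive <- function(read, primer, mm) {
    rv <- strsplit(read, "")[[1]]
    pv <- strsplit(primer, "")[[1]]
    hits <- integer(0)
    if (length(rv) < length(pv)) return(hits)
    for (off in 0:(length(rv) - length(pv))) {
      bad <- sum(!vapply(seq_along(pv), function(j) {
        rv[off + j] %in% sets[[pv[j]]]
      }, logical(1)))
      if (bad <= mm) hits <- c(hits, off)
    }
    hits
  }
  codes <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  set.seed(303)
  for (i in 1:30) {
    read <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
    primer <- paste(sample(codes, 6, replace = TRUE), collapse = "")
    for (mm in c(0L, 1L)) {
      expect_equal(scan_for_primer(read, primer, mm)$offset,
                   naive(read, primer, mm),
                   info = sprintf("read=%s primer=%s mm=%d", read, primer, mm))
    }
  }
})

test_that("FASTA and FASTQ reading round-trips ids and bases", {
  seqs <- c(rec1 = "ACGTACGTAA", rec2 = rand_dna(200, 9))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_identical(read_sequences(fa), seqs)
  # gzip round trip
  gz <- tempfile(fileext = ".fasta.gz")
  write_fasta(seqs, gz)
  expect_identical(read_sequences(gz), seqs)
  # FASTQ: qualities discarded, bases preserved
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@rec1", "ACGTACGTAA", "+", "IIIIIIIIII",
               "@rec2", "GGGTTTAACC", "+", "!!!!!!!!!!"), fq)
  got <- read_sequences(fq)
  expect_identical(unname(got), c("ACGTACGTAA", "GGGTTTAACC"))
  expect_identical(names(got), c("rec1", "rec2"))
})

test_that("reads are normalised and invalid input is rejected with context", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">low", "acgu", ">nn", "ACGNT"), fa)
  expect_identical(unname(read_sequences(fa)), c("ACGT", "ACGNT"))
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">oops", "ACRGT"), bad)
  expect_error(read_sequences(bad), "record 2.*position 3")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_warning(res <- read_sequences(empty), "empty")
  expect_length(res, 0)
  notseq <- tempfile(fileext = ".fa")
  writeLines("hello world", notseq)
  expect_error(read_sequences(notseq), "neither FASTA nor FASTQ")
  expect_error(read_sequences(tempfile()), "not found")
})

test_that("glob patterns expand to multiple files", {
  dir <- tempfile(); dir.create(dir)
  write_fasta(c(a = "ACGTACGT"), file.path(dir, "part1.fasta"))
  write_fasta(c(b = "TTTTCCCC"), file.path(dir, "part2.fasta"))
  got <- read_sequences(file.path(dir, "part*.fasta"))
  expect_identical(got, c(a = "ACGTACGT", b = "TTTTCCCC"))
  expect_error(read_sequences(file.path(dir, "nope*.fa")), "no files match")
})

test_that("primer pair context derives start/finish texts per orientation", {
  ctx <- emp_ctx()
  expect_equal(ctx$starting_set, c("GTGYCAGCMGCCGCGGTAA", "ATTAGAWACCCBNGTAGTCC"))
  expect_length(ctx$finishing_set, 2)
  expect_equal(ctx$finish_fwd$seq, "ATTAGAWACCCBNGTAGTCC")
  expect_equal(ctx$start_rc$seq, reverse_complement(ctx$forward$seq))
  expect_true(primer_matches(FIN_SITE, ctx$finish_fwd, 0))
  expect_true(primer_matches(FP_SITE, ctx$start_fwd, 0))
})
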