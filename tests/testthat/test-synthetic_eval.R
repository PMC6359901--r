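# Mock-community generation, read simulation, and precision/recall scoring.

pct_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * mean(av == bv)
}

test_that("make_community builds shared primer sites and distinct regions", {
  comm <- make_community(n_members = 5, seed = 3)
  m <- comm$members
  expect_equal(nrow(m), 5)
  expect_equal(length(unique(m$truth)), 5)
  expect_equal(sum(m$abundance), 1)
  expect_true(primer_matches(comm$fwd_site, comm$forward, 0))
  expect_true(primer_matches(comm$rev_site,
                             reverse_complement(comm$reverse), 0))
  # references embed site + region + site, so truth is the inter-primer slice
  expect_true(all(mapply(function(ref, tr) {
    grepl(paste0(comm$fwd_site, tr, comm$rev_site), ref, fixed = TRUE)
  }, m$reference, m$truth)))
  # pairwise divergence constraint (equal-length 250 bp regions)
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(pct_identity(m$truth[i], m$truth[j]), 90)
  # reproducible by seed
  expect_identical(make_community(n_members = 5, seed = 3)$members, m)
  expect_false(identical(make_community(n_members = 5, seed = 4)$members$truth,
                         m$truth))
})

test_that("single members and strain pairs produce the stated truth sets", {
  one <- make_community(n_members = 1, seed = 5)
  expect_equal(nrow(one$members), 1)
  sp <- make_community(n_members = 1, strains = list(list(of = 1, snps = 1)),
                       abundance = c(0.9, 0.1), seed = 6)
  expect_equal(nrow(sp$members), 2)
  expect_equal(sp$members$abundance, c(0.9, 0.1))
  d <- mapply(function(a, b) a != b,
              strsplit(sp$members$truth[1], "")[[1]],
              strsplit(sp$members$truth[2], "")[[1]])
  expect_equal(sum(d), 1)  # exactly one SNP apart
})

test_that("simulated reads hit the configured depth and cover every k-mer", {
  comm <- make_community(n_members = 3, seed = 8)
  reads <- simulate_reads(comm)
  expect_true(all(nchar(reads) == comm$read_length))
  per <- table(sub("_read.*", "", names(reads)))
  L <- nchar(comm$members$reference)
  expect_equal(unname(as.integer(per)),
               as.integer(round(comm$depth * L / comm$read_length)))
  expect_true(all(check_region_coverage(comm, reads, k = 32, min_count = 2)))
  # both strands appear
  expect_true(any(grepl("/rev$", names(reads))) &&
                any(grepl("/fwd$", names(reads))))
})

test_that("an engineered gap leaves that member uncovered, others intact", {
  comm <- make_community(n_members = 3, seed = 8)
  reads <- simulate_reads(comm, gap = list(member = 2, width = 40))
  cov <- check_region_coverage(comm, reads)
  expect_identical(unname(cov), c(TRUE, FALSE, TRUE))
  # no read overlaps the gapped window of member 2's region
  width <- 40L
  at <- (nchar(comm$members$truth[2]) - width) %/% 2L
  g0 <- comm$flank + nchar(comm$fwd_site) + at + 1L
  gap_seq <- substr(comm$members$reference[2], g0 - 5L, g0 + width + 4L)
  mid <- substr(gap_seq, 6L, 6L + width - 1L)
  hit <- vapply(reads, function(r)
    grepl(mid, r, fixed = TRUE) ||
      grepl(mid, reverse_complement(r), fixed = TRUE), logical(1))
  expect_false(any(hit))
})

test_that("substitution errors appear at the configured rate", {
  # one member so that the clean rerun shares the error run's read positions
  # (substitution draws shift the stream between members otherwise)
  clean_comm <- make_community(n_members = 1, depth = 90, seed = 12,
                               error_rate = 0)
  err_comm <- make_community(n_members = 1, depth = 90, seed = 12,
                             error_rate = 0.005)
  expect_identical(clean_comm$members, err_comm$members)
  clean <- simulate_reads(clean_comm, seed = 99)
  errs <- simulate_reads(err_comm, seed = 99)   # same start positions
  hamming <- function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  mism <- sum(vapply(seq_along(errs), function(i) {
    min(hamming(errs[[i]], clean[[i]]),
        hamming(reverse_complement(errs[[i]]), clean[[i]]))
  }, numeric(1)))
  total <- sum(nchar(errs))
  p <- mism / total
  se <- sqrt(0.005 * 0.995 / total)
  expect_lt(abs(p - 0.005), 3 * se)
})

test_that("evaluate_amplicons computes the precision/recall arithmetic", {
  comm <- make_community(n_members = 4, seed = 14)
  truths <- comm$members$truth
  perfect <- evaluate_amplicons(truths, comm)
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$recall, 100)
  missing1 <- evaluate_amplicons(truths[-2], comm)
  expect_equal(missing1$recall, 100 * 3 / 4)
  expect_equal(missing1$precision, 100)
  expect_false(missing1$per_member$found[2])
  chimera <- evaluate_amplicons(c(truths, rand_dna(250, 15)), comm)
  expect_equal(chimera$precision, 100 * 4 / 5)
  expect_equal(chimera$recall, 100)
  # duplicated outputs collapse to distinct sequences but feed read counts
  dup <- evaluate_amplicons(c(truths, truths[1]), comm)
  expect_equal(dup$precision, 100)
  expect_equal(dup$per_member$n_reads, c(2L, 1L, 1L, 1L))
  # excluding an uncovered member removes it from the recall denominator
  excl <- evaluate_amplicons(truths[-2], comm, exclude = 2)
  expect_equal(excl$recall, 100)
  expect_equal(excl$fn, 0)
})

test_that("identity mode accepts near matches at the OTU threshold", {
  comm <- make_community(n_members = 2, seed = 16)
  near <- comm$members$truth[1]
  substr(near, 10, 10) <- if (substr(near, 10, 10) == "A") "C" else "A"
  exact <- evaluate_amplicons(c(near, comm$members$truth[2]), comm)
  expect_equal(exact$tp, 1)          # the SNP copy is a false positive
  loose <- evaluate_amplicons(c(near, comm$members$truth[2]), comm,
                              mode = "identity", min_identity = 97)
  expect_equal(loose$tp, 2)          # 99.6% identity clears 97%
  expect_equal(loose$recall, 100)
})

test_that("fixtures round-trip through the writer and the readers", {
  comm <- make_community(n_members = 2, seed = 18)
  reads <- simulate_reads(comm)
  dir <- tempfile()
  paths <- write_fixture(comm, reads, dir, gz = TRUE)
  expect_identical(read_sequences(paths[["reads"]]), reads)
  truth <- read_sequences(paths[["truth"]])
  expect_identical(unname(truth), comm$members$truth)
  manifest <- read.delim(paths[["manifest"]])
  expect_equal(manifest$member, comm$members$member)
  expect_equal(manifest$truth_length, nchar(comm$members$truth))
})
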