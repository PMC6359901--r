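# Mock communities with ground truth, a shotgun read simulator, and the
# precision/recall evaluator used to score assembled amplicons.

# Resolve degenerate codes to one concrete A/C/G/T instantiation.
.instantiate <- function(iupac) {
  codes <- strsplit(iupac, "")[[1L]]
  paste(vapply(codes, function(cd) {
    s <- IUPAC_SETS[[cd]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# percent identity of two equal-length strings
.pid <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  100 * mean(av == bv)
}

#' Generate a mock community with known amplicon truth
#'
#' Every member is a reference "gene": a random flank, a concrete forward
#' primer site, a variable inter-primer region, the concrete reverse-primer
#' site (the reverse complement of the reverse primer), and another flank.
#' Primer sites are instantiated once from the degenerate primers and shared
#' by all members (they are conserved sites). The truth amplicon of a member
#' is its inter-primer region, primers excluded. Optional strain pairs copy an
#' existing member's region with a given number of SNPs.
#'
#' @param n_members number of independent members.
#' @param region_len integer range `c(lo, hi)` (or a single value) for
#'   inter-primer region lengths (default 250, the usual 16S V4 size).
#' @param forward,reverse degenerate primers (default EMP V4 pair).
#' @param divergence minimum pairwise percent difference between member
#'   regions (default 10); an error is raised if it cannot be met.
#' @param abundance vector of member weights (recycled/normalised to sum 1);
#'   default even.
#' @param strains optional list of `list(of = <member index>, snps = <int>)`
#'   describing extra strain members derived from existing ones.
#' @param flank bases of random sequence outside each primer site (default 50,
#'   so reads can bracket the sites).
#' @param read_length,depth,error_rate read-simulation parameters stored with
#'   the community: read length in bases (default 100), mean per-member fold
#'   coverage (default 30), and per-base substitution probability (default 0).
#' @param seed RNG seed making the community reproducible.
#' @return object of class `synthetic_community`: list with `members`
#'   (data.frame: `member`, `reference`, `truth`, `abundance`), `fwd_site`,
#'   `rev_site`, `forward`, `reverse`, `flank`, `read_length`, `depth`,
#'   `error_rate`, `seed`.
#' @export
make_community <- function(n_members = 15L,
                           region_len = 250L,
                           forward = emp_v4_primers()[["forward"]],
                           reverse = emp_v4_primers()[["reverse"]],
                           divergence = 10,
                           abundance = NULL,
                           strains = NULL,
                           flank = 50L,
                           read_length = 100L,
                           depth = 30,
                           error_rate = 0,
                           seed = 1L) {
  stopifnot(n_members >= 1L)
  if (length(region_len) == 1L) region_len <- c(region_len, region_len)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  fwd_site <- .instantiate(forward)
  rev_site <- .instantiate(reverse_complement(reverse))
  regions <- character(0)
  for (i in seq_len(n_members)) {
    for (attempt in 1:100) {
      len <- if (region_len[1] == region_len[2]) region_len[1]
             else sample(seq(region_len[1], region_len[2]), 1L)
      cand <- .random_seq(len)
      ok <- !length(regions) || all(vapply(regions, function(r) {
        nchar(r) != nchar(cand) || .pid(r, cand) < (100 - divergence)
      }, logical(1)))
      if (ok) break
      if (attempt == 100)
        stop("cannot satisfy the divergence constraint", call. = FALSE)
    }
    regions <- c(regions, cand)
  }
  ids <- sprintf("member_%02d", seq_len(n_members))
  if (!is.null(strains)) {
    for (s in strains) {
      base <- regions[[s$of]]
      pos <- sample(nchar(base), s$snps)
      var <- base
      for (p in pos) {
        cur <- substr(var, p, p)
        substr(var, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
      regions <- c(regions, var)
      ids <- c(ids, sprintf("%s_strain%d", ids[s$of], s$snps))
    }
  }
  n <- length(regions)
  if (is.null(abundance)) abundance <- rep(1, n)
  abundance <- rep_len(abundance, n)
  abundance <- abundance / sum(abundance)
  refs <- paste0(vapply(seq_len(n), function(i) .random_seq(flank),
                        character(1)),
                 fwd_site, regions, rev_site,
                 vapply(seq_len(n), function(i) .random_seq(flank),
                        character(1)))
  structure(list(
    members = data.frame(member = ids, reference = refs, truth = regions,
                         abundance = abundance, stringsAsFactors = FALSE),
    fwd_site = fwd_site, rev_site = rev_site,
    forward = forward, reverse = reverse, flank = as.integer(flank),
    read_length = as.integer(read_length), depth = depth,
    error_rate = error_rate, seed = as.integer(seed)
  ), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "<synthetic_community: %d members, regions %d-%d bp, %d bp reads, depth %gx, error %g>\n",
    nrow(x$members), min(nchar(x$members$truth)), max(nchar(x$members$truth)),
    x$read_length, x$depth, x$error_rate))
  invisible(x)
}

#' Simulate shotgun reads from a community
#'
#' Read starts are uniform along each reference, strands are random, and the
#' per-member read count is fixed so that member `i` receives fold coverage
#' `depth * n_members * abundance_i` (even abundances give every member the
#' community's nominal depth). Substitution errors are i.i.d. at `error_rate`.
#' A coverage gap can be engineered by excluding all reads overlapping a
#' window of one member's inter-primer region.
#'
#' @param community a [make_community()] object.
#' @param gap optional `list(member = <index>, at = <0-based offset into the
#'   region, NULL for centred>, width = <bases, default 40>)`.
#' @param seed RNG seed (defaults to `community$seed + 1`).
#' @return named character vector of reads (names encode member, index and
#'   strand).
#' @export
simulate_reads <- function(community, gap = NULL, seed = NULL) {
  stopifnot(inherits(community, "synthetic_community"))
  if (is.null(seed)) seed <- community$seed + 1L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  m <- community$members
  rl <- community$read_length
  n_members <- nrow(m)
  reads <- character(0)
  for (i in seq_len(n_members)) {
    ref <- m$reference[i]
    L <- nchar(ref)
    if (L < rl) stop("reference shorter than the read length", call. = FALSE)
    cov <- community$depth * n_members * m$abundance[i]
    n_reads <- round(cov * L / rl)
    starts <- 1:(L - rl + 1L)
    if (!is.null(gap) && gap$member == i) {
      width <- if (is.null(gap$width)) 40L else gap$width
      at <- if (is.null(gap$at))
        (nchar(m$truth[i]) - width) %/% 2L else gap$at
      # window in reference coordinates (1-based)
      g0 <- community$flank + nchar(community$fwd_site) + at + 1L
      g1 <- g0 + width - 1L
      # drop every start whose read overlaps [g0, g1]
      starts <- starts[starts + rl - 1L < g0 | starts > g1]
      if (!length(starts))
        stop("gap leaves no valid read start positions", call. = FALSE)
    }
    pos <- sample(starts, n_reads, replace = TRUE)
    rs <- substring(ref, pos, pos + rl - 1L)
    # error draws are consumed even at rate 0 so that runs differing only in
    # error_rate share positions and strands (handy for oracle comparisons)
    rs <- vapply(rs, function(r) {
      hits <- which(stats::runif(rl) < community$error_rate)
      for (p in hits) {
        cur <- substr(r, p, p)
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
      r
    }, character(1), USE.NAMES = FALSE)
    flip <- stats::runif(n_reads) < 0.5
    rs[flip] <- reverse_complement(rs[flip])
    names(rs) <- sprintf("%s_read%05d/%s", m$member[i], seq_len(n_reads),
                         ifelse(flip, "rev", "fwd"))
    reads <- c(reads, rs)
  }
  reads
}

#' Check complete k-mer coverage of every member's amplicon
#'
#' A member counts as fully covered when every `k`-window of its
#' primer-flanked amplicon (forward site + region + reverse site) occurs at
#' least `min_count` times among the reads (either strand) -- the condition
#' under which denoising keeps the whole extension path intact.
#'
#' @param community a [make_community()] object.
#' @param reads character vector of simulated reads.
#' @param k window size (default 32).
#' @param min_count required depth per window (default 2).
#' @return named logical vector, one element per member.
#' @export
check_region_coverage <- function(community, reads, k = 32L, min_count = 2L) {
  tbl <- build_kmer_table(c(reads, reverse_complement(reads)), k)
  m <- community$members
  vapply(seq_len(nrow(m)), function(i) {
    amp <- paste0(community$fwd_site, m$truth[i], community$rev_site)
    all(vapply(tile_windows(amp, k), function(w) kt_count(tbl, w),
               integer(1)) >= min_count)
  }, logical(1)) |> stats::setNames(m$member)
}

#' Score assembled amplicons against the community truth
#'
#' Distinct output sequences are compared with the truth amplicons. By
#' default a true positive is an exact sequence match (the truth is known, so
#' nothing weaker is needed); `mode = "identity"` instead accepts matches at
#' `min_identity` or better (the usual 97% OTU convention), computed by global
#' pairwise alignment. Members listed in `exclude` (e.g. those with an
#' engineered coverage gap) are left out of the false-negative count, so
#' recall is then over the fully covered members.
#'
#' @param outputs character vector of assembled amplicons (need not be
#'   distinct; per-member read counts use the full vector).
#' @param community a [make_community()] object.
#' @param mode `"exact"` (default) or `"identity"`.
#' @param min_identity percent identity threshold for `mode = "identity"`.
#' @param exclude member ids (or indices) excluded from the recall
#'   denominator.
#' @return object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall` (percent), and `per_member` (data.frame: `member`,
#'   `found`, `n_reads`, `excluded`).
#' @export
evaluate_amplicons <- function(outputs, community,
                               mode = c("exact", "identity"),
                               min_identity = 97, exclude = NULL) {
  mode <- match.arg(mode)
  m <- community$members
  if (is.numeric(exclude)) exclude <- m$member[exclude]
  distinct <- unique(outputs)
  matches <- function(out, truth) {
    if (mode == "exact") return(out == truth)
    if (out == truth) return(TRUE)
    aln <- Biostrings::pairwiseAlignment(out, truth, type = "global")
    Biostrings::pid(aln) >= min_identity
  }
  out_is_tp <- vapply(distinct, function(o) {
    any(vapply(m$truth, function(t) matches(o, t), logical(1)))
  }, logical(1))
  found <- vapply(m$truth, function(t) {
    any(vapply(distinct, function(o) matches(o, t), logical(1)))
  }, logical(1))
  n_reads <- vapply(m$truth, function(t) sum(outputs == t), integer(1))
  excluded <- m$member %in% exclude
  tp <- sum(out_is_tp)
  fp <- sum(!out_is_tp)
  fn <- sum(!found & !excluded)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * sum(found & !excluded) /
    (sum(found & !excluded) + fn) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall,
    per_member = data.frame(member = m$member, found = found,
                            n_reads = n_reads, excluded = excluded,
                            row.names = NULL, stringsAsFactors = FALSE)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: TP=%d FP=%d FN=%d | precision %.1f%%, recall %.1f%%>\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' Write a community fixture to disk
#'
#' Emits the simulated reads (`reads.fasta`, gzipped when `gz = TRUE`), the
#' truth amplicons (`truth.fasta`) and a manifest TSV (`manifest.tsv`:
#' member, abundance, truth length).
#'
#' @param community a [make_community()] object.
#' @param reads reads from [simulate_reads()].
#' @param dir output directory (created if needed).
#' @param gz gzip the reads file (default FALSE).
#' @return named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(community, reads, dir, gz = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reads = file.path(dir, if (gz) "reads.fasta.gz" else "reads.fasta"),
             truth = file.path(dir, "truth.fasta"),
             manifest = file.path(dir, "manifest.tsv"))
  write_fasta(reads, paths[["reads"]])
  m <- community$members
  write_fasta(stats::setNames(m$truth, m$member), paths[["truth"]])
  utils::write.table(
    data.frame(member = m$member, abundance = m$abundance,
               truth_length = nchar(m$truth)),
    paths[["manifest"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Evaluation report as a data frame row
#' @param report an `eval_report`.
#' @return one-row data.frame with counts and percentages.
#' @export
eval_summary <- function(report) {
  data.frame(tp = report$tp, fp = report$fp, fn = report$fn,
             precision = report$precision, recall = report$recall)
}
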