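# Shared fixtures. Heavier end-to-end communities are built once per test run
# and cached; everything is generated in code under fixed seeds.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE))
    assign(name, expr, envir = .cache)
  get(name, envir = .cache, inherits = FALSE)
}

# Concrete instantiations of the EMP V4 primer sites used by hand-built reads
# (degenerate codes resolved: Y->T, M->A; W->A, B->G, N->A in the RC site).
FP_SITE <- "GTGTCAGCAGCCGCGGTAA"    # matches GTGYCAGCMGCCGCGGTAA
FIN_SITE <- "ATTAGAAACCCGAGTAGTCC"  # matches RC(reverse) ATTAGAWACCCBNGTAGTCC

emp_ctx <- function(max_mismatches = 0L) {
  p <- emp_v4_primers()
  primer_pair_context(p[["forward"]], p[["reverse"]],
                      max_mismatches = max_mismatches)
}

# counts of a kmer_table in key order (hash order is not comparable)
kt_sorted <- function(t) {
  x <- kt_counts(t)
  x[order(names(x))]
}

# deterministic pseudo-random ACGT string
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

run_quiet <- function(comm, reads, seed = 7L, out = tempfile(fileext = ".fasta"),
                      min_count = 2L) {
  cfg <- run_config(comm$forward, comm$reverse, inputs = NULL, output = out,
                    rng_seed = seed, min_count = min_count)
  summary <- suppressWarnings(suppressMessages(run_pipeline(cfg, reads = reads)))
  amps <- unname(as.character(Biostrings::readDNAStringSet(out)))
  list(summary = summary, amps = amps, out = out)
}

# The reference study community: 15 members, 250 bp inter-primer regions,
# 100 bp reads at 30x per member, error-free.
base_community <- function() cached("comm", make_community(seed = 42))
base_reads <- function() cached("reads", simulate_reads(base_community()))
base_run <- function() cached("run", run_quiet(base_community(), base_reads()))

# Same community with a 40 bp read-free gap in member 3's region.
gap_reads <- function() cached("gap_reads",
  simulate_reads(base_community(), gap = list(member = 3, width = 40)))
gap_run <- function() cached("gap_run", run_quiet(base_community(), gap_reads()))

# Two strains differing by one SNP, mixed 90:10, deep coverage so the minor
# allele keeps k-mer support at every rung of the ladder.
strain_community <- function() cached("strain_comm",
  make_community(n_members = 1, strains = list(list(of = 1, snps = 1)),
                 abundance = c(0.9, 0.1), depth = 600, seed = 11))
strain_run <- function() cached("strain_run", {
  comm <- strain_community()
  run_quiet(comm, simulate_reads(comm))
})
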