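---
title: "ampliseek: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliseek: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliseek)
```

## The problem

Amplicon sequencing profiles a microbial community by PCR-amplifying a marker
region (classically the 16S rRNA V4 region between the EMP 515F/806R primers)
and sequencing the product. Shotgun (WGS) metagenome sequencing avoids PCR
bias but scatters the marker gene across short reads that never span the whole
inter-primer region, and reads covering conserved stretches cannot be placed
precisely. ampliseek reconstructs, from a shotgun read pool, the full-length
sequences that PCR with a given primer pair *would have produced* — one
"in-silico amplicon" per read that carries the forward primer — so that
standard amplicon pipelines (OTU clustering, taxonomic classification) can be
applied to WGS data without assembly of the whole metagenome.

The intended input is a read pool already reduced to the neighbourhood of the
target gene (for example by an HMM or k-mer reference prefilter, which
typically discards ~99.9% of a bacterial WGS dataset). Prefiltering is about
memory and speed, not correctness: off-target reads are removed again by the
first phase.

## The algorithm

Everything is organised around one *extension orientation*: the forward
strand of the amplicon,

```
[forward primer site] [inter-primer region] [RC(reverse primer) site]
```

Shotgun reads are unstranded, so an unoriented read can show one of four
primer texts: the forward primer `F` or `RC(R)` (forward-strand reads), and
`R` or `RC(F)` (reverse-strand reads). Reads are canonicalised into extension
orientation before any k-mer is collected; in that orientation `F` starts a
region and `RC(R)` finishes it. For the EMP V4 pair, `RC(R)` is
`ATTAGAWACCCBNGTAGTCC`. Degenerate primer matching treats each IUPAC code as
a base set; an `N` in a *read* matches nothing except a primer `N`, because
an unknown base is not evidence for a constrained primer position. The default
mismatch tolerance is 0: the degenerate codes already absorb the designed
primer variability, and strict matching is reproducible. A `max_mismatches`
knob exists for primers known to sit on divergent sites.

### Phase 1 — selecting the region reads

A 32-mer hash set (the *inter-primer filter*) is seeded with every N-free
32-window of the post-primer tail of each read that carries the forward
primer (either strand; the read is flipped into extension orientation first).
The pool is then re-scanned: any read whose *first* 32-mer is already in the
filter donates all of its 32-windows. Passes repeat until a full pass adds
nothing. This fixed point subsumes the informal stopping rule "the whole
region is covered and the selected reads carry a finishing primer": once
every region 32-mer is present no read can add more. A hard cap of 100 rounds
guards against pathological inputs. Windows *past* a finishing-primer match
are never added — extension must stop at the primer, so k-mer space must end
there too.

Selection then keeps reads whose first 32-mer (either orientation) is in the
filter, plus all primer-bearing reads, and trims them:

* a **starting** read keeps the bases strictly after the forward primer —
  and is marked `is_starting` only when that tail is at least 32 bases,
  since a shorter tail cannot form the k-mer context extension needs;
* any read containing a finishing primer is clipped just *after* the match.
  The primer is kept so the extender can terminate on it, and is removed
  again from the final amplicons, which are therefore primer-free on both
  ends.

One consequence of the "starts with a filter k-mer" rule is that reads whose
first k-mer straddles a primer site are not selected. Their k-mers are
redundant (fully covered communities lose nothing), and the same rule is what
keeps flanking sequence out of the tables.

### Phase 2 — the k-mer table ladder

The trimmed region reads are tiled into count tables at k = 32, 40, 48, …,
up to the dominant (modal) trimmed read length; 100 bp reads give nine
tables. Short k-mers are plentiful but shared between related organisms;
long k-mers are specific but sparse, especially near the trimmed region
edges. The ladder keeps both.

Each table is then denoised. Two rules:

* **count floor** (`min_count`, default 2): k-mers seen once are far more
  likely to contain a sequencing error than to be real at any usable depth.
  Depth-1 fixtures must set `min_count = 1`.
* **error-variant rule** (`variant_ratio`, default 10), applied at k = 32
  only: a k-mer is dropped when some Hamming-distance-1 neighbour in the
  table outnumbers it at least 10:1. That count profile is the k-mer-spectrum
  signature of a substitution error inside an abundant k-mer; genuine strain
  variants are far less lopsided (a 2:1 or even 5:1 pair survives). The rule
  is restricted to the smallest k because neighbour enumeration grows with k
  and every erroneous long k-mer contains an erroneous 32-mer already caught
  at the bottom rung. Denoising is idempotent by construction: survivors are
  only ever compared against other survivors on a second pass.

### Phase 3 — extension

Each starting read is extended one base at a time. Per appended base:

1. **Terminate?** The terminal window is matched against the finishing
   primer (the whole starting read is scanned once up front, so only the
   newest window needs checking thereafter). On a match the extension stops;
   the primer match and everything after it is trimmed away.
2. **Candidates at k = 32.** The four possible next bases are screened by
   testing `tail31 + b` against the denoised 32-mer table. No survivor is a
   dead end (the read is abandoned); one survivor is appended directly.
3. **k-escalation.** With several survivors, progressively longer k are
   consulted: a base survives at k only if it survived every smaller k *and*
   its terminal k-mer exists at k. A single survivor decides. If *all*
   candidates vanish at the next k (the longer table is simply too sparse
   there), the decision falls back to the survivors of the previous k rather
   than treating everything as dead.
4. **Downstream lookahead.** If ambiguity survives the ladder, each candidate
   branch is probed by recursively extending it up to `lookahead_budget`
   (default 500) further bases. Exactly one branch reaching a finishing
   primer wins. Several finishing branches are decided by a random draw
   weighted by the terminal 32-mer counts — depths 90 vs 10 pick the deeper
   branch 90% of the time — which is what keeps minor strains represented in
   the output at roughly their true proportion instead of being absorbed by
   the dominant strain. If no branch finishes, the one that extended furthest
   is taken (ties again by the weighted draw). Dead-end terminal k-mers found
   during lookahead are memoised within the extension of one read, and
   failures that may merely reflect an exhausted budget are never memoised.
5. **Safety rails.** An extension is abandoned when it reaches
   `max_amplicon_length` (default 5000) or revisits the same terminal 32-mer
   more than `max_loop_visits` (default 4) times — the tandem-repeat guard
   that makes unbounded extension impossible.

Only terminated extensions are written out. Per-decision counters
(`stats_table()`) report how often each mechanism fired: on clean data the
single-choice-at-32 row dominates and lookahead is rare, which is also why
the recursion's worst-case cost rarely matters in practice.

All tie-breaking draws come from one generator seeded by `rng_seed`,
consumed in input-read order, so a run is byte-reproducible from its seed
and inputs; the global RNG state is saved and restored around the run.

## The synthetic communities

`make_community()` builds what the evaluation needs and nothing more: each
member is random flanking sequence (50 bp — enough for reads to bracket the
primer sites), a *shared* concrete instantiation of each primer site
(primer sites are conserved; sharing them is the worst case for phase 1,
which must fan out from one seed into every member), and an independent
random inter-primer region (250 bp by default, the 16S V4 size), with a
pairwise-divergence check (default: no two regions above 90% identity).
Strain pairs — copies of a member's region with a fixed number of SNPs —
can be added for tie-breaking studies. `simulate_reads()` draws uniform read
starts on both strands with i.i.d. substitution errors; per-member read
counts are fixed (not multinomial) at `depth * n_members * abundance_i` fold
coverage, so even abundances give every member the nominal depth exactly.

Default study conditions, fixed once: 15 members, 250 bp regions, 100 bp
reads, 30x per-member depth, error rate 0, EMP V4 primers. At 30x and 100 bp
reads every region 32-mer is expected to be covered ~20x, so complete
coverage (verifiable with `check_region_coverage()`) holds with margin. The
two-strain 90:10 fixture instead uses a mean per-member depth of 600x (so
the minor strain sits at ~120x): the proportional tie-breaker is only
reached when *both* alleles stay viable at every rung of the ladder, and the
minor allele's terminal 96-mer depth is only ~5% of its fold coverage — at
120x that is ~6 expected observations, comfortably above the denoising
floor; at 30x it would often vanish and the decision would (correctly, given
the evidence) collapse to the major strain at some longer k.

What the simulator does *not* model: quality scores, indels, coverage bias,
chimeras, fragment-length distributions, paired-end structure, and real
inter-species sequence structure (conserved domains inside the variable
region). Passing these tests therefore demonstrates the algorithm's logic —
selection, denoising, escalation, proportional tie-breaking, termination —
not robustness to every artefact of real sequencers. Conversely the shared
primer sites and uniform random regions make the fixtures *harder* than real
data in one respect: every member's extension starts from an identical
primer-adjacent k-mer neighbourhood.

`evaluate_amplicons()` scores distinct output sequences against the known
truth: exact sequence equality by default — the truth is known, so nothing
weaker is warranted — with an optional 97%-identity mode matching the OTU
convention for comparisons at clustering resolution. Members excluded for
known-incomplete coverage (e.g. an engineered gap) are removed from the
recall denominator, mirroring how organisms absent from the read data are
excluded from published benchmark evaluations.

## Numerical and degenerate-input choices

* Ambiguity resolution consults k = 32 first and escalates only on demand;
  the per-k decision counters are reported exactly so this behaviour is
  observable.
* `N` bases: windows containing `N` never enter filters or tables; an `N`
  in a read never matches a non-`N` primer position. A read whose tail
  reaches an `N` dead-ends and is abandoned, not guessed.
* Zero starting reads, empty files, or a filter that never grows all produce
  an empty FASTA plus a warning — exit status 0, since "no amplicon found"
  is a result, not a failure.
* Ties in the "longest downstream" rule are broken by the same
  depth-weighted draw as finishing ties, keeping the whole decision path
  seed-reproducible.
* `k_min` is validated at ≥ 16 in `run_config()` (below that, random k-mer
  collisions defeat the distinctiveness assumption the method rests on);
  library-level functions accept smaller k for constructed examples.

## Problem sizes used in the bundled checks

The test-suite and the acceptance script run entirely on generated data at
desk scale, chosen to exercise every decision path while staying quick: the
15-member community is ~1,800 reads and ~300 starting reads (a few seconds
end to end), and the deep two-strain fixture is ~4,700 reads and ~830
starting reads, of which ~80% meet an ambiguous decision at the SNP. The
proportional-draw frequency is measured over 100,000 draws.

## Known limitations

* Like any assembler, a region must be *completely* covered by overlapping
  reads to be reconstructed; rare community members with coverage gaps yield
  no amplicon (they are abandoned extensions, visible in the statistics).
* Counts of output amplicons reflect starting-read counts, i.e. coverage of
  the primer site, not organism abundance directly.
* Paired-end information is ignored; mates are independent reads.
* The denoising thresholds are heuristics exposed as flags; very low-depth
  data needs `min_count = 1`, at the cost of passing errors through.
* Extension is single-threaded; determinism is defined by input order and
  seed, not by scheduling.
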