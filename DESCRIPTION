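Package: ampliseek
Title: Targeted In-Silico Amplicon Assembly from Shotgun Metagenome Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts and assembles full-length inter-primer marker-gene
    sequences ("in-silico amplicons") from shotgun metagenome reads, given a
    pair of possibly degenerate PCR primers. Reads covering the primer-defined
    region are selected with an iteratively grown 32-mer filter, tiled into a
    ladder of denoised k-mer count tables, and reads carrying the forward
    primer are then extended one base at a time -- escalating to longer k-mers
    on ambiguity, looking downstream by bounded recursion, and breaking
    remaining ties at random in proportion to 32-mer depth -- until the
    reverse-primer site is reached. Includes a mock-community read simulator
    with ground truth and a precision/recall evaluator, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
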