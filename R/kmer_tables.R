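# k-mer tiling, the multi-length k-mer count table ladder, and denoising.
#
# Tables are hash maps (R environments) so membership tests during extension
# are O(1). Everything fits in memory at the scale of a primer-filtered read
# pool.

#' All N-free k-windows of a sequence
#'
#' @param x A/C/G/T/N string.
#' @param k window length.
#' @return character vector of windows (empty when `nchar(x) < k`); windows
#'   containing `N` are skipped.
#' @export
tile_windows <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  w <- substring(x, 1:(n - k + 1L), k:n)
  w[!grepl("N", w, fixed = TRUE)]
}

# --- k-mer hash set (used by the phase-1 region filter) ---------------------

new_kmer_set <- function() new.env(parent = emptyenv(), hash = TRUE)

ks_add <- function(set, kmers) {
  for (km in kmers) assign(km, TRUE, envir = set)
  invisible(set)
}

ks_has <- function(set, kmer) {
  exists(kmer, envir = set, inherits = FALSE)
}

ks_size <- function(set) length(set)

ks_keys <- function(set) ls(set, sorted = FALSE)

# --- k-mer count tables -----------------------------------------------------

#' Construct a k-mer count table
#'
#' @param k k-mer length.
#' @param counts named integer vector (names are length-`k` A/C/G/T strings).
#' @return object of class `kmer_table` with fields `k` and `env`
#'   (environment mapping k-mer to count).
#' @export
kmer_table <- function(k, counts = integer(0)) {
  stopifnot(k >= 1L)
  if (length(counts) && any(nchar(names(counts)) != k))
    stop("all k-mer keys must have length k = ", k, call. = FALSE)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (length(counts)) {
    counts <- stats::setNames(as.integer(counts), names(counts))
    list2env(as.list(counts), env)
  }
  structure(list(k = as.integer(k), env = env), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table k=%d, %d distinct k-mers>\n", x$k, kt_size(x)))
  invisible(x)
}

#' Number of distinct k-mers in a table
#' @param table a [kmer_table()].
#' @return integer.
#' @export
kt_size <- function(table) length(table$env)

#' Count of one k-mer (0 when absent)
#' @param table a [kmer_table()].
#' @param kmer length-`k` string.
#' @return integer count.
#' @export
kt_count <- function(table, kmer) {
  if (exists(kmer, envir = table$env, inherits = FALSE))
    get(kmer, envir = table$env, inherits = FALSE)
  else 0L
}

#' Is a k-mer present?
#' @inheritParams kt_count
#' @return logical.
#' @export
kt_has <- function(table, kmer) exists(kmer, envir = table$env, inherits = FALSE)

#' All k-mers of a table as a named count vector
#' @param table a [kmer_table()].
#' @return named integer vector.
#' @export
kt_counts <- function(table) {
  keys <- ls(table$env, sorted = FALSE)
  if (!length(keys)) return(stats::setNames(integer(0), character(0)))
  stats::setNames(vapply(keys, get, integer(1), envir = table$env), keys)
}

#' Build one k-mer count table from reads
#'
#' Tiles every N-free k-window of every read; reads shorter than `k`
#' contribute nothing.
#'
#' @param reads character vector of A/C/G/T/N sequences.
#' @param k k-mer length.
#' @return a [kmer_table()].
#' @export
build_kmer_table <- function(reads, k) {
  w <- unlist(lapply(reads, tile_windows, k = k), use.names = FALSE)
  if (!length(w)) return(kmer_table(k))
  tab <- table(w)
  kmer_table(k, stats::setNames(as.integer(tab), names(tab)))
}

#' The ladder of k values for a given read length
#'
#' k runs from `k_min` upward in steps of `k_step`, truncated at the read
#' length; 100 bp reads give nine values (32, 40, ..., 96).
#'
#' @param read_length dominant read length in bases.
#' @param k_min smallest k (default 32).
#' @param k_step increment (default 8).
#' @return integer vector (empty when `read_length < k_min`).
#' @export
k_values <- function(read_length, k_min = 32L, k_step = 8L) {
  if (read_length < k_min) return(integer(0))
  as.integer(seq(k_min, read_length, by = k_step))
}

#' Build the k-mer table ladder
#'
#' @param reads character vector of region reads (extension orientation).
#' @param ks increasing k values, e.g. from [k_values()].
#' @return object of class `kmer_ladder`: list with `tables` (named by k),
#'   `ks`, `k_min`.
#' @export
build_ladder <- function(reads, ks) {
  ks <- sort(unique(as.integer(ks)))
  if (!length(ks)) stop("no k values; reads shorter than k_min?", call. = FALSE)
  tables <- lapply(ks, function(k) build_kmer_table(reads, k))
  names(tables) <- as.character(ks)
  structure(list(tables = tables, ks = ks, k_min = ks[1L]),
            class = "kmer_ladder")
}

#' Assemble a ladder from existing tables
#'
#' Mostly useful for small constructed examples.
#'
#' @param tables list of [kmer_table()]s with strictly increasing `k`.
#' @return a `kmer_ladder`.
#' @export
kmer_ladder <- function(tables) {
  ks <- vapply(tables, `[[`, integer(1), "k")
  if (is.unsorted(ks, strictly = TRUE))
    stop("table k values must be strictly increasing", call. = FALSE)
  names(tables) <- as.character(ks)
  structure(list(tables = tables, ks = ks, k_min = ks[1L]),
            class = "kmer_ladder")
}

#' @export
print.kmer_ladder <- function(x, ...) {
  cat(sprintf("<kmer_ladder k = %s; sizes = %s>\n",
              paste(x$ks, collapse = ","),
              paste(vapply(x$tables, kt_size, integer(1)), collapse = ",")))
  invisible(x)
}

#' All Hamming-distance-1 neighbours of a k-mer
#' @param kmer A/C/G/T string.
#' @return character vector of length `3 * nchar(kmer)`.
#' @keywords internal
hamming1_neighbours <- function(kmer) {
  k <- nchar(kmer)
  bases <- c("A", "C", "G", "T")
  out <- character(3L * k)
  j <- 0L
  for (i in seq_len(k)) {
    cur <- substr(kmer, i, i)
    for (b in bases[bases != cur]) {
      s <- kmer
      substr(s, i, i) <- b
      j <- j + 1L
      out[j] <- s
    }
  }
  out
}

#' Denoise a k-mer count table
#'
#' Removes (a) k-mers seen fewer than `min_count` times, and (b) k-mers
#' dominated by a Hamming-distance-1 neighbour whose count is at least
#' `variant_ratio` times their own -- the k-mer spectrum signature of a
#' sequencing-error variant of an abundant k-mer. Genuine strain variants are
#' retained because their counts are not that lopsided. The operation is
#' idempotent.
#'
#' @param table a [kmer_table()].
#' @param min_count minimum count to keep (default 2).
#' @param variant_ratio dominance ratio for the error-variant rule
#'   (default 10).
#' @param hamming apply the neighbour rule (default TRUE; the pipeline uses it
#'   only at the smallest k, where neighbour enumeration is cheap and errors
#'   are caught before longer tables are consulted).
#' @return a new, possibly smaller [kmer_table()].
#' @export
denoise <- function(table, min_count = 2L, variant_ratio = 10, hamming = TRUE) {
  counts <- kt_counts(table)
  if (!length(counts)) return(kmer_table(table$k))
  keep <- counts >= min_count
  if (hamming && any(keep)) {
    maxc <- max(counts)
    for (km in names(counts)[keep]) {
      c0 <- counts[[km]]
      if (variant_ratio * c0 > maxc) next  # nothing could dominate it
      nb <- hamming1_neighbours(km)
      nbc <- counts[nb]
      if (any(!is.na(nbc) & nbc >= variant_ratio * c0)) keep[[km]] <- FALSE
    }
  }
  kmer_table(table$k, counts[keep])
}

#' Denoise every table of a ladder
#'
#' The error-variant (Hamming-1) rule is applied at `k_min` only; larger-k
#' tables are filtered on `min_count` alone.
#'
#' @param ladder a `kmer_ladder`.
#' @inheritParams denoise
#' @return a denoised `kmer_ladder`.
#' @export
denoise_ladder <- function(ladder, min_count = 2L, variant_ratio = 10) {
  tables <- lapply(ladder$tables, function(t) {
    denoise(t, min_count = min_count, variant_ratio = variant_ratio,
            hamming = (t$k == ladder$k_min))
  })
  structure(list(tables = tables, ks = ladder$ks, k_min = ladder$k_min),
            class = "kmer_ladder")
}

#' Per-k table sizes as a data frame (debug aid)
#' @param ladder a `kmer_ladder`.
#' @return data.frame with columns `k` and `n_kmers`.
#' @export
ladder_sizes <- function(ladder) {
  data.frame(k = ladder$ks,
             n_kmers = vapply(ladder$tables, kt_size, integer(1)),
             row.names = NULL)
}
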