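#' Mapping policy
#'
#' @param k Seed k-mer length (default 21).
#' @param max_mismatch_rate Mismatch budget as a fraction of read length;
#'   an alignment is kept when its mismatches are at most
#'   `floor(max_mismatch_rate * read_len)` (default 0.05).
#' @param require_unique_best Discard reads whose best alignment is not
#'   strictly better than the second best (default `TRUE`).
#' @param min_read_len Reads shorter than this are not mapped (default 20).
#' @return An object of class `map_policy`.
#' @export
map_policy <- function(k = 21L, max_mismatch_rate = 0.05,
                       require_unique_best = TRUE, min_read_len = 20L) {
  if (max_mismatch_rate <= 0 || max_mismatch_rate >= 0.5) {
    stop("max_mismatch_rate must be in (0, 0.5)")
  }
  structure(list(k = as.integer(k), max_mismatch_rate = max_mismatch_rate,
                 require_unique_best = isTRUE(require_unique_best),
                 min_read_len = as.integer(min_read_len)),
            class = "map_policy")
}

#' Build a dual-orientation reference index
#'
#' Every input chromosome is indexed twice: as itself and as its reverse
#' complement (entry name suffixed `_rc`). All alignments are then reported
#' in the forward orientation of one of the oriented entries -- a
#' reverse-strand hit on `chr1` is equivalently a forward hit on
#' `chr1_rc` -- mirroring a pipeline that maps against a doubled reference
#' and keeps only FLAG = 0 records.
#'
#' @param refs Named character vector of chromosome sequences (ACGT).
#' @param policy A [map_policy()].
#' @return An object of class `reference_index` with components `entries`
#'   (named character vector of both oriented copies), `lengths`, `k`,
#'   `policy`, and `n_kmer_positions` (total indexed k-mer positions,
#'   counting duplicates).
#' @export
build_index <- function(refs, policy = map_policy()) {
  if (length(refs) == 0L) stop("reference list is empty")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("reference sequences must be named")
  }
  refs <- toupper(refs)
  short <- nchar(refs) < policy$k
  if (any(short)) {
    warning("skipping ", sum(short), " reference entries shorter than k = ",
            policy$k)
    refs <- refs[!short]
    if (length(refs) == 0L) stop("no reference entries of length >= k remain")
  }
  entries <- c(refs, setNames(dna_revcomp(refs), paste0(names(refs), "_rc")))
  structure(list(
    entries = entries,
    lengths = setNames(nchar(entries), names(entries)),
    k = policy$k,
    policy = policy,
    n_kmer_positions = sum(pmax(nchar(entries) - policy$k + 1L, 0L))
  ), class = "reference_index")
}

#' Map reads against a dual-orientation reference index
#'
#' Seed-and-extend: every k-mer of a read seeds candidate diagonals, each
#' candidate is extended ungapped over the full read length and scored by
#' mismatch count. A read is reported only when its best alignment is
#' within the mismatch budget and (by default) strictly better than the
#' second-best candidate; ambiguous reads are discarded.
#'
#' @param reads A [fastq_set()] or character vector of read sequences.
#' @param index A [reference_index()][build_index()].
#' @return A `data.table` with columns `query_id`, `ref_entry` (oriented
#'   entry name), `pos` (1-based leftmost coordinate), `mismatches`,
#'   `mapped_len`; one row per mapped read.
#' @export
map_reads <- function(reads, index) {
  stopifnot(inherits(index, "reference_index"))
  if (inherits(reads, "fastq_set")) {
    ids <- reads$id
    seqs <- reads$seq
  } else {
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read_%d", seq_along(reads))
    seqs <- unname(as.character(reads))
  }
  pol <- index$policy
  hits <- cpp_map_reads(seqs, unname(index$entries), index$k,
                        pol$max_mismatch_rate, pol$require_unique_best,
                        pol$min_read_len)
  data.table(
    query_id = ids[hits$read_idx],
    ref_entry = names(index$entries)[hits$ref_idx],
    pos = hits$pos,
    mismatches = hits$mismatches,
    mapped_len = hits$mapped_len
  )
}

#' Map a single read
#'
#' @param read A character string or length-1 [fastq_set()].
#' @param index A [reference_index()][build_index()].
#' @return A one-row alignment `data.table`, or `NULL` when the read is
#'   unmappable or ambiguous.
#' @export
map_read <- function(read, index) {
  res <- map_reads(if (inherits(read, "fastq_set")) read[1] else read[1],
                   index)
  if (nrow(res) == 0L) NULL else res
}

#' Project an oriented-entry coordinate back to forward genome space
#'
#' An alignment at 1-based leftmost position `pos` with length `len` on the
#' reverse-complement copy of a chromosome of length `entry_len` starts, in
#' forward coordinates, at `entry_len - (pos + len - 1) + 1`.
#'
#' @param pos 1-based leftmost coordinate on the `_rc` entry.
#' @param len Alignment length.
#' @param entry_len Chromosome length.
#' @return 1-based leftmost forward-strand coordinate.
#' @export
rc_to_fwd_pos <- function(pos, len, entry_len) {
  entry_len - (pos + len - 1L) + 1L
}
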