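#' Two-round junction trimming policy
#'
#' Round 1 removes everything up to and including the 29-nt anchor +
#' partial-mosaic-end pattern, allowing up to `floor(round1_error_rate * 29)`
#' errors (2 at defaults) -- unit-cost substitutions and indels in `"edit"`
#' mode, substitutions only in `"hamming"` mode. The variable-length
#' balancer is removed implicitly because all bases 5' of the match are
#' discarded. Round 2 then requires the read to start exactly with the
#' remaining 10-nt mosaic end, removed with no mismatch allowed. Reads
#' failing either round, or left shorter than `min_remaining_len`, are
#' discarded together with their mates.
#'
#' @param round1_error_rate Maximum error rate for the round-1 match
#'   (default 0.10).
#' @param round1_window Read prefix length searched for the round-1 match
#'   (default 37 = max balancer 6 + pattern 29 + indel slack 2); the match
#'   must end within this window.
#' @param min_remaining_len Minimum read length after both rounds
#'   (default 20, a mappability floor).
#' @param error_model `"edit"` (substitutions + indels) or `"hamming"`
#'   (substitutions only).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(round1_error_rate = 0.10, round1_window = 37L,
                        min_remaining_len = 20L,
                        error_model = c("edit", "hamming")) {
  error_model <- match.arg(error_model)
  lc <- layout_constants()
  structure(list(
    round1_pattern = lc$round1_pattern,
    round1_error_rate = round1_error_rate,
    round1_max_errors = as.integer(floor(round1_error_rate *
                                           nchar(lc$round1_pattern))),
    round1_window = as.integer(round1_window),
    round2_pattern = lc$me10,
    min_remaining_len = as.integer(min_remaining_len),
    error_model = error_model
  ), class = "trim_policy")
}

# vectorised round-1 locate over a character vector of reads
locate_round1_many <- function(seqs, policy) {
  m <- cpp_locate_round1(seqs, policy$round1_pattern,
                         policy$round1_max_errors, policy$round1_window,
                         policy$error_model == "edit")
  list(end_offset = m[, 1], n_errors = m[, 2])
}

#' Locate the round-1 junction pattern in a read
#'
#' Finds the best occurrence of the 29-nt anchor + partial mosaic end near
#' the 5' end of Read 1. Ties are broken by fewest errors, then by the
#' smallest match end.
#'
#' @param read1 A single read: a character string or a length-1
#'   [fastq_set()].
#' @param policy A [trim_policy()].
#' @return A list with `end_offset` (1-based offset of the last matched
#'   base; trimming removes bases `1:end_offset`) and `n_errors`, or `NULL`
#'   when no match satisfies the error budget.
#' @export
locate_round1 <- function(read1, policy = trim_policy()) {
  seq <- if (inherits(read1, "fastq_set")) read1$seq[1] else as.character(read1)
  r <- locate_round1_many(seq, policy)
  if (is.na(r$end_offset[1])) return(NULL)
  list(end_offset = r$end_offset[1], n_errors = r$n_errors[1])
}

# core vectorised trimming; returns per-pair status and trimmed Read 1
trim_core <- function(seqs, quals, policy) {
  n <- length(seqs)
  status <- rep("KEPT", n)
  loc <- locate_round1_many(seqs, policy)
  end1 <- loc$end_offset
  status[is.na(end1)] <- "DROP_ROUND1"

  p2 <- policy$round2_pattern
  w2 <- nchar(p2)
  ok1 <- !is.na(end1)
  has_me10 <- rep(FALSE, n)
  has_me10[ok1] <- substr(seqs[ok1], end1[ok1] + 1L, end1[ok1] + w2) == p2
  status[ok1 & !has_me10] <- "DROP_ROUND2"

  cut <- ifelse(ok1 & has_me10, end1 + w2, NA_integer_)
  rem <- nchar(seqs) - cut
  short <- !is.na(cut) & rem < policy$min_remaining_len
  status[short] <- "DROP_SHORT"

  keep <- status == "KEPT"
  list(
    status = status,
    removed = cut,
    seq = ifelse(keep, substr(seqs, cut + 1L, nchar(seqs)), NA_character_),
    qual = ifelse(keep, substr(quals, cut + 1L, nchar(quals)), NA_character_)
  )
}

#' Trim a single read pair
#'
#' @param pair A [read_pairs()] object of length 1 (or any length; the
#'   first pair is used).
#' @param policy A [trim_policy()].
#' @return A list with `status` (`"KEPT"`, `"DROP_ROUND1"`,
#'   `"DROP_ROUND2"`, `"DROP_SHORT"`), `trimmed_read1` (a [fastq_set()] or
#'   `NULL`), `removed_prefix_len_r1`, and `removed_r2_mate` (`TRUE` when
#'   the pair is discarded).
#' @export
trim_pair <- function(pair, policy = trim_policy()) {
  stopifnot(inherits(pair, "read_pairs"))
  res <- trim_core(pair$r1$seq[1], pair$r1$qual[1], policy)
  kept <- res$status == "KEPT"
  list(
    status = res$status,
    trimmed_read1 = if (kept) fastq_set(pair$r1$id[1], res$seq, res$qual) else NULL,
    removed_prefix_len_r1 = if (kept) res$removed else NA_integer_,
    removed_r2_mate = !kept
  )
}

#' Filter and trim read pairs to junction reads
#'
#' Applies the two trimming rounds to every Read 1, keeping pairs whose
#' Read 1 passes both rounds (Read 2 is carried along unmodified) and
#' discarding the mates of failing reads. The usable-read fraction is the
#' kept fraction of all input pairs.
#'
#' @param pairs A [read_pairs()] object.
#' @param policy A [trim_policy()].
#' @return A list with `pairs` (kept pairs, Read 1 trimmed, input order
#'   preserved), `stats` (class `trim_stats`: `n_input`, `n_kept`,
#'   `n_drop_round1`, `n_drop_round2`, `n_drop_short`, `usable_fraction`),
#'   and `status` (per input pair).
#' @export
filter_pairs <- function(pairs, policy = trim_policy()) {
  stopifnot(inherits(pairs, "read_pairs"))
  n <- length(pairs)
  if (n == 0L) {
    stats <- structure(list(n_input = 0L, n_kept = 0L, n_drop_round1 = 0L,
                            n_drop_round2 = 0L, n_drop_short = 0L,
                            usable_fraction = 0), class = "trim_stats")
    return(list(pairs = pairs, stats = stats, status = character(0)))
  }
  res <- trim_core(pairs$r1$seq, pairs$r1$qual, policy)
  keep <- which(res$status == "KEPT")
  trimmed <- read_pairs(
    fastq_set(pairs$r1$id[keep], res$seq[keep], res$qual[keep]),
    pairs$r2[keep]
  )
  stats <- structure(list(
    n_input = n,
    n_kept = length(keep),
    n_drop_round1 = sum(res$status == "DROP_ROUND1"),
    n_drop_round2 = sum(res$status == "DROP_ROUND2"),
    n_drop_short = sum(res$status == "DROP_SHORT"),
    usable_fraction = length(keep) / n
  ), class = "trim_stats")
  list(pairs = trimmed, stats = stats, status = res$status)
}

#' @export
print.trim_stats <- function(x, ...) {
  cat(sprintf(
    "trim: %d pairs in, %d kept (usable fraction %.4f); dropped %d round-1, %d round-2, %d short\n",
    x$n_input, x$n_kept, x$usable_fraction,
    x$n_drop_round1, x$n_drop_round2, x$n_drop_short))
  invisible(x)
}
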