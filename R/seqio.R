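#' Create a set of sequencing reads
#'
#' Lightweight container for FASTQ records: parallel vectors of identifiers,
#' uppercase DNA sequences (`A`, `C`, `G`, `T`, `N`), and optional per-base
#' quality strings.
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of DNA sequences.
#' @param qual Optional character vector of quality strings, same lengths as
#'   `seq`; defaults to constant Q40 (`"I"`).
#' @return An object of class `fastq_set`.
#' @export
fastq_set <- function(id, seq, qual = NULL) {
  seq <- toupper(seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(seq))) stop("empty sequences are not allowed")
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  if (length(qual) != length(seq) || any(nchar(qual) != nchar(seq))) {
    stop("quality strings must match sequence lengths")
  }
  structure(list(id = unname(as.character(id)), seq = unname(seq),
                 qual = unname(qual)),
            class = "fastq_set")
}

#' @export
length.fastq_set <- function(x) length(x$id)

#' @export
`[.fastq_set` <- function(x, i) {
  fastq_set(x$id[i], x$seq[i], x$qual[i])
}

#' @export
print.fastq_set <- function(x, ...) {
  cat("<fastq_set> ", length(x), " reads\n", sep = "")
  invisible(x)
}

#' Pair identifier shared by two read mates
#'
#' Strips a trailing `/1` or `/2` and any space-delimited comment, covering
#' the common FASTQ naming dialects.
#'
#' @param id Character vector of read identifiers.
#' @return Character vector of pair identifiers.
#' @export
pair_id <- function(id) {
  sub("/[12]$", "", sub("\\s.*$", "", id))
}

#' Create a set of read pairs
#'
#' @param r1,r2 Two [fastq_set()] objects of equal length whose identifiers
#'   agree after [pair_id()] normalisation.
#' @return An object of class `read_pairs`.
#' @export
read_pairs <- function(r1, r2) {
  stopifnot(inherits(r1, "fastq_set"), inherits(r2, "fastq_set"))
  if (length(r1) != length(r2)) {
    stop("pairing error: Read 1 has ", length(r1), " records but Read 2 has ",
         length(r2))
  }
  bad <- which(pair_id(r1$id) != pair_id(r2$id))
  if (length(bad)) {
    stop("pairing error: mate identifiers disagree at record ", bad[1], " ('",
         r1$id[bad[1]], "' vs '", r2$id[bad[1]], "')")
  }
  structure(list(r1 = r1, r2 = r2), class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$r1)

#' @export
`[.read_pairs` <- function(x, i) {
  structure(list(r1 = x$r1[i], r2 = x$r2[i]), class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("<read_pairs> ", length(x), " pairs\n", sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; gzipped when it ends in `.gz`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A [fastq_set()].
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    fastq_set(names(x), as.character(x), as.character(mcols(x)$qualities))
  }, error = function(e) {
    stop("malformed FASTQ in '", path, "' (records must span 4 lines): ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Write a FASTQ file
#'
#' @param fq A [fastq_set()].
#' @param path Output path; gzipped when it ends in `.gz`.
#' @export
write_fastq <- function(fq, path) {
  stopifnot(inherits(fq, "fastq_set"))
  x <- Biostrings::DNAStringSet(fq$seq)
  names(x) <- fq$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(fq$qual),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 Paths to the Read 1 and Read 2 FASTQ files.
#' @return A [read_pairs()] object, pairs in file order.
#' @export
read_fastq_pairs <- function(path1, path2) {
  read_pairs(read_fastq(path1), read_fastq(path2))
}

#' Write paired FASTQ files
#'
#' @param pairs A [read_pairs()] object.
#' @param path1,path2 Output paths for Read 1 and Read 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  stopifnot(inherits(pairs, "read_pairs"))
  write_fastq(pairs$r1, path1)
  write_fastq(pairs$r2, path2)
  invisible(c(path1, path2))
}

# reference-space length consumed by a CIGAR string (M/D/N/=/X)
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    if (m[1] == -1L) return(NA_integer_)
    parts <- regmatches(cg, gregexpr("(\\d+)([MIDNSHP=X])", cg))[[1]]
    ops <- substr(parts, nchar(parts), nchar(parts))
    lens <- as.integer(substr(parts, 1L, nchar(parts) - 1L))
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from SAM text
#'
#' Parses the mandatory columns of a SAM text file (header lines beginning
#' `@` are skipped). Unmapped records (FLAG bit 0x4) are dropped;
#' reverse-strand records (FLAG bit 0x10) are kept but flagged with
#' orientation `"RC"` so the caller can discard them (see
#' [filter_forward()]), mirroring a FLAG = 0 filter. Only columns 1-6 are
#' interpreted; the CIGAR is used solely for the reference-space mapped
#' length. A mismatch count is taken from an `NM:i:` tag when present.
#'
#' @param path Path to a SAM text file.
#' @return A `data.table` with columns `query_id`, `ref_entry`,
#'   `orientation` (`"FWD"`/`"RC"`), `pos` (1-based leftmost), `mapped_len`,
#'   `mismatches`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.table(query_id = character(), ref_entry = character(),
                      orientation = character(), pos = integer(),
                      mapped_len = integer(), mismatches = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("SAM parse error in '", path, "': line ",
         which(nf < 6L)[1], " of the alignment section is missing mandatory ",
         "columns (QNAME..CIGAR)")
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  if (anyNA(flag)) stop("SAM parse error in '", path, "': non-numeric FLAG")
  keep <- bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:6)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  data.table(
    query_id = vapply(fields, `[[`, character(1), 1L),
    ref_entry = vapply(fields, `[[`, character(1), 3L),
    orientation = ifelse(bitwAnd(flag, 16L) > 0L, "RC", "FWD"),
    pos = as.integer(vapply(fields, `[[`, character(1), 4L)),
    mapped_len = cigar_ref_len(vapply(fields, `[[`, character(1), 6L)),
    mismatches = nm
  )
}

#' Keep only forward-orientation alignments
#'
#' The junction caller consumes forward-orientation alignments only (the
#' FLAG = 0 class when the reference carries both oriented copies of each
#' chromosome). Alignments produced by [map_reads()] are already all
#' forward; this filter is for externally ingested SAM records.
#'
#' @param aln An alignment table as returned by [read_sam_alignments()] or
#'   [map_reads()].
#' @return The subset with `orientation == "FWD"` (or `aln` unchanged when
#'   no orientation column is present).
#' @export
filter_forward <- function(aln) {
  aln <- as.data.table(aln)
  if ("orientation" %in% names(aln)) aln[orientation == "FWD"] else aln
}

#' Construct a junction table
#'
#' @param df A data.frame with columns `ref_entry` (oriented entry name,
#'   `"chr1"` or `"chr1_rc"`), `pos` (1-based leftmost coordinate), `count`
#'   (reads supporting the junction), and optionally `cpm` and `is_true`.
#' @param total_mapped_reads Total number of mapped alignments the counts
#'   were derived from; the CPM denominator.
#' @return An object of class `junction_table` (a data.frame with attribute
#'   `total_mapped_reads`).
#' @export
junction_table <- function(df, total_mapped_reads) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("ref_entry", "pos", "count") %in% names(df)))
  if (anyDuplicated(df[c("ref_entry", "pos")])) {
    stop("junction identities (ref_entry, pos) must be unique")
  }
  total_mapped_reads <- as.numeric(total_mapped_reads)
  df$cpm <- if (total_mapped_reads > 0) df$count / total_mapped_reads * 1e6
            else rep(0, nrow(df))
  if (is.null(df$is_true)) df$is_true <- rep(NA, nrow(df))
  df <- df[order(df$ref_entry, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, total_mapped_reads = total_mapped_reads,
            class = c("junction_table", "data.frame"))
}

#' Total mapped reads underlying a junction table
#' @param tab A [junction_table()].
#' @return A single number.
#' @export
total_mapped_reads <- function(tab) attr(tab, "total_mapped_reads")

# decompose oriented entry names into base reference + orientation
entry_orientation <- function(ref_entry) {
  ifelse(endsWith(ref_entry, "_rc"), "RC", "FWD")
}
entry_base <- function(ref_entry) sub("_rc$", "", ref_entry)

#' Write a junction table to TSV or BED
#'
#' The TSV has columns `ref`, `orientation`, `pos` (1-based), `count`,
#' `cpm`, `is_true`, preceded by a `#total_mapped_reads=` comment so the
#' file round-trips losslessly. BED6 output uses 0-based half-open
#' single-base intervals `[pos - 1, pos)` with `name` = orientation,
#' `score` = count, and `strand` `+`/`-` for forward/reverse junctions.
#'
#' @param tab A [junction_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_junction_table <- function(tab, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(inherits(tab, "junction_table"))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#total_mapped_reads=%.0f", total_mapped_reads(tab)), con)
    out <- data.frame(
      ref = entry_base(tab$ref_entry),
      orientation = entry_orientation(tab$ref_entry),
      pos = tab$pos, count = tab$count, cpm = tab$cpm, is_true = tab$is_true,
      stringsAsFactors = FALSE
    )
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ori <- entry_orientation(tab$ref_entry)
    out <- data.frame(
      chrom = entry_base(tab$ref_entry),
      start = tab$pos - 1L, end = tab$pos,
      name = ori, score = tab$count,
      strand = ifelse(ori == "RC", "-", "+"),
      stringsAsFactors = FALSE
    )
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a junction table written by [write_junction_table()]
#'
#' @param path Path to the TSV file.
#' @return A [junction_table()].
#' @export
read_junction_table <- function(path) {
  first <- readLines(path, n = 1L)
  total <- if (startsWith(first, "#total_mapped_reads=")) {
    as.numeric(sub("#total_mapped_reads=", "", first))
  } else {
    stop("not a junction TSV (missing #total_mapped_reads header): ", path)
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(junction_table(data.frame(ref_entry = character(), pos = integer(),
                                     count = integer()), total))
  }
  df$ref_entry <- ifelse(df$orientation == "RC", paste0(df$ref, "_rc"), df$ref)
  junction_table(df[c("ref_entry", "pos", "count", "is_true")], total)
}
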