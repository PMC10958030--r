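#' De-duplicate alignments into putative junctions
#'
#' Groups forward-orientation alignments by (oriented entry, leftmost
#' coordinate) and counts the reads supporting each coordinate. Each unique
#' coordinate is a putative transposon-DNA junction; the CPM denominator is
#' the number of alignments entering the caller.
#'
#' @param alignments An alignment table from [map_reads()] or
#'   [read_sam_alignments()] after [filter_forward()]. Must contain columns
#'   `ref_entry` and `pos`.
#' @return A [junction_table()] with `is_true` unset.
#' @export
putative_junctions <- function(alignments) {
  aln <- as.data.table(alignments)
  if ("orientation" %in% names(aln) && any(aln$orientation != "FWD")) {
    stop("alignments must be forward-orientation only; apply filter_forward()")
  }
  if (nrow(aln) == 0L) {
    return(junction_table(data.frame(ref_entry = character(), pos = integer(),
                                     count = integer()), 0))
  }
  grp <- aln[, .(count = .N), by = .(ref_entry, pos)]
  junction_table(grp, nrow(aln))
}

#' Classify putative junctions as true junctions
#'
#' Putative junctions supported by fewer than `cpm_min` counts per million
#' mapped reads are filtered out (flagged, not removed): `is_true` is
#' `cpm >= cpm_min`, the complement of a strict `< cpm_min` removal rule.
#'
#' @param table A [junction_table()].
#' @param cpm_min CPM support threshold (default 1).
#' @return The table with `is_true` set.
#' @export
classify_true <- function(table, cpm_min = 1.0) {
  stopifnot(inherits(table, "junction_table"))
  tot <- total_mapped_reads(table)
  table$is_true <- if (tot > 0) table$cpm >= cpm_min else
    rep(FALSE, nrow(table))
  table
}

#' Number of unique insertion sites (true junctions)
#'
#' @param table A [junction_table()] after [classify_true()].
#' @return Integer count of rows with `is_true`.
#' @export
uis_count <- function(table) {
  stopifnot(inherits(table, "junction_table"))
  sum(table$is_true, na.rm = TRUE)
}

#' Subsample read pairs to a fixed depth
#'
#' Uniform sample without replacement of exactly
#' `min(n_target, n_available)` pairs, preserving input order. Read depth
#' is equalised across strains and conditions before junction calling so
#' that UIS counts are comparable.
#'
#' @param pairs A [read_pairs()] object.
#' @param n_target Target number of pairs (default 5,000,000).
#' @param seed Integer seed.
#' @return A [read_pairs()] object.
#' @export
subsample_pairs <- function(pairs, n_target = 5e6, seed = 1L) {
  stopifnot(inherits(pairs, "read_pairs"))
  n <- length(pairs)
  if (n_target < 0) stop("n_target must be >= 0")
  if (n <= n_target) {
    if (n < n_target) {
      warning("only ", n, " pairs available; returning all of them")
    }
    return(pairs)
  }
  idx <- with_seed(seed, sort(sample.int(n, n_target)))
  pairs[idx]
}

#' Compare UIS counts across conditions
#'
#' Mirrors a selection-method comparison: per condition, the mean UIS
#' across replicates is expressed as a percentage of the reference
#' condition's mean. Replicate variability is the plus/minus half-range of
#' the per-replicate relative percentages for 2 replicates, or their
#' standard deviation for more.
#'
#' @param tables Named list: one [junction_table()] per condition, or a
#'   list of junction tables (replicates) per condition. Tables must have
#'   been through [classify_true()].
#' @param reference Name of the reference condition.
#' @param cfu Optional named numeric vector of CFU counts per condition;
#'   adds a `cfu_to_uis_pct` column (100 * mean UIS / CFU).
#' @return A data.frame of class `comparison_report` with columns
#'   `condition`, `n_replicates`, `mean_uis`, `relative_pct`, `variance`
#'   (and optionally `cfu`, `cfu_to_uis_pct`).
#' @export
compare_conditions <- function(tables, reference, cfu = NULL) {
  if (!reference %in% names(tables)) {
    stop("reference condition '", reference, "' not found")
  }
  reps <- lapply(tables, function(x) {
    if (inherits(x, "junction_table")) list(x) else x
  })
  uis <- lapply(reps, function(r) vapply(r, uis_count, numeric(1)))
  ref_mean <- mean(uis[[reference]])
  if (ref_mean == 0) stop("reference condition has zero UIS")
  rows <- lapply(names(reps), function(cond) {
    u <- uis[[cond]]
    rel <- 100 * u / ref_mean
    variance <- if (cond == reference || length(u) < 2L) NA_real_
      else if (length(u) == 2L) diff(range(rel)) / 2
      else stats::sd(rel)
    data.frame(condition = cond, n_replicates = length(u),
               mean_uis = mean(u), relative_pct = mean(rel),
               variance = variance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfu)) {
    out$cfu <- unname(cfu[out$condition])
    out$cfu_to_uis_pct <- 100 * out$mean_uis / out$cfu
  }
  structure(out, reference = reference,
            class = c("comparison_report", "data.frame"))
}

#' Precision and recall of junction recovery against simulation truth
#'
#' Projects the truth sites into oriented-entry space (see
#' [project_truth()]) and matches each called true junction to a truth site
#' on the same entry within `tolerance_bp`. Precision is the matched
#' fraction of called true junctions (1 by convention when none are
#' called); recall is the detected fraction of truth sites.
#'
#' @param table A [junction_table()] after [classify_true()].
#' @param truth An `insertion_truth` table from [sample_truth()].
#' @param ref_lengths Named integer vector of chromosome lengths.
#' @param tolerance_bp Maximum coordinate difference for a match
#'   (default 0, exact).
#' @return A list with `precision`, `recall`, `n_called`, `n_truth`,
#'   `detected_abundance_floor` (smallest clone abundance among detected
#'   sites, `NA` when none).
#' @export
recovery_metrics <- function(table, truth, ref_lengths, tolerance_bp = 0L) {
  stopifnot(inherits(table, "junction_table"))
  tp <- project_truth(truth, ref_lengths)
  called <- table[which(table$is_true), , drop = FALSE]
  if (nrow(called) == 0L) {
    return(list(precision = 1.0, recall = 0.0, n_called = 0L,
                n_truth = nrow(truth),
                detected_abundance_floor = NA_real_))
  }
  truth_key <- paste(tp$ref_entry, tp$entry_pos)
  shift <- seq.int(-tolerance_bp, tolerance_bp)
  called_keys <- lapply(shift, function(s) paste(called$ref_entry, called$pos + s))
  called_match <- Reduce(`|`, lapply(called_keys, function(k) k %in% truth_key))
  truth_match <- Reduce(`|`, lapply(shift, function(s) {
    paste(tp$ref_entry, tp$entry_pos + s) %in% paste(called$ref_entry, called$pos)
  }))
  detected_ab <- tp$abundance[truth_match]
  list(
    precision = mean(called_match),
    recall = mean(truth_match),
    n_called = nrow(called),
    n_truth = nrow(truth),
    detected_abundance_floor = if (any(truth_match)) min(detected_ab) else NA_real_
  )
}
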