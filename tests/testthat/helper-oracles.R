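# Independent reference implementations used to check the package kernels.

# Brute-force semi-global aligner: edit distance of `pattern` against every
# prefix-anchored window of each read, with free read prefix and suffix.
# Vectorised across reads via matrix dynamic programming; mirrors the
# documented trimming semantics (ties: fewest errors, then smallest end)
# but shares no code with the package implementation.
oracle_locate <- function(seqs, pattern, max_err, window,
                          mode = c("edit", "hamming")) {
  mode <- match.arg(mode)
  n <- length(seqs)
  w <- min(window, min(nchar(seqs)))
  stopifnot(all(nchar(seqs) >= w))
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  rm_ <- matrix(unlist(strsplit(substr(seqs, 1, w), "")), nrow = n,
                byrow = TRUE)
  end <- rep(NA_integer_, n)
  err <- rep(NA_integer_, n)
  if (mode == "edit") {
    prev <- matrix(0L, n, w + 1L)
    for (i in seq_len(m)) {
      cur <- matrix(0L, n, w + 1L)
      cur[, 1] <- i
      for (j in seq_len(w)) {
        mis <- (rm_[, j] != p[i]) | (rm_[, j] == "N")
        cur[, j + 1] <- pmin(prev[, j] + mis, prev[, j + 1] + 1L,
                             cur[, j] + 1L)
      }
      prev <- cur
    }
    d <- prev[, -1, drop = FALSE]  # d[, j] = errors for match ending at j
  } else {
    noff <- w - m + 1L
    if (noff < 1L) return(list(end = end, err = err))
    d <- matrix(NA_integer_, n, w)
    for (o in seq_len(noff)) {
      mm <- rowSums((rm_[, o:(o + m - 1), drop = FALSE] !=
                       matrix(p, n, m, byrow = TRUE)) |
                      (rm_[, o:(o + m - 1), drop = FALSE] == "N"))
      d[, o + m - 1L] <- as.integer(mm)
    }
  }
  for (i in seq_len(n)) {
    di <- d[i, ]
    best <- suppressWarnings(min(di, na.rm = TRUE))
    if (is.finite(best) && best <= max_err) {
      err[i] <- best
      end[i] <- which(di == best)[1]
    }
  }
  list(end = end, err = err)
}

# Exhaustive mapping oracle: scan all positions of all oriented entries with
# Biostrings' naive mismatch matcher, apply the same budget and unique-best
# rules as the documented mapper contract.
oracle_map_read <- function(seq, entries, max_mm_rate = 0.05,
                            min_read_len = 20L) {
  len <- nchar(seq)
  if (len < min_read_len) return(NULL)
  budget <- floor(max_mm_rate * len)
  pat <- Biostrings::DNAString(seq)
  best <- NULL
  best_mm <- Inf
  second <- Inf
  for (en in names(entries)) {
    subj <- Biostrings::DNAString(entries[[en]])
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = budget)
    if (length(hits) == 0) next
    mm <- Biostrings::neditStartingAt(pat, subj,
                                      starting.at = Biostrings::start(hits))
    for (i in seq_along(mm)) {
      if (mm[i] < best_mm) {
        second <- best_mm
        best_mm <- mm[i]
        best <- list(ref_entry = en, pos = Biostrings::start(hits)[i],
                     mismatches = mm[i])
      } else if (mm[i] < second) {
        second <- mm[i]
      }
    }
  }
  if (is.null(best) || best_mm > budget || !(best_mm < second)) return(NULL)
  best
}
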