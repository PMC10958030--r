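# internal helpers shared across modules

# reverse complement for character vectors of DNA (A/C/G/T/N)
dna_revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# random DNA string; uniform base usage (50% GC), optional homopolymer cap
random_dna <- function(n, max_homopolymer = Inf) {
  if (n <= 0) return("")
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, n, replace = TRUE)
  if (is.finite(max_homopolymer)) {
    repeat {
      r <- rle(x)
      bad <- which(r$lengths > max_homopolymer)
      if (length(bad) == 0L) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in bad) {
        brk <- seq(starts[i] + max_homopolymer, ends[i], by = max_homopolymer + 1L)
        x[brk] <- vapply(x[brk],
                         function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
    }
  }
  paste(x, collapse = "")
}

# derive a per-stage seed from the run seed, kept within 32-bit integer range
derive_seed <- function(seed, ordinal) {
  as.integer((as.numeric(seed) + ordinal) %% .Machine$integer.max)
}
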