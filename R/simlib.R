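#' Configuration for a simulated transposon-mutant library
#'
#' Defaults reflect the sequencing conditions of the workflow the package
#' models: 150 bp paired-end reads from 300-400 bp sonication fragments,
#' with roughly 80% of sequenced pairs carrying a transposon-DNA junction
#' and the remainder being non-junction genomic carryover.
#'
#' @param n_insertions Number of unique insertion sites in the library.
#' @param genome_len Total genome length in bp (default 200,000).
#' @param n_chromosomes Number of chromosomes the genome is split into.
#' @param abundance_sigma Log-normal shape parameter for clone abundances
#'   (0 = all clones equally abundant; default 1).
#' @param n_read_pairs Number of read pairs to simulate.
#' @param junction_fraction Fraction of pairs derived from junction
#'   fragments (default 0.8).
#' @param fragment_len_range Sonication fragment length range, bp.
#' @param read_len Read length, bp (default 150).
#' @param base_error_rate Per-base substitution error probability
#'   (default 0.001).
#' @param balancer_mode `"random"`: each junction read gets a fresh random
#'   balancer of length 3-6; `"fixed_set"`: one fixed balancer per length,
#'   drawn once from the seed, as in a real primer set.
#' @param seed Integer seed; all randomness in the simulation derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_insertions, genome_len = 200000L, n_chromosomes = 1L,
                       abundance_sigma = 1.0, n_read_pairs = 100000L,
                       junction_fraction = 0.8,
                       fragment_len_range = c(300L, 400L), read_len = 150L,
                       base_error_rate = 0.001,
                       balancer_mode = c("random", "fixed_set"), seed = 1L) {
  balancer_mode <- match.arg(balancer_mode)
  cfg <- list(
    n_insertions = as.integer(n_insertions),
    genome_len = as.integer(genome_len),
    n_chromosomes = as.integer(n_chromosomes),
    abundance_sigma = abundance_sigma,
    n_read_pairs = as.integer(n_read_pairs),
    junction_fraction = junction_fraction,
    fragment_len_range = as.integer(fragment_len_range),
    read_len = as.integer(read_len),
    base_error_rate = base_error_rate,
    balancer_mode = balancer_mode,
    seed = as.integer(seed)
  )
  if (cfg$n_insertions < 1L) stop("n_insertions must be >= 1")
  if (cfg$n_insertions > cfg$genome_len - 2L * cfg$read_len) {
    stop("config error: n_insertions exceeds genome_len - 2 * read_len")
  }
  if (cfg$junction_fraction < 0 || cfg$junction_fraction > 1) {
    stop("config error: junction_fraction must be in [0, 1]")
  }
  if (cfg$base_error_rate < 0 || cfg$base_error_rate >= 1) {
    stop("config error: base_error_rate must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a random genome
#'
#' @param len Total genome length in bp (>= 1000).
#' @param n_chrom Number of chromosomes; the length is split evenly, with
#'   the remainder on the last chromosome.
#' @param seed Integer seed.
#' @return A named character vector (`chr1` ... `chrN`) of uppercase ACGT
#'   sequences.
#' @export
simulate_genome <- function(len, n_chrom = 1L, seed = 1L) {
  len <- as.integer(len)
  n_chrom <- as.integer(n_chrom)
  if (len < 1000L) stop("config error: genome length must be >= 1000 bp")
  if (n_chrom < 1L) stop("config error: n_chrom must be >= 1")
  per <- len %/% n_chrom
  lens <- rep(per, n_chrom)
  lens[n_chrom] <- lens[n_chrom] + len - sum(lens)
  with_seed(seed, {
    setNames(vapply(lens, random_dna, character(1)),
             paste0("chr", seq_len(n_chrom)))
  })
}

#' Sample true insertion sites with clone abundances
#'
#' Draws `n` distinct insertion sites uniformly over the genome (at least
#' `read_len` from either contig end, so every junction read fits) with
#' random orientation, and i.i.d. log-normal(0, `sigma`) clone abundances
#' normalised to sum to 1. `pos` is the first genomic base downstream of the
#' transposon in read orientation: forward-orientation reads run rightward
#' from `pos` on the plus strand, reverse-orientation reads run leftward on
#' the minus strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n Number of insertion sites.
#' @param sigma Log-normal shape parameter (0 gives equal abundances).
#' @param seed Integer seed.
#' @param read_len Minimum distance of a site from either contig end.
#' @return An `insertion_truth` data.frame with columns `ref_id`, `pos`,
#'   `orientation` (`"FWD"`/`"RC"`), `abundance`.
#' @export
sample_truth <- function(genome, n, sigma = 1.0, seed = 1L, read_len = 150L) {
  n <- as.integer(n)
  lens <- nchar(genome)
  avail <- pmax(lens - 2L * read_len + 1L, 0L)
  if (n > sum(avail)) {
    stop("config error: cannot place ", n, " distinct sites at least ",
         read_len, " bp from contig ends")
  }
  with_seed(seed, {
    seen <- character(0)
    ref <- character(0); pos <- integer(0); ori <- character(0)
    while (length(seen) < n) {
      need <- n - length(seen)
      ri <- sample.int(length(genome), need, replace = TRUE,
                       prob = avail / sum(avail))
      p <- read_len + as.integer(ceiling(runif(need) * avail[ri]))
      o <- sample(c("FWD", "RC"), need, replace = TRUE)
      key <- paste(names(genome)[ri], p, o)
      fresh <- !duplicated(key) & !(key %in% seen)
      seen <- c(seen, key[fresh])
      ref <- c(ref, names(genome)[ri][fresh])
      pos <- c(pos, p[fresh])
      ori <- c(ori, o[fresh])
    }
    ab <- if (sigma == 0) rep(1, n) else rlnorm(n, 0, sigma)
    truth <- data.frame(ref_id = ref, pos = pos, orientation = ori,
                        abundance = ab / sum(ab), stringsAsFactors = FALSE)
    structure(truth, class = c("insertion_truth", "data.frame"))
  })
}

#' Project truth sites into oriented-entry coordinates
#'
#' Junction identity lives in oriented-entry space: a forward site on `chr1`
#' at `pos` keeps its coordinate, while a reverse site maps to entry
#' `chr1_rc` at `L - pos + 1` (`L` = chromosome length), matching the
#' leftmost coordinate the mapper reports for its reads.
#'
#' @param truth An `insertion_truth` table from [sample_truth()].
#' @param ref_lengths Named integer vector of chromosome lengths.
#' @return `truth` with two extra columns, `ref_entry` and `entry_pos`.
#' @export
project_truth <- function(truth, ref_lengths) {
  rc <- truth$orientation == "RC"
  truth$ref_entry <- ifelse(rc, paste0(truth$ref_id, "_rc"), truth$ref_id)
  L <- unname(ref_lengths[truth$ref_id])
  truth$entry_pos <- ifelse(rc, L - truth$pos + 1L, truth$pos)
  truth
}

# substitute each base with probability `rate` by a random different base
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  wid <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), wid, rate)
  kmax <- max(nerr)
  if (kmax == 0L) return(seqs)
  rot <- matrix(c("C", "G", "T",   # A ->
                  "A", "G", "T",   # C ->
                  "A", "C", "T",   # G ->
                  "A", "C", "G"),  # T ->
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_len(kmax)) {
    idx <- which(nerr >= k)
    p <- as.integer(ceiling(runif(length(idx)) * wid[idx]))
    cur <- substr(seqs[idx], p, p)
    ok <- cur %in% rownames(rot)  # leave N untouched
    pick <- as.integer(ceiling(runif(sum(ok)) * 3))
    repl <- rot[cbind(match(cur[ok], rownames(rot)), pick)]
    i2 <- idx[ok]
    s <- seqs[i2]
    substr(s, p[ok], p[ok]) <- repl
    seqs[i2] <- s
  }
  seqs
}

# random balancer strings of lengths 3-6 for n reads
random_balancers <- function(n, mode, lens) {
  blen <- lens[1] + as.integer(ceiling(runif(n) * (lens[2] - lens[1] + 1L))) - 1L
  if (mode == "fixed_set") {
    fixed <- vapply(lens[1]:lens[2], random_dna, character(1))
    fixed[blen - lens[1] + 1L]
  } else {
    full <- do.call(paste0, as.data.frame(
      matrix(sample(c("A", "C", "G", "T"), n * lens[2], replace = TRUE),
             nrow = n), stringsAsFactors = FALSE))
    substr(full, 1L, blen)
  }
}

#' Generate read pairs for a simulated library (in memory)
#'
#' With probability `junction_fraction` a pair is a junction fragment: a
#' truth site is chosen with probability proportional to its clone
#' abundance, and Read 1 is balancer + anchor + mosaic end + genomic
#' sequence from the site onward, truncated to `read_len`. Read 2 is the
#' reverse complement of the distal end of the fragment (length uniform in
#' `fragment_len_range`), which for these fragment sizes is entirely
#' genomic. Non-junction pairs are plain genomic fragments sequenced from
#' either end. Substitution errors are applied to every base independently
#' at `base_error_rate`.
#'
#' @param config A [sim_config()].
#' @param genome Named character vector of chromosome sequences.
#' @param truth An `insertion_truth` table from [sample_truth()].
#' @return A list with `pairs` (a [read_pairs()]), `is_junction` (logical
#'   per pair), and `site_idx` (truth row index per junction pair, `NA`
#'   otherwise).
#' @export
generate_read_pairs <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"))
  lc <- layout_constants()
  n <- config$n_read_pairs
  rl <- config$read_len
  glens <- nchar(genome)
  with_seed(derive_seed(config$seed, 1L), {
    is_junc <- runif(n) < config$junction_fraction
    nj <- sum(is_junc)
    frag <- config$fragment_len_range[1] + as.integer(
      ceiling(runif(n) * (config$fragment_len_range[2] -
                          config$fragment_len_range[1] + 1L))) - 1L

    seq1 <- character(n); seq2 <- character(n)
    site_idx <- rep(NA_integer_, n)

    if (nj > 0) {
      si <- sample.int(nrow(truth), nj, replace = TRUE, prob = truth$abundance)
      site_idx[is_junc] <- si
      bal <- random_balancers(nj, config$balancer_mode, lc$balancer_len_range)
      prefix <- paste0(bal, lc$anchor20, lc$me19)
      glen <- rl - nchar(prefix)
      ref <- truth$ref_id[si]
      pos <- truth$pos[si]
      L <- unname(glens[ref])
      fwd <- truth$orientation[si] == "FWD"
      gext <- frag[is_junc] - nchar(prefix)  # genomic extent of the fragment

      g1 <- character(nj); g2 <- character(nj)
      if (any(fwd)) {
        g1[fwd] <- substring(genome[ref[fwd]], pos[fwd],
                             pos[fwd] + glen[fwd] - 1L)
        e2 <- pmin(pos[fwd] + gext[fwd] - 1L, L[fwd])
        g2[fwd] <- dna_revcomp(substring(genome[ref[fwd]],
                                         pmax(e2 - rl + 1L, 1L), e2))
      }
      if (any(!fwd)) {
        g1[!fwd] <- dna_revcomp(substring(genome[ref[!fwd]],
                                          pos[!fwd] - glen[!fwd] + 1L,
                                          pos[!fwd]))
        s2 <- pmax(pos[!fwd] - gext[!fwd] + 1L, 1L)
        g2[!fwd] <- substring(genome[ref[!fwd]], s2,
                              pmin(s2 + rl - 1L, L[!fwd]))
      }
      seq1[is_junc] <- paste0(prefix, g1)
      seq2[is_junc] <- g2
    }

    if (nj < n) {
      bg <- !is_junc
      nb <- sum(bg)
      fl <- frag[bg]
      ri <- sample.int(length(genome), nb, replace = TRUE,
                       prob = glens / sum(glens))
      maxstart <- pmax(glens[ri] - fl + 1L, 1L)
      st <- as.integer(ceiling(runif(nb) * maxstart))
      en <- pmin(st + fl - 1L, glens[ri])
      flip <- runif(nb) < 0.5  # fragments are sequenced from either strand
      a <- substring(genome[names(genome)[ri]], st, pmin(st + rl - 1L, en))
      b <- dna_revcomp(substring(genome[names(genome)[ri]],
                                 pmax(en - rl + 1L, st), en))
      seq1[bg] <- ifelse(flip, b, a)
      seq2[bg] <- ifelse(flip, a, b)
    }

    seq1 <- mutate_bases(seq1, config$base_error_rate)
    seq2 <- mutate_bases(seq2, config$base_error_rate)
    ids <- sprintf("sim_%07d", seq_len(n))
    list(
      pairs = read_pairs(fastq_set(ids, seq1), fastq_set(ids, seq2)),
      is_junction = is_junc,
      site_idx = site_idx
    )
  })
}

#' Simulate a complete mutant library and write its files
#'
#' Convenience wrapper running [simulate_genome()], [sample_truth()], and
#' [generate_read_pairs()] from a single configuration, writing the genome
#' FASTA, paired FASTQ files, truth TSV, and a YAML manifest of all
#' parameters.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param compress Write gzipped FASTQ files (default `FALSE`).
#' @return Invisibly, a list of class `sim_output` with file paths
#'   (`genome_fasta`, `fastq_r1`, `fastq_r2`, `truth_tsv`, `manifest`), the
#'   in-memory `genome`, `truth`, and `pairs`, plus `is_junction`.
#' @export
simulate_library <- function(config, outdir, compress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config$genome_len, config$n_chromosomes,
                            seed = derive_seed(config$seed, 0L))
  truth <- sample_truth(genome, config$n_insertions, config$abundance_sigma,
                        seed = derive_seed(config$seed, 2L),
                        read_len = config$read_len)
  sim <- generate_read_pairs(config, genome, truth)

  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- list(
    genome_fasta = file.path(outdir, "genome.fasta"),
    fastq_r1 = file.path(outdir, paste0("reads_R1", ext)),
    fastq_r2 = file.path(outdir, paste0("reads_R2", ext)),
    truth_tsv = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.yaml")
  )
  write_fasta(genome, paths$genome_fasta)
  write_fastq_pairs(sim$pairs, paths$fastq_r1, paths$fastq_r2)
  write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(c(unclass(config),
                     list(n_pairs_written = length(sim$pairs))),
                   paths$manifest)
  invisible(structure(
    c(paths, list(genome = genome, truth = truth, pairs = sim$pairs,
                  is_junction = sim$is_junction, site_idx = sim$site_idx)),
    class = "sim_output"))
}

#' Read a truth TSV written by [simulate_library()]
#' @param path Path to the truth TSV.
#' @return An `insertion_truth` data.frame.
#' @export
read_truth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  structure(df, class = c("insertion_truth", "data.frame"))
}
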