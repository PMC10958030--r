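# Small fixture builders shared across test files.

LC <- layout_constants()

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute `k` distinct positions of `s` with different bases
sub_bases <- function(s, at) {
  for (p in at) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  s
}

# a canonical 150-nt junction read: balancer + 29-nt pattern + 10-nt ME +
# genomic filler
make_junction_read <- function(balancer = "TAC", genomic = NULL,
                               read_len = 150L) {
  head <- paste0(balancer, LC$round1_pattern, LC$me10)
  if (is.null(genomic)) genomic <- rand_dna(read_len - nchar(head))
  paste0(head, genomic)
}

pairs_from_seqs <- function(seqs1, seqs2 = NULL) {
  ids <- sprintf("p%04d", seq_along(seqs1))
  if (is.null(seqs2)) seqs2 <- vapply(nchar(seqs1), rand_dna, "")
  read_pairs(fastq_set(ids, seqs1), fastq_set(ids, seqs2))
}

# tiny error-free simulated library shared by mapper/junction tests
tiny_sim <- function(n_insertions = 30, n_read_pairs = 5000,
                     genome_len = 20000, junction_fraction = 0.9,
                     base_error_rate = 0, seed = 101) {
  cfg <- sim_config(n_insertions = n_insertions, genome_len = genome_len,
                    n_read_pairs = n_read_pairs,
                    junction_fraction = junction_fraction,
                    base_error_rate = base_error_rate, seed = seed)
  genome <- simulate_genome(cfg$genome_len, cfg$n_chromosomes, seed = seed + 1)
  truth <- sample_truth(genome, cfg$n_insertions, cfg$abundance_sigma,
                        seed = seed + 2)
  sim <- generate_read_pairs(cfg, genome, truth)
  list(config = cfg, genome = genome, truth = truth, pairs = sim$pairs,
       is_junction = sim$is_junction, site_idx = sim$site_idx)
}
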