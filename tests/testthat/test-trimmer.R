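test_that("a canonical junction read loses 29 then 10 bases and is kept", {
  set.seed(1)
  genomic <- rand_dna(111)
  read <- paste0(LC$round1_pattern, LC$me10, genomic)  # no balancer
  expect_equal(nchar(read), 150L)
  loc <- locate_round1(read)
  expect_equal(loc$end_offset, 29L)
  expect_equal(loc$n_errors, 0L)
  out <- trim_pair(pairs_from_seqs(read))
  expect_equal(out$status, "KEPT")
  expect_equal(out$removed_prefix_len_r1, 39L)
  expect_equal(out$trimmed_read1$seq, genomic)
  expect_false(out$removed_r2_mate)
})

test_that("the balancer is removed implicitly with the round-1 match", {
  set.seed(2)
  read <- make_junction_read(balancer = "TAC")
  loc <- locate_round1(read)
  expect_equal(loc$end_offset, 32L)  # 3-nt balancer + 29-nt pattern
  out <- trim_pair(pairs_from_seqs(read))
  expect_equal(out$status, "KEPT")
  expect_equal(out$removed_prefix_len_r1, 42L)
  expect_equal(nchar(out$trimmed_read1$seq), 108L)
})

test_that("round 1 tolerates floor(10% of 29) = 2 errors and no more", {
  # substitutions are planted at interior pattern positions (2-27): a
  # substitution at the first or last positions can be absorbed more cheaply
  # by the free read prefix or a boundary indel under edit distance
  set.seed(3)
  for (i in 1:20) {
    bal <- rand_dna(sample(3:6, 1))
    tail <- paste0(LC$me10, rand_dna(120))
    p2 <- sub_bases(LC$round1_pattern, sample(2:27, 2))
    r2 <- paste0(bal, p2, tail)
    loc <- locate_round1(r2)
    expect_equal(loc$n_errors, 2L)
    expect_equal(loc$end_offset, nchar(bal) + 29L)
    p3 <- sub_bases(LC$round1_pattern, sample(2:27, 3))
    expect_null(locate_round1(paste0(bal, p3, tail)))
  }
})

test_that("round 2 requires the exact 10-nt mosaic-end remnant", {
  set.seed(4)
  me10_bad <- sub_bases(LC$me10, 4)
  read <- paste0("TACG", LC$round1_pattern, me10_bad, rand_dna(107))
  out <- trim_pair(pairs_from_seqs(read))
  expect_equal(out$status, "DROP_ROUND2")
  expect_null(out$trimmed_read1)
  expect_true(out$removed_r2_mate)
})

test_that("reads left too short after trimming are dropped", {
  read <- paste0(LC$round1_pattern, LC$me10, "ACGTA")  # 5 nt remain
  out <- trim_pair(pairs_from_seqs(read))
  expect_equal(out$status, "DROP_SHORT")
  pol <- trim_policy(min_remaining_len = 5)
  expect_equal(trim_pair(pairs_from_seqs(read), pol)$status, "KEPT")
})

test_that("reads without the pattern are dropped in round 1", {
  set.seed(5)
  out <- trim_pair(pairs_from_seqs(rand_dna(150)))
  expect_equal(out$status, "DROP_ROUND1")
})

test_that("edit-mode locate agrees with the brute-force aligner", {
  set.seed(6)
  pol <- trim_policy()
  n <- 2000
  reads <- character(n)
  for (i in seq_len(n)) {
    kind <- i %% 5
    bal <- rand_dna(sample(3:6, 1))
    core <- LC$round1_pattern
    if (kind == 1) core <- sub_bases(core, sample(29, sample(1:2, 1)))
    if (kind == 2) core <- sub_bases(core, sample(29, sample(3:4, 1)))
    if (kind == 3) {  # deletion in the read
      p <- sample(2:28, 1)
      core <- paste0(substr(core, 1, p - 1), substr(core, p + 1, 29))
    }
    if (kind == 4) {  # insertion in the read
      p <- sample(2:28, 1)
      core <- paste0(substr(core, 1, p), rand_dna(1), substr(core, p + 1, 29))
    }
    reads[i] <- substr(paste0(bal, core, LC$me10, rand_dna(120)), 1, 150)
  }
  got <- tradiskit:::locate_round1_many(reads, pol)
  want <- oracle_locate(reads, pol$round1_pattern, pol$round1_max_errors,
                        pol$round1_window, "edit")
  expect_identical(got$end_offset, want$end)
  expect_identical(got$n_errors, want$err)
})

test_that("hamming mode agrees with its oracle and is never more permissive", {
  set.seed(7)
  pol_h <- trim_policy(error_model = "hamming")
  pol_e <- trim_policy(error_model = "edit")
  reads <- vapply(1:500, function(i) {
    core <- if (i %% 2) sub_bases(LC$round1_pattern, sample(29, sample(3, 1)))
            else rand_dna(29)
    paste0(rand_dna(sample(3:6, 1)), core, rand_dna(120))
  }, "")
  got <- tradiskit:::locate_round1_many(reads, pol_h)
  want <- oracle_locate(reads, pol_h$round1_pattern, pol_h$round1_max_errors,
                        pol_h$round1_window, "hamming")
  expect_identical(got$end_offset, want$end)
  expect_identical(got$n_errors, want$err)
  edit <- tradiskit:::locate_round1_many(reads, pol_e)
  ham_hit <- !is.na(got$end_offset)
  expect_true(all(!is.na(edit$end_offset[ham_hit])))
  expect_true(all(edit$n_errors[ham_hit] <= got$n_errors[ham_hit]))
})

test_that("filter_pairs preserves order, counts all drop reasons, and syncs mates", {
  set.seed(8)
  good <- vapply(1:30, function(i) make_junction_read(rand_dna(4)), "")
  bad1 <- vapply(1:10, function(i) rand_dna(150), "")
  bad2 <- vapply(1:10, function(i) {
    paste0("TAC", LC$round1_pattern, sub_bases(LC$me10, 5), rand_dna(108))
  }, "")
  seqs <- c(good, bad1, bad2)[order(runif(50))]
  pairs <- pairs_from_seqs(seqs)
  res <- filter_pairs(pairs)
  expect_equal(res$stats$n_input, 50L)
  expect_equal(res$stats$n_kept, 30L)
  expect_equal(res$stats$n_drop_round1, 10L)
  expect_equal(res$stats$n_drop_round2, 10L)
  expect_equal(res$stats$usable_fraction, 0.6)
  # kept Read 2 mates correspond to kept Read 1 ids, input order preserved
  expect_identical(res$pairs$r1$id, res$pairs$r2$id)
  expect_identical(res$pairs$r1$id, pairs$r1$id[res$status == "KEPT"])
})

test_that("trimming an error-free library is idempotent", {
  sim <- tiny_sim(junction_fraction = 1, n_read_pairs = 1000)
  res <- filter_pairs(sim$pairs)
  expect_equal(res$stats$usable_fraction, 1.0)
  again <- tradiskit:::locate_round1_many(res$pairs$r1$seq, trim_policy())
  expect_true(all(is.na(again$end_offset)))
})

test_that("usable fraction tracks the junction fraction on clean reads", {
  sim <- tiny_sim(junction_fraction = 0.8, n_read_pairs = 20000,
                  n_insertions = 100, genome_len = 50000)
  res <- filter_pairs(sim$pairs)
  expect_lt(abs(res$stats$usable_fraction - 0.8), 0.01)
})

test_that("empty input yields zero stats and no pairs", {
  pairs <- pairs_from_seqs(character(0))
  res <- filter_pairs(pairs)
  expect_equal(res$stats$n_input, 0L)
  expect_equal(res$stats$usable_fraction, 0)
  expect_equal(length(res$pairs), 0L)
})
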