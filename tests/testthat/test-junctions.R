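aln_at <- function(keys) {
  data.table::data.table(
    query_id = sprintf("q%d", seq_along(keys)),
    ref_entry = sub(":.*", "", keys),
    pos = as.integer(sub(".*:", "", keys)),
    mismatches = 0L, mapped_len = 100L
  )
}

test_that("de-duplication counts reads per (entry, leftmost coordinate)", {
  aln <- aln_at(c(rep("chr1:100", 5), rep("chr1_rc:250", 3)))
  tab <- putative_junctions(aln)
  expect_equal(nrow(tab), 2L)
  expect_equal(total_mapped_reads(tab), 8)
  expect_equal(tab$count[tab$ref_entry == "chr1"], 5L)
  expect_equal(tab$count[tab$ref_entry == "chr1_rc"], 3L)

  one <- putative_junctions(aln_at(rep("chr2:7", 1000)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 1000L)

  empty <- putative_junctions(aln_at(character(0)))
  expect_equal(nrow(empty), 0L)
  expect_equal(total_mapped_reads(empty), 0)
})

test_that("junction counts are conserved and permutation-invariant", {
  set.seed(20)
  keys <- sprintf("chr1:%d", sample(500, 2000, replace = TRUE))
  t1 <- putative_junctions(aln_at(keys))
  t2 <- putative_junctions(aln_at(sample(keys)))
  expect_equal(sum(t1$count), 2000L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_error(putative_junctions(
    data.frame(ref_entry = "chr1", pos = 1L, orientation = "RC")),
    "forward-orientation")
})

test_that("true-junction classification applies the CPM threshold inclusively", {
  df <- data.frame(ref_entry = "chr1", pos = c(10L, 20L, 30L),
                   count = c(1L, 2L, 4L))
  tab <- classify_true(junction_table(df, 2e6), cpm_min = 1)
  expect_equal(tab$cpm, c(0.5, 1.0, 2.0))
  expect_equal(tab$is_true, c(FALSE, TRUE, TRUE))  # cpm exactly 1 is kept
  expect_equal(uis_count(tab), 2L)
  # monotone: raising the threshold never increases UIS
  u <- vapply(c(0, 0.5, 1, 1.5, 2, 3),
              function(cm) uis_count(classify_true(junction_table(df, 2e6), cm)),
              numeric(1))
  expect_true(all(diff(u) <= 0))
  # zero denominator: nothing is true
  expect_equal(uis_count(classify_true(junction_table(df, 0))), 0L)
})

test_that("subsampling is exact, order-preserving, seeded, and warns when short", {
  pairs <- pairs_from_seqs(vapply(1:500, function(i) rand_dna(40), ""))
  sub <- subsample_pairs(pairs, 100, seed = 5)
  expect_equal(length(sub), 100L)
  expect_true(all(sub$r1$id %in% pairs$r1$id))
  expect_identical(sub$r1$id, intersect(pairs$r1$id, sub$r1$id))  # in order
  expect_identical(subsample_pairs(pairs, 100, seed = 5)$r1$id, sub$r1$id)
  expect_false(identical(subsample_pairs(pairs, 100, seed = 6)$r1$id,
                         sub$r1$id))
  expect_warning(out <- subsample_pairs(pairs, 1000, seed = 1), "available")
  expect_equal(length(out), 500L)
  expect_identical(subsample_pairs(pairs, 500, seed = 1), pairs)
})

test_that("UIS never increases under read downsampling", {
  sim <- tiny_sim(n_read_pairs = 8000, n_insertions = 60)
  idx <- build_index(sim$genome)
  call_uis <- function(pairs) {
    trimmed <- filter_pairs(pairs)
    uis_count(classify_true(putative_junctions(
      map_reads(trimmed$pairs$r1, idx))))
  }
  full <- call_uis(sim$pairs)
  for (s in 1:3) {
    down <- call_uis(subsample_pairs(sim$pairs, 2000, seed = s))
    expect_lte(down, full)
  }
})

test_that("condition comparison reports relative percentages as in a UIS table", {
  mk <- function(n) {
    classify_true(junction_table(
      data.frame(ref_entry = "chr1", pos = seq_len(n),
                 count = rep(10L, n)), 10 * n))
  }
  rep1 <- compare_conditions(
    list(agar = mk(10000), liquid = mk(8500)), reference = "agar")
  expect_equal(rep1$relative_pct[rep1$condition == "agar"], 100.0)
  expect_equal(rep1$relative_pct[rep1$condition == "liquid"], 85.0)

  rep2 <- compare_conditions(
    list(agar = list(mk(10000), mk(10000)),
         liquid = list(mk(8400), mk(8600))), reference = "agar")
  liquid <- rep2[rep2$condition == "liquid", ]
  expect_equal(liquid$relative_pct, 85.0)
  expect_equal(liquid$variance, 1.0)  # half-range of 84% and 86%
  expect_true(is.na(rep2$variance[rep2$condition == "agar"]))

  rep3 <- compare_conditions(list(a = mk(100), b = mk(50)), reference = "a",
                             cfu = c(a = 200, b = 200))
  expect_equal(rep3$cfu_to_uis_pct, c(50, 25))

  expect_error(compare_conditions(list(a = mk(10)), reference = "zzz"),
               "not found")
  none <- classify_true(junction_table(
    data.frame(ref_entry = "chr1", pos = 1L, count = 1L), 1e9))
  expect_error(compare_conditions(list(a = none), reference = "a"), "zero UIS")
})

test_that("recovery metrics match truth after orientation projection", {
  g <- c(chr1 = strrep("A", 1000))
  truth <- structure(
    data.frame(ref_id = c("chr1", "chr1"), pos = c(200L, 700L),
               orientation = c("FWD", "RC"), abundance = c(0.6, 0.4)),
    class = c("insertion_truth", "data.frame"))
  # RC site at 700 projects to chr1_rc at 1000 - 700 + 1 = 301
  tab <- classify_true(junction_table(
    data.frame(ref_entry = c("chr1", "chr1_rc", "chr2"),
               pos = c(200L, 301L, 50L), count = c(5L, 5L, 5L)), 15))
  m <- recovery_metrics(tab, truth, nchar(g))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1.0)
  expect_equal(m$detected_abundance_floor, 0.4)

  off <- classify_true(junction_table(
    data.frame(ref_entry = "chr1", pos = 202L, count = 5L), 5))
  expect_equal(recovery_metrics(off, truth, nchar(g))$recall, 0)
  expect_equal(recovery_metrics(off, truth, nchar(g), tolerance_bp = 2)$recall,
               0.5)

  none <- junction_table(data.frame(ref_entry = character(), pos = integer(),
                                    count = integer()), 0)
  none <- classify_true(none)
  m0 <- recovery_metrics(none, truth, nchar(g))
  expect_equal(m0$precision, 1.0)  # by convention
  expect_equal(m0$recall, 0.0)
})

test_that("recall is monotone in the matching tolerance", {
  sim <- tiny_sim(n_read_pairs = 3000, n_insertions = 40)
  idx <- build_index(sim$genome)
  trimmed <- filter_pairs(sim$pairs)
  tab <- classify_true(putative_junctions(map_reads(trimmed$pairs$r1, idx)))
  r <- vapply(0:3, function(tol) {
    recovery_metrics(tab, sim$truth, nchar(sim$genome), tol)$recall
  }, numeric(1))
  expect_true(all(diff(r) >= 0))
})
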