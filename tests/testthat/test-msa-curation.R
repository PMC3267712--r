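test_that("segment extraction drops outside columns and emptied rows", {
  a <- msa(c("r1", "r2", "r3"),
           c("ACDEFGHIKL", "AC--FGHI--", "ACDEFGHIKL"))
  s <- extract_segment(a, c(2L, 6L))
  expect_equal(dim(s), c(3L, 4L))
  expect_equal(s$seqs[1], "DEFG")

  # full-range interval is the identity
  expect_equal(extract_segment(a, c(0L, 10L))$seqs, a$seqs)

  # a row that is all-gap inside the interval is dropped and reported
  b <- msa(c("r1", "r2"), c("ABCD", "A--D"))
  s2 <- extract_segment(b, c(1L, 3L))
  expect_equal(s2$ids, "r1")
  expect_equal(attr(s2, "dropped"), "r2")
})

test_that("residue positions map to alignment columns", {
  a <- msa(c("q", "r"), c("-ME-AH", "AMEW-H"))
  # residue 1 of q ('M') sits in column 1 (0-based)
  expect_equal(residue_to_column(a, "q", c(1L, 3L)), c(1L, 4L))
  expect_error(residue_to_column(a, "q", 9L), "out of range")
})

test_that("pairwise identity ignores dual-gap columns", {
  expect_equal(pairwise_identity("MEAH", "MEAH"), 1.0)
  expect_equal(pairwise_identity("ME-H", "MEAH"), 0.75)
  expect_equal(pairwise_identity("----", "----"), 0.0)  # empty denominator
  expect_equal(pairwise_identity("ME--", "ME-W"), 2 / 3)
})

test_that("redundancy removal keeps the longer member, ties go to later id", {
  # identical rows: the lexicographically later id is removed
  a <- msa(c("alpha", "beta"), c("MEAH", "MEAH"))
  r <- remove_redundant(a, 0.8)
  expect_equal(r$aln$ids, "alpha")
  expect_equal(r$removed, "beta")

  # 0.85-identical pair, A longer => B removed
  b <- msa(c("A", "B"),
           c("MEAHWKLYPRDEAHWKLYPC", "MEAHWKLYPRDEAHWKLY--"))
  expect_gte(pairwise_identity(b$seqs[1], b$seqs[2]), 0.8)
  r2 <- remove_redundant(b, 0.8)
  expect_equal(r2$removed, "B")

  # all pairs below threshold: unchanged
  c3 <- msa(c("x", "y"), c("MEAH", "WKLY"))
  expect_equal(remove_redundant(c3, 0.8)$aln, c3)
})

test_that("progressive realignment is exact on pairs (enumeration oracle)", {
  set.seed(42)
  for (rep in 1:25) {
    a <- random_peptide(sample(2:5, 1), alphabet = c("A", "C", "D", "E"))
    b <- random_peptide(sample(2:5, 1), alphabet = c("A", "C", "D", "E"))
    aln <- realign(c(s1 = a, s2 = b))
    got <- attr(aln, "score")
    expect_equal(got, oracle_global_score(a, b),
                 info = sprintf("pair %s / %s", a, b))
  }
})

test_that("realignment is deterministic and order-invariant", {
  seqs <- c(s1 = "HEAAHWWKLY", s2 = "HEAAHWKLY", s3 = "HEGAHWWKLY",
            s4 = "PEAAHWWKLY")
  a1 <- realign(seqs)
  a2 <- realign(rev(seqs))
  expect_equal(sort(a1$ids), sort(a2$ids))
  m1 <- m60miner:::msa_matrix(a1)[sort(a1$ids), ]
  m2 <- m60miner:::msa_matrix(a2)[sort(a2$ids), ]
  expect_equal(m1, m2)

  # identical sequences align without gaps
  g <- realign(c(x = "MEAHW", y = "MEAHW"))
  expect_equal(g$seqs, c("MEAHW", "MEAHW"))
  expect_equal(pairwise_identity(g$seqs[1], g$seqs[2]), 1.0)
})

test_that("rare long indel blocks are stripped, short or common ones kept", {
  # 4 rows; 3-column block occupied by 1 row only -> deleted
  a <- msa(paste0("r", 1:4),
           c("MEAHWWWKLY", "MEAH---KLY", "MEAH---KLY", "MEAH---KLY"))
  s <- strip_rare_long_indels(a, 2L, 0.5)
  expect_equal(dim(s$aln)[2], 7L)
  expect_equal(s$removed_blocks$start, 4L)
  expect_equal(s$removed_blocks$end, 7L)

  # 2-column block at the length boundary (max_indel_len = 2) -> kept
  b <- msa(paste0("r", 1:4),
           c("MEAHWWKLY", "MEAH--KLY", "MEAH--KLY", "MEAH--KLY"))
  expect_equal(dim(strip_rare_long_indels(b, 2L, 0.5)$aln)[2], 9L)

  # occupancy 3/4 >= 0.5 -> kept regardless of length
  c3 <- msa(paste0("r", 1:4),
            c("MEAHWWWKLY", "MEAHWWWKLY", "MEAHWWWKLY", "MEAH---KLY"))
  expect_equal(dim(strip_rare_long_indels(c3, 2L, 0.5)$aln)[2], 10L)

  # occupancy exactly at the threshold is not insert-like
  d <- msa(paste0("r", 1:4),
           c("MEAHWWWKLY", "MEAHWWWKLY", "MEAH---KLY", "MEAH---KLY"))
  expect_equal(dim(strip_rare_long_indels(d, 2L, 0.5)$aln)[2], 10L)
})

test_that("curation removes planted duplicates and inserts, then converges", {
  fx <- curation_fixture(synthetic_config(seed = 11))
  cu <- curate(fx$aln, curation_params())
  expect_true(cu$report$converged)
  expect_equal(dim(cu$aln)[1], fx$expected_rows)
  expect_equal(dim(cu$aln)[2], fx$expected_cols)
  removed <- cu$report$actions$target[cu$report$actions$action == "remove_redundant"]
  expect_setequal(removed, fx$duplicate_ids)
})

test_that("curation reports non-convergence when iterations are capped", {
  fx <- curation_fixture(synthetic_config(seed = 12))
  cu <- curate(fx$aln, curation_params(max_iterations = 1L))
  expect_false(cu$report$converged)
})

test_that("an already-curated alignment is a fixed point", {
  fx <- curation_fixture(synthetic_config(seed = 13))
  once <- curate(fx$aln, curation_params())
  twice <- curate(once$aln, curation_params())
  expect_equal(twice$aln, once$aln)
  expect_equal(twice$report$iterations, 1L)
})
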