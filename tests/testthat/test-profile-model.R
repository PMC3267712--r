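make_onehot_profile <- function(consensus, gap_open = 4, gap_extend = 1,
                                eps = 1e-9) {
  # near-deterministic emissions concentrated on a consensus string
  K <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1]]
  em <- matrix(eps / 19, K, 20, dimnames = list(NULL, m60miner:::AA20))
  for (i in seq_len(K)) em[i, cons[i]] <- 1 - eps
  structure(list(profile_id = "onehot", match_columns = seq_len(K) - 1L,
                 emissions = em, background = uniform_background(),
                 gap_open = gap_open, gap_extend = gap_extend,
                 provenance = list()), class = "profile_model")
}

test_that("profile emissions follow the pseudocount formula", {
  # column of 27 'A' with weight 1 and uniform background: (27+1)/(27+20)
  a <- msa(sprintf("r%02d", 1:27), rep("A", 27))
  p <- build_profile(a, pseudocount_weight = 1)
  expect_equal(unname(p$emissions[1, "A"]), 28 / 47)
  expect_equal(unname(p$emissions[1, "C"]), 1 / 47)
  expect_equal(sum(p$emissions[1, ]), 1, tolerance = 1e-12)

  # single-sequence alignment: three match states
  p3 <- build_profile(msa("r1", "HEH"))
  expect_equal(profile_length(p3), 3L)
  expect_equal(unname(p3$emissions[1, "H"]), (1 + 1) / (1 + 20))

  # 40% occupancy column is excluded from match states
  b <- msa(paste0("r", 1:5), c("HA", "HA", "H-", "H-", "H-"))
  pb <- build_profile(b)
  expect_equal(pb$match_columns, 0L)
  # no column at or above half occupancy: profile construction refuses
  expect_error(build_profile(msa(paste0("r", 1:7),
                                 c("A--", "A--", "-A-", "-A-",
                                   "--A", "--A", "--A"))),
               "occupancy")
})

test_that("consensus of a concentrated profile scores the closed form", {
  p <- make_onehot_profile("HEWKY")
  hit <- score_sequence(p, c(s = "HEWKY"))
  expect_equal(hit$bit_score, 5 * log2((1 - 1e-9) / (1 / 20)),
               tolerance = 1e-6)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 5L)

  # residues emitted exactly at background score 0 (empty envelope)
  flat <- p
  flat$emissions[] <- 1 / 20
  hit0 <- score_sequence(flat, c(s = "HEWKY"))
  expect_equal(hit0$bit_score, 0)
  expect_true(is.na(hit0$start))
})

test_that("the DP scorer matches exhaustive path enumeration", {
  set.seed(7)
  for (rep in 1:120) {
    K <- sample(2:4, 1)
    L <- sample(2:6, 1)
    aln_rows <- vapply(1:3, function(i) random_peptide(K), character(1))
    prof <- build_profile(msa(paste0("r", 1:3), aln_rows),
                          gap_open = sample(2:5, 1), gap_extend = 1)
    s <- random_peptide(L)
    got <- score_sequence(prof, c(x = s))$bit_score
    want <- oracle_local_score(prof, strsplit(s, "")[[1]])
    expect_equal(got, want, tolerance = 1e-9,
                 info = sprintf("rep %d: seq %s", rep, s))
  }
})

test_that("ambiguity letters score as background in match states", {
  p <- make_onehot_profile("HEWKY")
  # X at a consensus position contributes 0 instead of the match reward
  full <- score_sequence(p, c(s = "HEWKY"))$bit_score
  amb <- score_sequence(p, c(s = "HEXKY"))$bit_score
  expect_equal(amb, full - log2((1 - 1e-9) / (1 / 20)), tolerance = 1e-6)
})

test_that("calibration is seeded, deterministic, and scale-covariant", {
  sim <- generate(synthetic_config(seed = 2, n_taxa = 8L,
                                   proteins_per_taxon = 2L,
                                   families = list(list(family_id = "famA",
                                                        domain_length = 60L,
                                                        conservation = 0.85,
                                                        n_carriers = 6L))))
  p <- build_profile(sim$family_alignments$famA)
  f1 <- calibrate(p, 150L, n_decoys = 60L, seed = 9L)
  f2 <- calibrate(p, 150L, n_decoys = 60L, seed = 9L)
  expect_equal(f1$location, f2$location)
  expect_equal(f1$scale, f2$scale)
  expect_gt(f1$scale, 0)

  # doubling the spread of the scores doubles the fitted Gumbel scale
  set.seed(31)
  x <- -log(-log(runif(1000))) * 2.5 + 10   # Gumbel(10, 2.5) sample
  fit1 <- m60miner:::fit_gumbel(x)
  fit2 <- m60miner:::fit_gumbel(2 * x)
  expect_equal(unname(fit2[["scale"]] / fit1[["scale"]]), 2, tolerance = 1e-6)
  expect_equal(fit1[["scale"]], 2.5, tolerance = 0.2)
})

test_that("E-values follow the extreme-value law", {
  fit <- structure(list(location = 12, scale = 2), class = "calibration_fit")
  expect_equal(e_value(fit, 12, 1), 1 - exp(-1))   # at the location
  expect_equal(e_value(fit, 1e6, 1), 0)            # limit at +infinity
  expect_equal(e_value(fit, 15, 10), 10 * e_value(fit, 15, 1))  # linearity
  # strictly decreasing in the score (within the non-saturated range)
  s <- seq(10, 30, by = 0.5)
  expect_true(all(diff(e_value(fit, s, 1)) < 0))
})

test_that("search recovers planted carriers and nothing else", {
  sim <- generate(synthetic_config(seed = 5))
  p <- build_profile(sim$family_alignments$famA, "famA")
  fit <- calibrate(p, nchar(sim$records$residues), n_decoys = 100L, seed = 3L)
  hits <- search_profile(p, sim$records, fit, e_cutoff = 1e-5)
  carriers_A <- sim$truth$protein_id[sim$truth$carrier &
                                       sim$truth$family_id == "famA"]
  expect_gte(sum(carriers_A %in% hits$target_id) / length(carriers_A), 0.95)
  background <- sim$truth$protein_id[!sim$truth$carrier]
  expect_equal(sum(background %in% hits$target_id), 0L)
  # hits are a filter of score_sequence output: no recomputation drift
  i <- which(sim$records$id == hits$target_id[1])
  expect_equal(hits$bit_score[1],
               score_sequence(p, sim$records[i, ])$bit_score)
  # e_cutoff 0 yields nothing
  expect_equal(nrow(search_profile(p, sim$records, fit, e_cutoff = 0)), 0L)
})

test_that("score-difference partition handles missing scores and ties", {
  ha <- data.frame(target_id = c("p1", "p2", "p4"),
                   bit_score = c(260, 50, 30))
  hb <- data.frame(target_id = c("p2", "p3", "p4"),
                   bit_score = c(80, 40, 30))
  pr <- partition_by_score_difference(ha, hb)
  tab <- pr$table
  expect_equal(tab$delta[tab$target_id == "p1"], 260)  # absent from B -> +260
  expect_equal(tab$assignment[tab$target_id == "p1"], "A")
  expect_equal(tab$assignment[tab$target_id == "p2"], "B")  # 50 - 80 = -30
  expect_equal(tab$assignment[tab$target_id == "p4"], "tie")
  expect_equal(sum(pr$counts), nrow(tab))
  # swapping the profile roles maps A counts to B counts exactly
  sw <- partition_by_score_difference(hb, ha)
  expect_equal(unname(sw$counts["A"]), unname(pr$counts["B"]))
  expect_equal(unname(sw$counts["B"]), unname(pr$counts["A"]))
  # duplicate targets are rejected
  expect_error(partition_by_score_difference(
    data.frame(target_id = c("p1", "p1"), bit_score = c(1, 2)), hb),
    "duplicate target")
})

test_that("profile TSV serialisation round-trips", {
  sim <- generate(synthetic_config(seed = 2, n_taxa = 8L,
                                   proteins_per_taxon = 2L,
                                   families = list(list(family_id = "famA",
                                                        domain_length = 40L,
                                                        conservation = 0.85,
                                                        n_carriers = 6L))))
  p <- build_profile(sim$family_alignments$famA, "famA")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$profile_id, p$profile_id)
  expect_equal(q$match_columns, p$match_columns)
  expect_equal(q$emissions, p$emissions, tolerance = 1e-8)
  s <- c(x = random_peptide(60))
  expect_equal(score_sequence(q, s)$bit_score,
               score_sequence(p, s)$bit_score, tolerance = 1e-6)
})
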