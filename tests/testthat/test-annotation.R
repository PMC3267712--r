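mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(target_id = "p1", domain_id = r[[1]], start = r[[2]],
               end = r[[3]], bit_score = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("architecture assembly resolves overlaps greedily by score", {
  # disjoint hits: both kept, ordered by start
  a <- assemble_architecture(mk_hits(list("CBM32", 200L, 300L, 50),
                                     list("PF13402", 10L, 100L, 80)))
  expect_equal(a$hits$domain_id, c("PF13402", "CBM32"))

  # nested lower-scoring hit dropped at the default tolerance
  b <- assemble_architecture(mk_hits(list("PF13402", 0L, 100L, 80),
                                     list("PF03272", 20L, 60L, 30)))
  expect_equal(b$hits$domain_id, "PF13402")

  # tolerance 1.0 keeps everything
  c3 <- assemble_architecture(mk_hits(list("PF13402", 0L, 100L, 80),
                                      list("PF03272", 20L, 60L, 30)),
                              overlap_tolerance = 1.0)
  expect_equal(nrow(c3$hits), 2L)

  # input order does not matter
  h <- mk_hits(list("A", 0L, 50L, 10), list("B", 40L, 90L, 20),
               list("C", 80L, 130L, 15))
  a1 <- assemble_architecture(h)
  a2 <- assemble_architecture(h[c(3, 1, 2), ])
  expect_equal(a1$hits, a2$hits)

  expect_error(assemble_architecture(mk_hits(list("A", 0L, 50L, 10)),
                                     seq_length = 40L), "outside sequence")
})

test_that("co-occurrence counts domains and proteins over focal carriers", {
  archs <- list(
    assemble_architecture(data.frame(
      target_id = "p1", domain_id = c("PF13402", "CBM32", "CBM32"),
      start = c(0L, 120L, 240L), end = c(100L, 220L, 340L),
      bit_score = c(80, 40, 40))),
    assemble_architecture(data.frame(
      target_id = "p2", domain_id = c("PF13402", "CBM32", "CBM32", "BACON"),
      start = c(0L, 120L, 240L, 360L), end = c(100L, 220L, 340L, 420L),
      bit_score = c(80, 40, 40, 25))),
    assemble_architecture(data.frame(
      target_id = "p3", domain_id = "CBM32", start = 0L, end = 100L,
      bit_score = 40)))
  tab <- cooccurrence_table(archs, "PF13402")
  # two focal proteins carry 2 CBM32 each: (CBM32, 4, 2); p3 is not focal
  expect_equal(tab$n_domains[tab$domain_id == "CBM32"], 4L)
  expect_equal(tab$n_proteins[tab$domain_id == "CBM32"], 2L)
  expect_equal(tab$n_proteins[tab$domain_id == "BACON"], 1L)
  expect_equal(tab$domain_id, c("CBM32", "BACON"))  # sorted by n_proteins

  # total instances bookkeeping
  expect_equal(sum(tab$n_domains), 5L)

  # no co-occurring domains -> empty table
  solo <- list(assemble_architecture(data.frame(
    target_id = "q", domain_id = "PF13402", start = 0L, end = 50L,
    bit_score = 10)))
  expect_equal(nrow(cooccurrence_table(solo, "PF13402")), 0L)
})

test_that("combination queries respect required and forbidden sets", {
  archs <- list(
    assemble_architecture(data.frame(
      target_id = "p1", domain_id = c("PF13402", "CBM32"),
      start = c(0L, 150L), end = c(100L, 250L), bit_score = c(80, 40))),
    assemble_architecture(data.frame(
      target_id = "p2", domain_id = c("PF13402", "CBM51"),
      start = c(0L, 150L), end = c(100L, 250L), bit_score = c(80, 40))),
    assemble_architecture(data.frame(
      target_id = "p3", domain_id = "PF13402", start = 0L, end = 100L,
      bit_score = 80)))
  expect_equal(combination_query(archs, c("PF13402", "CBM32")), "p1")
  expect_equal(combination_query(archs, "PF13402", forbidden = "CBM51"),
               c("p1", "p3"))
  expect_equal(combination_query(archs, character()), c("p1", "p2", "p3"))
  expect_equal(combination_query(archs, "PF13402", forbidden = "PF13402"),
               character())
  expect_error(combination_query(archs, "NOPE"), "unknown domain id")
  # consistency: a single-domain query equals the set listing that domain
  expect_setequal(combination_query(archs, "PF13402"),
                  vapply(archs, `[[`, "", "target_id"))
})

test_that("the surface heuristic flags planted features and nothing on poly-S", {
  # planted lipobox LSGC with the cysteine at position 18
  lip <- c(s = paste0(strrep("S", 14), "LSGC", strrep("S", 60)))
  f <- flag_surface(lip)
  expect_equal(f$lipoprotein, "yes")
  expect_true(f$extracellular_candidate)
  expect_equal(unname(f$provenance["lipoprotein"]), "heuristic")

  # hydrophobic N-terminal window after a basic residue: signal peptide
  sp <- c(s = paste0("MKRLLIVLLIVLLI", strrep("S", 80)))
  expect_equal(flag_surface(sp)$signal_peptide, "yes")

  polyS <- flag_surface(c(s = strrep("S", 100)))
  expect_equal(polyS$signal_peptide, "no")
  expect_equal(polyS$tmd_count, 0L)
  expect_equal(polyS$lipoprotein, "no")
  expect_false(polyS$extracellular_candidate)

  # a long hydrophobic stretch after residue 40 counts as a TMD
  tm <- c(s = paste0(strrep("S", 50), strrep("L", 24), strrep("S", 40)))
  expect_gte(flag_surface(tm)$tmd_count, 1L)
})

test_that("external predictions take precedence over the heuristic", {
  ext <- data.frame(target_id = "s", signal_peptide = "yes",
                    tmd_count = NA_integer_, lipoprotein = "no",
                    stringsAsFactors = FALSE)
  f <- flag_surface(c(s = strrep("S", 100)), external_predictions = ext)
  expect_equal(f$signal_peptide, "yes")
  expect_equal(unname(f$provenance["signal_peptide"]), "external")
  expect_equal(unname(f$provenance["tmd_count"]), "heuristic")  # NA falls back
  expect_true(f$extracellular_candidate)
})

test_that("surface fractions count unknowns in the denominator", {
  mk <- function(id, flag) {
    structure(list(target_id = id, hits = m60miner:::empty_hits(),
                   motif_status = NA_character_,
                   surface = list(extracellular_candidate = flag)),
              class = "protein_architecture")
  }
  archs <- list(mk("a", TRUE), mk("b", TRUE), mk("c", TRUE), mk("d", FALSE))
  expect_equal(surface_fraction(archs), 0.75)
  unknowns <- list(mk("a", NA), mk("b", NA))
  expect_equal(surface_fraction(unknowns), 0.0)
  expect_error(surface_fraction(list()), "empty")
})

test_that("planted surface prevalence is recovered through external tables", {
  cfg <- synthetic_config(seed = 21, n_taxa = 140L, proteins_per_taxon = 3L,
                          surface = list(sp_fraction = 0.76,
                                         lipobox_fraction = 0),
                          families = list(list(family_id = "famA",
                                               domain_length = 80L,
                                               conservation = 0.85,
                                               n_carriers = 400L)))
  sim <- generate(cfg)
  carriers <- sim$truth$protein_id[sim$truth$carrier]
  no_hits <- data.frame(target_id = character(), domain_id = character(),
                        start = integer(), end = integer(),
                        bit_score = numeric(), stringsAsFactors = FALSE)
  archs <- lapply(carriers, function(id) {
    rec <- sim$records[sim$records$id == id, , drop = FALSE]
    assemble_architecture(no_hits,
                          surface = flag_surface(rec, sim$external_predictions))
  })
  for (i in seq_along(archs)) archs[[i]]$target_id <- carriers[i]
  frac <- surface_fraction(archs)
  expect_gte(frac, 0.71)
  expect_lte(frac, 0.81)
})
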