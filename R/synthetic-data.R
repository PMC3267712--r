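# Ground-truth proteome generator: protein families emitted from positional
# residue profiles implanted in background sequence, planted zincin/gluzincin
# motifs with controlled spacers, diverged sister families for the subfamily
# partition, surface-feature planting, and habitat tables with a configured
# genotype-trait odds ratio. Everything is deterministic given one seed.

#' Configuration for the synthetic proteome generator
#'
#' Defaults describe the regime the pipeline assumes: two diverged sister
#' domain families carried by a minority of proteins, a gluzincin motif
#' planted inside every domain instance, surface-targeting features on
#' roughly three quarters of carriers, and a habitat trait enriched among
#' domain-positive taxa at odds ratio 4.
#'
#' @param seed master seed; every substream derives from it
#' @param n_taxa number of taxa
#' @param proteins_per_taxon proteins emitted per taxon
#' @param protein_length length of every protein
#' @param background residue background distribution
#' @param families list of family specs: `family_id`, `domain_length`,
#'   `conservation` (per-column probability of the consensus residue),
#'   `n_carriers`, optional `parent` + `sister_divergence` (per-column
#'   mutation probability applied to the parent consensus)
#' @param motif list: `spacer_range` (H-to-E spacer bounds), `planted_fraction`,
#'   `offset` (0-based motif offset inside the domain)
#' @param surface list: `sp_fraction`, `lipobox_fraction` planted on carriers
#' @param habitat list: `trait`, `baseline_prevalence`, `odds_ratio`
#' @param redundancy list for [curation_fixture()]: `n_base_rows`,
#'   `n_duplicate_rows`, `insert_len`, `insert_occupancy`
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(
    seed = 1L,
    n_taxa = 80L,
    proteins_per_taxon = 3L,
    protein_length = 300L,
    background = uniform_background(),
    families = list(
      list(family_id = "famA", domain_length = 80L, conservation = 0.85,
           n_carriers = 40L),
      list(family_id = "famB", domain_length = 80L, conservation = 0.85,
           n_carriers = 40L, parent = "famA", sister_divergence = 0.35)),
    motif = list(spacer_range = c(8L, 28L), planted_fraction = 1.0,
                 offset = 20L),
    surface = list(sp_fraction = 0.76, lipobox_fraction = 0.10),
    habitat = list(trait = "mucosa", baseline_prevalence = 0.30,
                   odds_ratio = 4),
    redundancy = list(n_base_rows = 8L, n_duplicate_rows = 2L,
                      insert_len = 5L, insert_occupancy = 0.25)) {
  stopifnot(n_taxa >= 1, proteins_per_taxon >= 1, protein_length >= 1,
            abs(sum(background) - 1) < 1e-9,
            habitat$odds_ratio > 0,
            motif$planted_fraction >= 0, motif$planted_fraction <= 1)
  for (f in families) {
    if (f$domain_length > protein_length) {
      stop("family '", f$family_id, "': domain longer than protein")
    }
    stopifnot(f$conservation > 0, f$conservation < 1, f$n_carriers >= 0)
  }
  total <- n_taxa * proteins_per_taxon
  if (sum(vapply(families, function(f) as.numeric(f$n_carriers),
                 numeric(1))) > total) {
    stop("more carriers requested than proteins available")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 proteins_per_taxon = as.integer(proteins_per_taxon),
                 protein_length = as.integer(protein_length),
                 background = background, families = families, motif = motif,
                 surface = surface, habitat = habitat,
                 redundancy = redundancy),
            class = "synthetic_config")
}

# sample a background sequence as a character vector
sample_background <- function(n, background) {
  sample(AA20, n, replace = TRUE, prob = background)
}

# family consensus sequences, honouring parent/sister_divergence links
family_consensus <- function(config) {
  cons <- list()
  for (f in config$families) {
    if (is.null(f$parent)) {
      cons[[f$family_id]] <- sample_background(f$domain_length, config$background)
    } else {
      parent <- cons[[f$parent]]
      if (is.null(parent)) stop("parent family '", f$parent, "' must be listed first")
      mutate <- runif(length(parent)) < f$sister_divergence
      out <- parent
      for (i in which(mutate)) out[i] <- sample(setdiff(AA20, parent[i]), 1L)
      cons[[f$family_id]] <- out
    }
  }
  cons
}

# emit one domain instance from a consensus at a conservation level
emit_instance <- function(consensus, conservation, background) {
  take <- runif(length(consensus)) < conservation
  out <- sample_background(length(consensus), background)
  out[take] <- consensus[take]
  out
}

#' Generate a synthetic proteome with full ground truth
#'
#' @param config a [synthetic_config()]
#' @param out_dir optional directory; when given, writes `proteins.fasta`,
#'   `taxa.tsv`, `truth.tsv`, `predictions.tsv`, per-family instance
#'   alignments, and a `manifest.tsv` recording the seed
#' @return list: `records` (protein data.frame), `truth` (per-protein truth
#'   table), `taxa` (habitat table), `family_alignments` (named list of
#'   [msa] of the true domain instances), `external_predictions`
#'   (synthetic predictor summary consistent with the planted truth),
#'   `config`
#' @export
generate <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  n_prot <- config$n_taxa * config$proteins_per_taxon
  taxon_of <- rep(seq_len(config$n_taxa), each = config$proteins_per_taxon)
  prot_ids <- sprintf("t%03d_p%d", taxon_of,
                      rep(seq_len(config$proteins_per_taxon), config$n_taxa))
  taxon_ids <- sprintf("t%03d", seq_len(config$n_taxa))

  set.seed(derive_seed(config$seed, "consensus"))
  cons <- family_consensus(config)

  # carrier assignment: disjoint protein sets per family
  set.seed(derive_seed(config$seed, "carriers"))
  pool <- seq_len(n_prot)
  carrier_of <- rep(NA_character_, n_prot)
  for (f in config$families) {
    picked <- sample(pool, f$n_carriers)
    carrier_of[picked] <- f$family_id
    pool <- setdiff(pool, picked)
  }

  set.seed(derive_seed(config$seed, "sequences"))
  L <- config$protein_length
  fam_by_id <- setNames(config$families,
                        vapply(config$families, `[[`, "", "family_id"))
  truth <- data.frame(
    protein_id = prot_ids, taxon_id = taxon_ids[taxon_of],
    carrier = !is.na(carrier_of), family_id = carrier_of,
    dom_start = NA_integer_, dom_end = NA_integer_,
    motif_planted = FALSE, motif_start = NA_integer_,
    motif_end = NA_integer_, spacer_len = NA_integer_,
    sp_planted = FALSE, lipobox_planted = FALSE,
    stringsAsFactors = FALSE)
  seqs <- character(n_prot)
  instances <- lapply(fam_by_id, function(f) list())
  for (i in seq_len(n_prot)) {
    chars <- sample_background(L, config$background)
    if (!is.na(carrier_of[i])) {
      f <- fam_by_id[[carrier_of[i]]]
      dl <- f$domain_length
      # keep the N-terminal 40 residues free for surface-feature planting
      lo <- min(40L, L - dl)
      starts <- lo:(L - dl)
      start0 <- starts[sample.int(length(starts), 1L)]
      inst <- emit_instance(cons[[f$family_id]], f$conservation,
                            config$background)
      if (runif(1) < config$motif$planted_fraction) {
        off <- config$motif$offset
        # the planted motif must fit inside the domain instance
        k_max <- min(config$motif$spacer_range[2], dl - off - 6L)
        if (k_max < config$motif$spacer_range[1]) {
          stop("config infeasible: domain of family '", f$family_id,
               "' too short for the motif offset and spacer range")
        }
        ks <- config$motif$spacer_range[1]:k_max
        k <- ks[sample.int(length(ks), 1L)]
        inst[off + 1:5] <- c("H", "E", "A", "A", "H")
        inst[off + 6L + k] <- "E"
        truth$motif_planted[i] <- TRUE
        truth$motif_start[i] <- start0 + off
        truth$motif_end[i] <- start0 + off + 6L + k
        truth$spacer_len[i] <- k
      }
      chars[(start0 + 1L):(start0 + dl)] <- inst
      truth$dom_start[i] <- start0
      truth$dom_end[i] <- start0 + dl
      instances[[f$family_id]][[prot_ids[i]]] <- paste(inst, collapse = "")
      # surface features planted on carriers only
      if (runif(1) < config$surface$sp_fraction) {
        chars[1:14] <- c("M", "K", "R",
                         strsplit("LLIVLLIVLLI", "")[[1]])
        truth$sp_planted[i] <- TRUE
      }
      if (runif(1) < config$surface$lipobox_fraction) {
        chars[15:18] <- c("L", "S", "G", "C")
        truth$lipobox_planted[i] <- TRUE
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  records <- data.frame(id = prot_ids, description = "", residues = seqs,
                        stringsAsFactors = FALSE)
  family_alignments <- lapply(instances, function(x) {
    msa(names(x), unlist(x))
  })

  # taxa: genotype = at least one carrier protein; trait by logistic link
  set.seed(derive_seed(config$seed, "habitat"))
  carrier_count <- as.integer(tapply(truth$carrier, truth$taxon_id, sum))
  genotype <- carrier_count >= 1L
  p_trait <- stats::plogis(stats::qlogis(config$habitat$baseline_prevalence) +
                           log(config$habitat$odds_ratio) * genotype)
  trait <- rbinom(config$n_taxa, 1L, p_trait) == 1L
  taxa <- data.frame(taxon_id = taxon_ids,
                     positive_protein_count = carrier_count,
                     stringsAsFactors = FALSE)
  taxa[[config$habitat$trait]] <- trait

  external_predictions <- data.frame(
    target_id = prot_ids,
    signal_peptide = ifelse(truth$sp_planted, "yes", "no"),
    tmd_count = 0L,
    lipoprotein = ifelse(truth$lipobox_planted, "yes", "no"),
    stringsAsFactors = FALSE)

  out <- list(records = records, truth = truth, taxa = taxa,
              family_alignments = family_alignments,
              external_predictions = external_predictions, config = config)
  if (!is.null(out_dir)) write_synthetic(out, out_dir)
  out
}

write_synthetic <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$records, file.path(out_dir, "proteins.fasta"))
  write.table(sim$taxa, file.path(out_dir, "taxa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$external_predictions, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (fam in names(sim$family_alignments)) {
    write_alignment(sim$family_alignments[[fam]],
                    file.path(out_dir, paste0(fam, "_instances.fasta")))
  }
  manifest <- data.frame(key = c("seed", "n_taxa", "proteins_per_taxon",
                                 "protein_length"),
                         value = c(sim$config$seed, sim$config$n_taxa,
                                   sim$config$proteins_per_taxon,
                                   sim$config$protein_length))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Simulate a taxa-by-habitat table with a configured odds ratio
#'
#' Lightweight generator for calibration studies of the association test:
#' genotype flags are Bernoulli(`genotype_fraction`), the trait is drawn
#' through a logistic link so that the genotype-trait log-odds equals
#' `log(odds_ratio)`.
#'
#' @param n_taxa number of taxa
#' @param genotype_fraction expected fraction of genotype-positive taxa
#' @param baseline_prevalence trait prevalence among genotype-negative taxa
#' @param odds_ratio genotype-trait odds ratio (1 = no association)
#' @param trait trait column name
#' @param seed integer seed
#' @return habitat data.frame usable by [build_contingency()]
#' @export
simulate_habitat <- function(n_taxa = 450L, genotype_fraction = 0.12,
                             baseline_prevalence = 0.30, odds_ratio = 4,
                             trait = "mucosa", seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "simulate_habitat"))
  genotype <- runif(n_taxa) < genotype_fraction
  p_trait <- stats::plogis(stats::qlogis(baseline_prevalence) +
                           log(odds_ratio) * genotype)
  out <- data.frame(taxon_id = sprintf("t%05d", seq_len(n_taxa)),
                    positive_protein_count = as.integer(genotype),
                    stringsAsFactors = FALSE)
  out[[trait]] <- runif(n_taxa) < p_trait
  out
}

#' Build an alignment fixture with planted duplicates and insert blocks
#'
#' Emits a gapless family alignment, appends exact duplicate rows of the
#' first row, and splices in a low-occupancy insert block, recording what a
#' correct curation must remove.
#'
#' @param config a [synthetic_config()]; uses its `redundancy` spec
#' @return list: `aln` (the fixture [msa]), `expected_rows`,
#'   `expected_cols` after curation, `duplicate_ids`, `insert_block`
#'   (0-based half-open column interval), `base_cols`
#' @export
curation_fixture <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "curation_fixture"))
  rs <- config$redundancy
  f <- config$families[[1]]
  # lower conservation keeps base rows safely below the identity threshold
  consensus <- sample_background(f$domain_length, config$background)
  rows <- vapply(seq_len(rs$n_base_rows), function(i) {
    paste(emit_instance(consensus, 0.75, config$background), collapse = "")
  }, character(1))
  ids <- sprintf("base%02d", seq_len(rs$n_base_rows))
  dup_ids <- character()
  if (rs$n_duplicate_rows > 0L) {
    dup_ids <- sprintf("dup%02d", seq_len(rs$n_duplicate_rows))
    rows <- c(rows, rep(rows[1], rs$n_duplicate_rows))
    ids <- c(ids, dup_ids)
  }
  n_rows <- length(rows)
  # splice a poly-W insert block carried by a low-occupancy row subset
  n_carry <- max(1L, round(rs$insert_occupancy * n_rows))
  pos <- f$domain_length %/% 2L
  block <- paste(rep("W", rs$insert_len), collapse = "")
  gapblk <- paste(rep("-", rs$insert_len), collapse = "")
  carry <- seq_len(n_carry)   # the first rows carry the insert
  rows <- vapply(seq_len(n_rows), function(i) {
    paste0(substr(rows[i], 1, pos),
           if (i %in% carry) block else gapblk,
           substr(rows[i], pos + 1L, f$domain_length))
  }, character(1))
  list(aln = msa(ids, rows),
       expected_rows = rs$n_base_rows,
       expected_cols = f$domain_length,
       duplicate_ids = dup_ids,
       insert_block = c(pos, pos + rs$insert_len),
       base_cols = f$domain_length)
}
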