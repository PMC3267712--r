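# End-to-end driver: simulate (or accept) a proteome, curate the seed
# alignment, build and calibrate two sister profiles, search, partition by
# bit-score difference, scan motifs, assemble architectures, and test the
# habitat association. Every stage writes a TSV plus a manifest entry.

#' Run the full discovery pipeline on a synthetic proteome
#'
#' Stages, in order: simulate, curate, build profiles (A and B), scan
#' (search both calibrated profiles), partition, motif, annotate,
#' associate. Each stage appends a manifest row with its output file and
#' md5 hash; any failure aborts with the stage named.
#'
#' @param config a [synthetic_config()]; its seed drives every stage
#' @param out_dir output directory for stage TSVs (created if needed)
#' @param e_cutoff search significance cutoff (default 1e-5)
#' @param n_decoys decoys per profile calibration
#' @param curation a [curation_params()] for the seed-alignment stage
#' @return list: `manifest` (data.frame), `sim`, `curated`, `profiles`,
#'   `hits` (named list A/B), `partition`, `motifs`, `architectures`,
#'   `association`
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = tempfile("run"),
                         e_cutoff = 1e-5, n_decoys = 200L,
                         curation = curation_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), output = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, output = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    s <- generate(config, out_dir = file.path(out_dir, "simulated"))
    emit("simulate", file.path(out_dir, "simulated", "proteins.fasta"))
    s
  })

  curated <- stage("curate", {
    cu <- curate(sim$family_alignments[[1]], curation)
    f <- file.path(out_dir, "seed_curated.fasta")
    write_alignment(cu$aln, f)
    emit("curate", f)
    cu
  })

  profiles <- stage("build-profile", {
    fam_ids <- names(sim$family_alignments)[1:2]
    pa <- build_profile(curated$aln, profile_id = fam_ids[1])
    pb <- build_profile(sim$family_alignments[[2]], profile_id = fam_ids[2])
    fa <- file.path(out_dir, "profile_A.tsv"); write_profile(pa, fa)
    fb <- file.path(out_dir, "profile_B.tsv"); write_profile(pb, fb)
    emit("build-profile", fa); emit("build-profile", fb)
    list(A = pa, B = pb)
  })

  hits <- stage("scan", {
    lens <- nchar(sim$records$residues)
    fit_a <- calibrate(profiles$A, lens, n_decoys = n_decoys,
                       seed = derive_seed(config$seed, "calA"))
    fit_b <- calibrate(profiles$B, lens, n_decoys = n_decoys,
                       seed = derive_seed(config$seed, "calB"))
    ha <- search_profile(profiles$A, sim$records, fit_a, e_cutoff = e_cutoff)
    hb <- search_profile(profiles$B, sim$records, fit_b, e_cutoff = e_cutoff)
    fa <- file.path(out_dir, "hits_A.tsv"); write_hit_table(ha, fa)
    fb <- file.path(out_dir, "hits_B.tsv"); write_hit_table(hb, fb)
    emit("scan", fa); emit("scan", fb)
    list(A = ha, B = hb)
  })

  part <- stage("partition", {
    p <- partition_by_score_difference(hits$A, hits$B)
    f <- file.path(out_dir, "partition.tsv")
    write.table(p$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("partition", f)
    p
  })

  motifs <- stage("motif", {
    status <- vapply(seq_len(nrow(sim$records)), function(i) {
      classify_motif_status(sim$records[i, , drop = FALSE])
    }, character(1))
    tab <- data.frame(target_id = sim$records$id, motif_status = status,
                      stringsAsFactors = FALSE)
    f <- file.path(out_dir, "motifs.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("motif", f)
    tab
  })

  arch <- stage("annotate", {
    all_hits <- rbind(
      data.frame(target_id = hits$A$target_id, domain_id = profiles$A$profile_id,
                 start = hits$A$start, end = hits$A$end,
                 bit_score = hits$A$bit_score, stringsAsFactors = FALSE),
      data.frame(target_id = hits$B$target_id, domain_id = profiles$B$profile_id,
                 start = hits$B$start, end = hits$B$end,
                 bit_score = hits$B$bit_score, stringsAsFactors = FALSE))
    archs <- lapply(sim$records$id, function(id) {
      h <- all_hits[all_hits$target_id == id, , drop = FALSE]
      rec <- sim$records[sim$records$id == id, , drop = FALSE]
      assemble_architecture(
        h, seq_length = nchar(rec$residues),
        motif_status = motifs$motif_status[motifs$target_id == id],
        surface = flag_surface(rec, sim$external_predictions))
    })
    f <- file.path(out_dir, "architectures.tsv")
    write.table(architecture_table(archs), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit("annotate", f)
    archs
  })

  assoc <- stage("associate", {
    # genotype: taxa with >= 1 protein assigned to subfamily A
    pos <- part$table$target_id[part$table$assignment == "A"]
    taxon <- sub("_p\\d+$", "", pos)
    taxa <- sim$taxa
    taxa$positive_protein_count <- as.integer(
      table(factor(taxon, levels = taxa$taxon_id)))
    counts <- build_contingency(taxa, config$habitat$trait)
    r <- hypergeom_test(counts)
    tab <- data.frame(trait = config$habitat$trait, N = counts$N, M = counts$M,
                      n = counts$n, m = counts$m, mu = r$mu,
                      direction = r$direction, p_value = r$p_value,
                      stringsAsFactors = FALSE)
    f <- file.path(out_dir, "association.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("associate", f)
    r
  })

  list(manifest = manifest, sim = sim, curated = curated, profiles = profiles,
       hits = hits, partition = part, motifs = motifs, architectures = arch,
       association = assoc)
}

#' Read a pipeline configuration from a YAML file
#'
#' Convenience wrapper turning a YAML document of [synthetic_config()]
#' arguments into a config object; unknown keys are rejected.
#'
#' @param path YAML file
#' @return a `synthetic_config`
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  args <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config key '", bad[1], "'")
  do.call(synthetic_config, args)
}
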