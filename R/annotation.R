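# Per-protein domain architectures from hit intervals, domain co-occurrence
# tables, combination queries, and extracellular-targeting feature flags.

# Kyte-Doolittle hydropathy, used by the heuristic surface-feature stand-in
KD_SCALE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)

#' Assemble a non-conflicting domain architecture for one protein
#'
#' Hits are admitted greedily by descending bit score; a hit is kept when
#' its overlap with every already-retained hit is at most
#' `overlap_tolerance` as a fraction of the shorter of the two intervals.
#' Retained hits are ordered by start. The result is invariant to the input
#' row order (ties in score are broken by start, then domain id).
#'
#' @param hits data.frame with `target_id`, `domain_id`, `start`, `end`
#'   (0-based half-open), `bit_score`, optional `source`
#' @param overlap_tolerance overlap fraction tolerated (default 0.25)
#' @param seq_length optional protein length for bounds checking
#' @param motif_status optional motif status string to attach
#' @param surface optional `surface_features` to attach
#' @return object of class `protein_architecture`
#' @export
assemble_architecture <- function(hits, overlap_tolerance = 0.25,
                                  seq_length = NULL, motif_status = NA_character_,
                                  surface = NULL) {
  stopifnot(length(unique(hits$target_id)) <= 1L)
  if (!is.null(seq_length) && nrow(hits) > 0L &&
      any(hits$end > seq_length | hits$start < 0)) {
    stop("hit interval outside sequence bounds for target '",
         hits$target_id[1], "'")
  }
  if (is.null(hits$source)) hits$source <- rep("internal_scan", nrow(hits))
  ord <- order(-hits$bit_score, hits$start, hits$domain_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- integer()
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in keep) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov > overlap_tolerance * shorter) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  retained <- hits[keep, , drop = FALSE]
  retained <- retained[order(retained$start), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(target_id = if (nrow(hits)) hits$target_id[1] else NA_character_,
                 hits = retained, motif_status = motif_status,
                 surface = surface),
            class = "protein_architecture")
}

#' @export
print.protein_architecture <- function(x, ...) {
  doms <- if (nrow(x$hits)) {
    paste(sprintf("%s[%d-%d]", x$hits$domain_id, x$hits$start + 1L, x$hits$end),
          collapse = " + ")
  } else "(no domains)"
  cat(x$target_id, ": ", doms, "\n", sep = "")
  if (!is.na(x$motif_status)) cat("  motif: ", x$motif_status, "\n", sep = "")
  invisible(x)
}

#' Domain co-occurrence table for proteins containing a focal domain
#'
#' Over the proteins whose architecture contains `focal_domain`, counts for
#' every other domain the total number of instances and the number of
#' distinct proteins with at least one instance; sorted by protein count
#' (descending), ties by domain id.
#'
#' @param architectures list of `protein_architecture`
#' @param focal_domain domain id defining the protein subset
#' @return data.frame: `domain_id`, `n_domains`, `n_proteins`
#' @export
cooccurrence_table <- function(architectures, focal_domain) {
  has_focal <- vapply(architectures, function(a) {
    focal_domain %in% a$hits$domain_id
  }, logical(1))
  rows <- lapply(architectures[has_focal], function(a) {
    d <- a$hits$domain_id[a$hits$domain_id != focal_domain]
    if (length(d) == 0L) return(NULL)
    data.frame(domain_id = names(table(d)),
               n_domains = as.integer(table(d)), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(domain_id = character(), n_domains = integer(),
                      n_proteins = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(cbind(n_domains = rows$n_domains,
                         n_proteins = rep(1L, nrow(rows))) ~ domain_id,
                   data = rows, FUN = sum)
  agg <- agg[order(-agg$n_proteins, agg$domain_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Query proteins by required and forbidden domain combinations
#'
#' @param architectures list of `protein_architecture`
#' @param required domain ids that must all be present
#' @param forbidden domain ids none of which may be present
#' @param vocabulary declared domain vocabulary; defaults to every domain id
#'   seen in `architectures`
#' @return sorted character vector of protein ids
#' @export
combination_query <- function(architectures, required = character(),
                              forbidden = character(), vocabulary = NULL) {
  seen <- unique(unlist(lapply(architectures, function(a) a$hits$domain_id)))
  vocabulary <- vocabulary %||% seen
  unknown <- setdiff(c(required, forbidden), vocabulary)
  if (length(unknown)) stop("unknown domain id: '", unknown[1], "'")
  hit <- vapply(architectures, function(a) {
    doms <- a$hits$domain_id
    all(required %in% doms) && !any(forbidden %in% doms)
  }, logical(1))
  sort(vapply(architectures[hit], `[[`, "", "target_id"))
}

#' Surface-feature flags for one protein
#'
#' External predictor values (from SignalP/TMHMM/Phobius-class tools,
#' supplied as a table) take precedence. Absent those, a clearly-labelled
#' heuristic stand-in is used: an N-terminal signal peptide calls for a
#' hydrophobic window (>= 8 residues, mean Kyte-Doolittle hydropathy above
#' `hydro_threshold`) within residues 1-40 preceded by a basic residue in
#' positions 1-5; a lipoprotein calls for a lipobox-like `[LVI][ASTVG][GAS]C`
#' whose cysteine lies within residues 12-40; transmembrane segments are
#' counted as non-overlapping >= 18-residue hydrophobic windows after
#' residue 40.
#'
#' @param record one-row data.frame (`id`, `residues`) or named string
#' @param external_predictions optional data.frame keyed by `target_id`
#'   with columns `signal_peptide` (yes/no/unknown), `tmd_count` (integer or
#'   NA), `lipoprotein` (yes/no/unknown)
#' @param hydro_threshold mean-hydropathy cutoff for hydrophobic windows
#' @return object of class `surface_features`: `signal_peptide`,
#'   `tmd_count`, `lipoprotein`, `extracellular_candidate`, `provenance`
#' @export
flag_surface <- function(record, external_predictions = NULL,
                         hydro_threshold = 1.6) {
  if (is.character(record)) {
    record <- data.frame(id = names(record) %||% "seq",
                         residues = unname(record), stringsAsFactors = FALSE)
  }
  ext <- NULL
  if (!is.null(external_predictions)) {
    ext <- external_predictions[external_predictions$target_id == record$id, ,
                                drop = FALSE]
    if (nrow(ext) == 0L) ext <- NULL
  }
  chars <- strsplit(toupper(record$residues), "")[[1]]
  kd <- unname(KD_SCALE[chars])
  kd[is.na(kd)] <- 0
  n <- length(chars)
  win_mean <- function(w) {
    if (n < w) return(numeric())
    cs <- c(0, cumsum(kd))
    (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  }
  # heuristic signal peptide
  m8 <- win_mean(8L)
  sp_windows <- which(m8 > hydro_threshold)
  sp_windows <- sp_windows[sp_windows + 7L <= 40L]
  basic_pos <- which(chars[seq_len(min(5L, n))] %in% c("K", "R"))
  heur_sp <- if (length(basic_pos) > 0L &&
                 any(sp_windows > basic_pos[1])) "yes" else "no"
  # heuristic lipobox
  lipo_hits <- gregexpr("[LVI][ASTVG][GAS]C", paste(chars, collapse = ""))[[1]]
  heur_lp <- "no"
  if (lipo_hits[1] != -1L) {
    cys_pos <- lipo_hits + 3L
    if (any(cys_pos >= 12L & cys_pos <= 40L)) heur_lp <- "yes"
  }
  # heuristic TMD count: non-overlapping 18-residue hydrophobic windows
  m18 <- win_mean(18L)
  tm_starts <- which(m18 > hydro_threshold)
  tm_starts <- tm_starts[tm_starts > 40L]
  heur_tmd <- 0L
  last_end <- -1L
  for (s in tm_starts) {
    if (s > last_end) { heur_tmd <- heur_tmd + 1L; last_end <- s + 17L }
  }
  pick <- function(ext_val, heur_val) {
    if (!is.null(ext) && !is.na(ext_val) && ext_val != "unknown") {
      list(v = ext_val, from = "external")
    } else list(v = heur_val, from = "heuristic")
  }
  sp <- pick(if (!is.null(ext)) as.character(ext$signal_peptide) else NA, heur_sp)
  lp <- pick(if (!is.null(ext)) as.character(ext$lipoprotein) else NA, heur_lp)
  tmd <- if (!is.null(ext) && !is.na(ext$tmd_count)) {
    list(v = as.integer(ext$tmd_count), from = "external")
  } else list(v = heur_tmd, from = "heuristic")
  extracellular <- identical(sp$v, "yes") || (is.finite(tmd$v) && tmd$v >= 1L) ||
    identical(lp$v, "yes")
  structure(list(signal_peptide = sp$v, tmd_count = tmd$v, lipoprotein = lp$v,
                 extracellular_candidate = extracellular,
                 provenance = c(signal_peptide = sp$from, tmd_count = tmd$from,
                                lipoprotein = lp$from)),
            class = "surface_features")
}

#' Fraction of proteins flagged as extracellular candidates
#'
#' Unknown surface calls count in the denominator and never satisfy the
#' extracellular disjunction (conservative counting).
#'
#' @param architectures list of `protein_architecture` carrying `surface`
#' @param subset optional character vector of target ids restricting the set
#' @return fraction in \[0, 1\]
#' @export
surface_fraction <- function(architectures, subset = NULL) {
  ids <- vapply(architectures, `[[`, "", "target_id")
  if (!is.null(subset)) architectures <- architectures[ids %in% subset]
  if (length(architectures) == 0L) stop("empty protein subset")
  flags <- vapply(architectures, function(a) {
    isTRUE(a$surface$extracellular_candidate)
  }, logical(1))
  mean(flags)
}

#' Flat table view of a list of architectures
#' @param architectures list of `protein_architecture`
#' @return data.frame, one row per protein
#' @export
architecture_table <- function(architectures) {
  do.call(rbind, lapply(architectures, function(a) {
    data.frame(
      target_id = a$target_id,
      architecture = if (nrow(a$hits)) {
        paste(sprintf("%s[%d-%d]", a$hits$domain_id, a$hits$start + 1L,
                      a$hits$end), collapse = "+")
      } else "",
      motif_status = a$motif_status,
      signal_peptide = a$surface$signal_peptide %||% NA_character_,
      tmd_count = a$surface$tmd_count %||% NA_integer_,
      lipoprotein = a$surface$lipoprotein %||% NA_character_,
      extracellular_candidate = isTRUE(a$surface$extracellular_candidate),
      stringsAsFactors = FALSE)
  }))
}
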