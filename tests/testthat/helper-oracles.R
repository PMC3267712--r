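# Independent oracles used by the property tests. Each re-derives the
# expected quantity by a different route than the implementation under test
# (exhaustive enumeration, closed forms, regex automata, stats:: built-ins).

AA20 <- m60miner:::AA20

# --- exhaustive global alignment score (affine gaps, free enumeration) -----
# enumerates every global alignment of a and b column by column, scoring
# substitutions with BLOSUM62 and gap runs with -(open + (len-1) * extend).
oracle_global_score <- function(a, b, open = 11, extend = 1) {
  B <- m60miner:::get_blosum62()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, score + B[ca[i], cb[j]], "M")
    }
    if (i <= length(ca)) {
      rec(i + 1L, j, score - if (state == "X") extend else open, "X")
    }
    if (j <= length(cb)) {
      rec(i, j + 1L, score - if (state == "Y") extend else open, "Y")
    }
  }
  rec(1L, 1L, 0, "M")
  best
}

# --- exhaustive local profile-to-sequence score ----------------------------
# best local path through the match states: consecutive matched cells are
# connected either by a pure insert run (same next state, k skipped
# residues) or a pure delete run (skipped states, next residue), with
# affine costs; paths start and end on matched cells. Independent of the
# row-sweep DP in score_sequence.
oracle_local_score <- function(profile, seq_chars) {
  E <- m60miner:::emission_logodds(profile, seq_chars)
  K <- nrow(E); L <- length(seq_chars)
  go <- profile$gap_open; ge <- profile$gap_extend
  best <- 0
  val <- matrix(NA_real_, K, L)   # best score of a path ending at (i, j)
  for (j in seq_len(L)) {
    for (i in seq_len(K)) {
      v <- E[i, j]   # start fresh at (i, j)
      if (i > 1L && j > 1L) {
        v <- max(v, E[i, j] + val[i - 1L, j - 1L])                 # diagonal
        ip <- i - 1L
        for (jp in seq_len(j - 2L)) {                              # inserts
          k <- j - jp - 1L
          v <- max(v, E[i, j] + val[ip, jp] - go - (k - 1L) * ge)
        }
        jp <- j - 1L
        for (ip2 in seq_len(i - 2L)) {                             # deletes
          d <- i - ip2 - 1L
          v <- max(v, E[i, j] + val[ip2, jp] - go - (d - 1L) * ge)
        }
      }
      val[i, j] <- v
      best <- max(best, v)
    }
  }
  max(best, 0)
}

# --- regex-automaton motif oracle ------------------------------------------
# expands a zincin/gluzincin-style pattern into one fixed regex per spacer
# length and collects all overlapping matches via a lookahead. Wildcards
# admit ambiguity letters; literals do not.
oracle_motif_intervals <- function(seq_string, spacer = NULL) {
  wild <- paste0("[", paste(c(AA20, m60miner:::AA_AMBIG), collapse = ""), "]")
  pats <- if (is.null(spacer)) {
    sprintf("HE%s{2}H", wild)
  } else {
    sprintf("HE%s{2}H%s{%d}E", wild, wild, spacer[1]:spacer[2])
  }
  lens <- if (is.null(spacer)) 5L else 6L + spacer[1]:spacer[2]
  out <- NULL
  for (k in seq_along(pats)) {
    m <- gregexpr(paste0("(?=(", pats[k], "))"), seq_string, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    out <- rbind(out, cbind(start = as.integer(m) - 1L,
                            end = as.integer(m) - 1L + lens[k]))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- unique(as.data.frame(out))
  out[order(out$start, out$end), , drop = FALSE]
}

# --- plain-arithmetic hypergeometric upper tail ----------------------------
oracle_hyper_tail <- function(N, M, n, m) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# random ungapped peptide helper
random_peptide <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
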