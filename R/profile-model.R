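# Log-odds profile construction from a curated alignment, local dynamic-
# programming scoring in bits, Gumbel E-value calibration against shuffled
# decoys, database search, and the bit-score-difference subfamily partition.

#' Build a log-odds profile from a curated alignment
#'
#' Match states are the alignment columns with residue occupancy >= 0.5
#' (ties included). Emissions use background-proportional pseudocounts:
#' `(count_a + w * bg_a * 20) / (n_residues + w * 20)` with weight `w`.
#'
#' @param aln an [msa]
#' @param profile_id identifier stored with the profile
#' @param pseudocount_weight positive pseudocount weight (default 1)
#' @param background residue background distribution (default uniform)
#' @param gap_open,gap_extend affine insert/delete penalties in bits
#'   (defaults 4 and 1)
#' @return object of class `profile_model`
#' @export
build_profile <- function(aln, profile_id = "profile",
                          pseudocount_weight = 1,
                          background = uniform_background(),
                          gap_open = 4, gap_extend = 1) {
  stopifnot(pseudocount_weight > 0, abs(sum(background) - 1) < 1e-9)
  background <- background[AA20]
  m <- msa_matrix(aln)
  occ <- colMeans(m != "-")
  match_cols <- which(occ >= 0.5)
  if (length(match_cols) == 0L) {
    stop("no column reaches the 0.5 occupancy threshold; cannot build profile")
  }
  emissions <- matrix(0, length(match_cols), 20,
                      dimnames = list(NULL, AA20))
  for (k in seq_along(match_cols)) {
    col <- m[, match_cols[k]]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    n_res <- sum(counts)
    emissions[k, ] <- (as.numeric(counts) + pseudocount_weight * background * 20) /
      (n_res + pseudocount_weight * 20)
  }
  structure(list(
    profile_id = profile_id,
    match_columns = match_cols - 1L,       # 0-based original column indices
    emissions = emissions,
    background = background,
    gap_open = gap_open,
    gap_extend = gap_extend,
    provenance = list(n_rows = nrow(m), n_columns = ncol(m),
                      pseudocount_weight = pseudocount_weight,
                      match_rule = "occupancy >= 0.5")),
    class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model '", x$profile_id, "': ", nrow(x$emissions),
      " match states (from ", x$provenance$n_rows, " x ",
      x$provenance$n_columns, " alignment)\n", sep = "")
  cat("gap open ", x$gap_open, " bits, extend ", x$gap_extend, " bits\n", sep = "")
  invisible(x)
}

#' Number of match states of a profile
#' @param profile a `profile_model`
#' @return integer
#' @export
profile_length <- function(profile) nrow(profile$emissions)

# log2 odds emission matrix: K states x length(seq); ambiguity letters and
# any non-standard symbol score 0 (background)
emission_logodds <- function(profile, chars) {
  K <- nrow(profile$emissions)
  L <- length(chars)
  lo <- log2(sweep(profile$emissions, 2, profile$background, "/"))
  E <- matrix(0, K, L)
  std <- chars %in% AA20
  if (any(std)) E[, std] <- lo[, chars[std], drop = FALSE]
  E
}

#' Score one sequence against a profile
#'
#' Best local alignment of the profile's match/insert/delete state path to
#' the sequence by dynamic programming over log-odds emissions (bits) with
#' affine transition penalties. Insert-emitted residues score as background
#' (log-odds 0). Ambiguity letters score as background in match states.
#'
#' @param profile a `profile_model`
#' @param record one-row data.frame with `id` and `residues`, or a single
#'   named string
#' @return one-row data.frame: `target_id`, `profile_id`, `bit_score`,
#'   `e_value` (NA until calibrated), `start`, `end` (0-based half-open
#'   envelope; NA when the best score is <= 0)
#' @export
score_sequence <- function(profile, record) {
  if (is.character(record)) {
    record <- data.frame(id = names(record) %||% "seq",
                         residues = unname(record), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(record) == 1L, nchar(record$residues) >= 1L)
  chars <- strsplit(toupper(record$residues), "")[[1]]
  L <- length(chars)
  K <- nrow(profile$emissions)
  E <- emission_logodds(profile, chars)
  go <- profile$gap_open; ge <- profile$gap_extend
  NEG <- -1e9
  jx <- seq_len(L)
  prevM <- rep(NEG, L); prevI <- rep(NEG, L); prevD <- rep(NEG, L)
  prevSM <- prevSI <- prevSD <- rep(NA_integer_, L)
  best <- 0; best_end <- NA_integer_; best_start <- NA_integer_
  for (i in seq_len(K)) {
    # match: enter fresh (0) or extend from row i-1 diagonally
    dM <- c(NEG, prevM[-L]); dI <- c(NEG, prevI[-L]); dD <- c(NEG, prevD[-L])
    dSM <- c(NA, prevSM[-L]); dSI <- c(NA, prevSI[-L]); dSD <- c(NA, prevSD[-L])
    base <- pmax(0, dM, dI, dD)
    M <- E[i, ] + base
    SM <- ifelse(base == 0, jx,
                 ifelse(base == dM, dSM, ifelse(base == dI, dSI, dSD)))
    # delete of state i: from row i-1 at same j (no residue consumed)
    D <- pmax(prevM - go, prevD - ge)
    SD <- ifelse(prevM - go >= prevD - ge, prevSM, prevSD)
    # insert after state i: running max over this row's M
    if (L > 1L) {
      # I[j] = max_{j' <= j-1} (M[j'] - go - (j-1-j') * ge), via a running max
      A <- M + jx * ge
      runmax <- cummax(A)
      runidx <- cummax(ifelse(A >= runmax, jx, 0L))
      I <- rep(NEG, L)
      I[-1L] <- runmax[-L] - go - (jx[-1L] - 1L) * ge
      SI <- c(NA_integer_, SM[runidx[-L]])
    } else {
      I <- NEG; SI <- NA_integer_
    }
    mrow <- max(M)
    if (mrow > best) {
      j <- which.max(M)
      best <- mrow; best_end <- j; best_start <- SM[j]
    }
    prevM <- M; prevI <- I; prevD <- D
    prevSM <- SM; prevSI <- SI; prevSD <- SD
  }
  if (best <= 0) {
    start0 <- NA_integer_; end0 <- NA_integer_; best <- max(best, 0)
  } else {
    start0 <- best_start - 1L; end0 <- best_end
  }
  data.frame(target_id = record$id, profile_id = profile$profile_id,
             bit_score = best, e_value = NA_real_,
             start = start0, end = end0, stringsAsFactors = FALSE)
}

#' Calibrate a profile's score distribution on random decoys
#'
#' Draws `n_decoys` sequences residue-wise from the profile background at
#' lengths sampled from `length_distribution`, scores each, and fits a
#' Gumbel (extreme-value) law to the best-hit bit scores by maximum
#' likelihood.
#'
#' @param profile a `profile_model`
#' @param length_distribution integer vector of decoy lengths to sample from
#' @param n_decoys number of decoys (>= 50)
#' @param seed integer seed controlling all randomness here
#' @return object of class `calibration_fit`: `location`, `scale`,
#'   `n_decoys`, `seed`
#' @export
calibrate <- function(profile, length_distribution, n_decoys = 200L, seed = 1L) {
  stopifnot(n_decoys >= 50L, all(length_distribution >= 1L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "calibrate"))
  lens <- length_distribution[sample.int(length(length_distribution),
                                         n_decoys, replace = TRUE)]
  scores <- vapply(seq_len(n_decoys), function(d) {
    s <- paste(sample(AA20, lens[d], replace = TRUE, prob = profile$background),
               collapse = "")
    score_sequence(profile, setNames(s, paste0("decoy", d)))$bit_score
  }, numeric(1))
  if (sd(scores) < 1e-12) stop("degenerate calibration: decoy scores have zero variance")
  fit <- fit_gumbel(scores)
  structure(list(location = fit[["location"]], scale = fit[["scale"]],
                 n_decoys = n_decoys, seed = seed), class = "calibration_fit")
}

# Gumbel maximum-likelihood fit; moment estimates as a starting point
fit_gumbel <- function(x) {
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  opt <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  c(location = opt$par[1], scale = exp(opt$par[2]))
}

#' E-value of a bit score under a calibration fit
#'
#' `database_size` times the Gumbel upper-tail probability at `bit_score`;
#' strictly decreasing in the score.
#'
#' @param fit a `calibration_fit`
#' @param bit_score bit score(s)
#' @param database_size number of database sequences
#' @return numeric E-value(s)
#' @export
e_value <- function(fit, bit_score, database_size = 1) {
  stopifnot(database_size >= 1)
  z <- (bit_score - fit$location) / fit$scale
  database_size * (-expm1(-exp(-z)))
}

#' Search a sequence collection with a calibrated profile
#'
#' @param profile a `profile_model`
#' @param records data.frame with `id`, `residues`
#' @param fit a `calibration_fit` for this profile
#' @param e_cutoff report hits with E-value <= this (default 1e-5)
#' @param database_size effective database size (default `nrow(records)`)
#' @return hit data.frame sorted by ascending E-value (ties by target id)
#' @export
search_profile <- function(profile, records, fit, e_cutoff = 1e-5,
                           database_size = nrow(records)) {
  hits <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    score_sequence(profile, records[i, , drop = FALSE])
  }))
  hits$e_value <- e_value(fit, hits$bit_score, database_size)
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  hits[order(hits$e_value, hits$target_id), , drop = FALSE]
}

#' Partition targets by the difference of two profiles' bit scores
#'
#' The universe is every target hit by either profile; a missing score
#' contributes 0 to the difference `delta = score_A - score_B`. Assignment
#' is by the sign of `delta`; exact zeros are reported as ties, never
#' silently assigned.
#'
#' @param hits_A,hits_B hit data.frames (one row per target)
#' @return list of class `partition_result`: `table` (target_id, score_A,
#'   score_B, delta, assignment) and `counts` (named A/B/tie)
#' @export
partition_by_score_difference <- function(hits_A, hits_B) {
  if (anyDuplicated(hits_A$target_id)) {
    stop("duplicate target in hits_A: '",
         hits_A$target_id[duplicated(hits_A$target_id)][1],
         "' (take the per-target best upstream)")
  }
  if (anyDuplicated(hits_B$target_id)) {
    stop("duplicate target in hits_B: '",
         hits_B$target_id[duplicated(hits_B$target_id)][1], "'")
  }
  universe <- sort(union(hits_A$target_id, hits_B$target_id))
  sa <- setNames(hits_A$bit_score, hits_A$target_id)[universe]
  sb <- setNames(hits_B$bit_score, hits_B$target_id)[universe]
  sa[is.na(sa)] <- 0; sb[is.na(sb)] <- 0
  delta <- sa - sb
  assignment <- ifelse(delta > 0, "A", ifelse(delta < 0, "B", "tie"))
  tab <- data.frame(target_id = universe, score_A = unname(sa),
                    score_B = unname(sb), delta = unname(delta),
                    assignment = unname(assignment), stringsAsFactors = FALSE)
  counts <- c(A = sum(assignment == "A"), B = sum(assignment == "B"),
              tie = sum(assignment == "tie"))
  structure(list(table = tab, counts = counts), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("score-difference partition over", nrow(x$table), "targets:\n")
  print(x$counts)
  invisible(x)
}

# --- profile TSV serialisation ---------------------------------------------

#' Write a profile to a documented TSV
#' @param profile a `profile_model`
#' @param path output path
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# profile_id\t", profile$profile_id),
    paste0("# gap_open\t", profile$gap_open),
    paste0("# gap_extend\t", profile$gap_extend),
    paste0("# match_columns\t", paste(profile$match_columns, collapse = ",")),
    paste0("# background\t", paste(signif(profile$background, 10), collapse = ",")),
    paste(c("state", AA20), collapse = "\t")), con)
  for (k in seq_len(nrow(profile$emissions))) {
    writeLines(paste(c(k, signif(profile$emissions[k, ], 10)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path input path
#' @return a `profile_model`
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "\t"))
  meta <- setNames(kv[, 2], kv[, 1])
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body[1], "\t")[[1]]
  rows <- do.call(rbind, strsplit(body[-1], "\t"))
  em <- matrix(as.numeric(rows[, -1, drop = FALSE]), nrow = nrow(rows),
               dimnames = list(NULL, cols[-1]))
  structure(list(
    profile_id = unname(meta["profile_id"]),
    match_columns = as.integer(strsplit(meta["match_columns"], ",")[[1]]),
    emissions = em[, AA20, drop = FALSE],
    background = setNames(as.numeric(strsplit(meta["background"], ",")[[1]]), AA20),
    gap_open = as.numeric(meta["gap_open"]),
    gap_extend = as.numeric(meta["gap_extend"]),
    provenance = list(source = path)), class = "profile_model")
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
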