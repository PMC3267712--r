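# Iterative alignment curation: segment extraction, redundancy removal,
# progressive re-alignment, rare-long-indel stripping, and the loop that
# applies them to convergence. Produces the seed alignment for profiles.

#' Curation parameters
#'
#' @param segment optional 0-based half-open column interval `c(from, to)`
#'   extracted once before iterating; `NULL` keeps all columns
#' @param identity_threshold pairwise identity at or above which the shorter
#'   sequence of a pair is considered redundant (default 0.80)
#' @param max_indel_len maximal tolerated run length of insert-like columns
#'   (default 2); longer runs are deleted entire
#' @param indel_occupancy residue-occupancy fraction strictly below which a
#'   column counts as insert-like (default 0.50)
#' @param max_iterations cap on curation iterations (default 20)
#' @param gap_open,gap_extend affine gap costs of the internal aligner
#' @return list of class `curation_params`
#' @export
curation_params <- function(segment = NULL, identity_threshold = 0.80,
                            max_indel_len = 2L, indel_occupancy = 0.50,
                            max_iterations = 20L,
                            gap_open = 11, gap_extend = 1) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            max_indel_len >= 0, indel_occupancy >= 0, indel_occupancy <= 1,
            max_iterations >= 1)
  structure(list(segment = segment, identity_threshold = identity_threshold,
                 max_indel_len = as.integer(max_indel_len),
                 indel_occupancy = indel_occupancy,
                 max_iterations = as.integer(max_iterations),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "curation_params")
}

#' Extract a column interval from an alignment
#'
#' Rows that become all-gap inside the interval are dropped (and returned in
#' the `dropped` attribute).
#'
#' @param aln an [msa]
#' @param interval 0-based half-open column interval `c(from, to)`
#' @return an [msa] restricted to the interval
#' @export
extract_segment <- function(aln, interval) {
  nc <- nchar(aln$seqs[1])
  stopifnot(length(interval) == 2L, interval[1] >= 0, interval[2] <= nc,
            interval[1] < interval[2])
  seqs <- substr(aln$seqs, interval[1] + 1L, interval[2])
  keep <- gsub("-", "", seqs) != ""
  if (!any(keep)) stop("segment extraction left no non-empty rows")
  out <- msa(aln$ids[keep], seqs[keep])
  attr(out, "dropped") <- aln$ids[!keep]
  out
}

#' Map residue positions of one row to alignment columns
#'
#' Converts 1-based residue positions of an ungapped member sequence into
#' 0-based alignment column indices, for translating published
#' sequence-coordinate segments into column intervals.
#'
#' @param aln an [msa]
#' @param row_id row whose residue numbering is used
#' @param positions 1-based residue positions
#' @return 0-based column indices
#' @export
residue_to_column <- function(aln, row_id, positions) {
  i <- match(row_id, aln$ids)
  if (is.na(i)) stop("row '", row_id, "' not in alignment")
  chars <- strsplit(aln$seqs[i], "")[[1]]
  res_cols <- which(chars != "-")
  if (any(positions < 1L | positions > length(res_cols))) {
    stop("position out of range for row '", row_id, "' (",
         length(res_cols), " residues)")
  }
  res_cols[positions] - 1L
}

#' Pairwise identity between two aligned rows
#'
#' Identity = identical-residue columns / columns where at least one row has
#' a residue; dual-gap columns are ignored. Returns 0 when no column scores.
#'
#' @param a,b equal-length gapped strings
#' @return fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  scored <- ca != "-" | cb != "-"
  if (!any(scored)) return(0)
  sum(ca == cb & ca != "-" & scored) / sum(scored)
}

#' Remove redundant rows at an identity threshold
#'
#' Greedy, worst-first: while any pair reaches the threshold, the most
#' similar pair is resolved by removing its member with fewer residues in
#' the alignment (tie: the lexicographically later id). At least one row
#' always survives.
#'
#' @param aln an [msa]
#' @param identity_threshold fraction in (0, 1]
#' @return list `aln` (the reduced [msa]) and `removed` (character vector)
#' @export
remove_redundant <- function(aln, identity_threshold = 0.80) {
  n <- length(aln$ids)
  if (n == 1L) return(list(aln = aln, removed = character()))
  idm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(aln$seqs[i], aln$seqs[j])
    }
  }
  nres <- nchar(gsub("-", "", aln$seqs))
  ids <- aln$ids
  alive <- rep(TRUE, n)
  removed <- character()
  repeat {
    idx <- which(alive)
    if (length(idx) <= 1L) break
    sub <- idm[idx, idx, drop = FALSE]
    diag(sub) <- -1
    mx <- max(sub)
    if (mx < identity_threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1L, ]
    i <- idx[hit[1]]; j <- idx[hit[2]]
    drop_i <- if (nres[i] != nres[j]) {
      if (nres[i] < nres[j]) i else j
    } else {
      if (ids[i] > ids[j]) i else j   # tie: lexicographically later id goes
    }
    alive[drop_i] <- FALSE
    removed <- c(removed, ids[drop_i])
  }
  keep <- which(alive)
  list(aln = msa(ids[keep], aln$seqs[keep]), removed = removed)
}

# --- internal progressive aligner ------------------------------------------

blosum62_20 <- function() {
  B <- get_blosum62()
  B[AA20, AA20]
}

# cache the Biostrings substitution matrix in the package namespace
get_blosum62 <- local({
  B <- NULL
  function() {
    if (is.null(B)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      B <<- e$BLOSUM62
    }
    B
  }
})

# per-column residue frequency matrix (ncol x 20), gaps contribute nothing
profile_freqs <- function(aln) {
  m <- msa_matrix(aln)
  nc <- ncol(m)
  f <- matrix(0, nc, 20, dimnames = list(NULL, AA20))
  for (a in AA20) f[, a] <- colSums(m == a)
  # ambiguity letters spread uniformly over the 20 standard residues
  amb <- colSums(matrix(m %in% AA_AMBIG, nrow(m), nc))
  f <- f + amb / 20
  f / nrow(m)
}

# global profile-profile alignment (Gotoh affine, all state transitions
# allowed); returns merged msa. Column score = expected BLOSUM62 over the
# two column residue distributions; gap symbols score 0.
align_profiles <- function(alnA, alnB, gap_open = 11, gap_extend = 1) {
  S <- profile_freqs(alnA) %*% blosum62_20() %*% t(profile_freqs(alnB))
  La <- nrow(S); Lb <- ncol(S)
  NEG <- -1e9
  M <- matrix(NEG, La + 1L, Lb + 1L)
  X <- matrix(NEG, La + 1L, Lb + 1L)  # gap in B (A column unmatched)
  Y <- matrix(NEG, La + 1L, Lb + 1L)  # gap in A
  M[1, 1] <- 0
  for (i in seq_len(La)) X[i + 1L, 1] <- -gap_open - (i - 1L) * gap_extend
  for (j in seq_len(Lb)) Y[1, j + 1L] <- -gap_open - (j - 1L) * gap_extend
  jj <- seq_len(Lb) + 1L
  for (i in seq_len(La)) {
    ii <- i + 1L
    M[ii, jj] <- S[i, ] + pmax(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L],
                               Y[ii - 1L, jj - 1L])
    X[ii, jj] <- pmax(M[ii - 1L, jj] - gap_open, Y[ii - 1L, jj] - gap_open,
                      X[ii - 1L, jj] - gap_extend)
    # Y extends horizontally: running max over pmax(M, X) of this row
    Z <- pmax(M[ii, ], X[ii, ])
    A <- Z + seq_len(Lb + 1L) * gap_extend
    Y[ii, jj] <- pmax(cummax(A)[jj - 1L] - gap_open - jj * gap_extend +
                        gap_extend, NEG)
  }
  # traceback from the best terminal state
  path <- character()
  i <- La; j <- Lb
  state <- c("M", "X", "Y")[which.max(c(M[La + 1L, Lb + 1L],
                                        X[La + 1L, Lb + 1L],
                                        Y[La + 1L, Lb + 1L]))]
  score <- max(M[La + 1L, Lb + 1L], X[La + 1L, Lb + 1L], Y[La + 1L, Lb + 1L])
  while (i > 0L || j > 0L) {
    ii <- i + 1L; jj <- j + 1L
    if (state == "M") {
      path <- c("M", path)
      prev <- c(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      path <- c("X", path)
      if (i == 1L && j == 0L) { i <- 0L; next }
      prev <- c(M[ii - 1L, jj] - gap_open, X[ii - 1L, jj] - gap_extend,
                Y[ii - 1L, jj] - gap_open)
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1L
    } else {
      path <- c("Y", path)
      if (j == 1L && i == 0L) { j <- 0L; next }
      prev <- c(M[ii, jj - 1L] - gap_open, X[ii, jj - 1L] - gap_open,
                Y[ii, jj - 1L] - gap_extend)
      state <- c("M", "X", "Y")[which.max(prev)]
      j <- j - 1L
    }
  }
  mA <- msa_matrix(alnA); mB <- msa_matrix(alnB)
  nA <- nrow(mA); nB <- nrow(mB)
  outA <- matrix("-", nA, length(path)); outB <- matrix("-", nB, length(path))
  ia <- 0L; ib <- 0L
  for (k in seq_along(path)) {
    if (path[k] != "Y") { ia <- ia + 1L; outA[, k] <- mA[, ia] }
    if (path[k] != "X") { ib <- ib + 1L; outB[, k] <- mB[, ib] }
  }
  merged <- rbind(outA, outB)
  rownames(merged) <- c(rownames(mA), rownames(mB))
  out <- msa_from_matrix(merged)
  attr(out, "score") <- score
  out
}

# fraction of shared k-mers (of the smaller set), a cheap identity proxy
kmer_distance <- function(a, b, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  ka <- km(a); kb <- km(b)
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Progressively align ungapped protein sequences
#'
#' Builds a guide tree by UPGMA on k-mer (k = 3) distances, then merges
#' sequence groups bottom-up with global profile-profile dynamic programming
#' (BLOSUM62 expected column scores, affine gaps). Deterministic: records
#' are canonicalised by id before tree construction, so the result does not
#' depend on input order.
#'
#' @param records data.frame with `id`, `residues` (ungapped), or a named
#'   character vector
#' @param gap_open,gap_extend affine gap costs (defaults 11 and 1)
#' @return an [msa] over the input ids
#' @export
realign <- function(records, gap_open = 11, gap_extend = 1) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), residues = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(!any(grepl("-", records$residues, fixed = TRUE)))
  ord <- order(records$id)
  ids <- records$id[ord]
  seqs <- toupper(records$residues[ord])
  n <- length(ids)
  if (n == 1L) return(msa(ids, seqs))
  groups <- lapply(seq_len(n), function(i) msa(ids[i], seqs[i]))
  if (n == 2L) {
    return(align_profiles(groups[[1]], groups[[2]], gap_open, gap_extend))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs[i], seqs[j])
    }
  }
  tree <- hclust(as.dist(D), method = "average")   # UPGMA
  node <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(v) if (v < 0) groups[[-v]] else node[[v]]
    node[[s]] <- align_profiles(pick(tree$merge[s, 1]), pick(tree$merge[s, 2]),
                                gap_open, gap_extend)
  }
  out <- node[[n - 1L]]
  m <- msa_matrix(out)[ids, , drop = FALSE]
  msa_from_matrix(m)
}

#' Delete rare long insert blocks from an alignment
#'
#' A column is insert-like when its residue occupancy (non-gap fraction) is
#' strictly below `indel_occupancy`. Maximal runs of insert-like columns
#' longer than `max_indel_len` are deleted entire; shorter runs are kept.
#'
#' @param aln an [msa]
#' @param max_indel_len run-length threshold (default 2)
#' @param indel_occupancy occupancy threshold (default 0.50)
#' @return list `aln` (the stripped [msa]) and `removed_blocks`
#'   (data.frame of 0-based half-open column intervals)
#' @export
strip_rare_long_indels <- function(aln, max_indel_len = 2L,
                                   indel_occupancy = 0.50) {
  m <- msa_matrix(aln)
  occ <- colMeans(m != "-")
  insertish <- occ < indel_occupancy
  r <- rle(insertish)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kill <- r$values & r$lengths > max_indel_len
  blocks <- data.frame(start = starts[kill] - 1L, end = ends[kill])
  drop_cols <- unlist(mapply(seq, starts[kill], ends[kill], SIMPLIFY = FALSE))
  if (length(drop_cols)) {
    if (length(drop_cols) == ncol(m)) stop("indel stripping removed all columns")
    m <- m[, -drop_cols, drop = FALSE]
    keep_rows <- rowSums(m != "-") > 0
    m <- m[keep_rows, , drop = FALSE]
  }
  list(aln = msa_from_matrix(m), removed_blocks = blocks)
}

#' Iteratively curate an alignment
#'
#' Applies the segment extraction once (when `params$segment` is set), then
#' loops redundancy removal, progressive re-alignment of the surviving
#' (degapped) sequences, and rare-long-indel stripping until an iteration
#' changes nothing or `max_iterations` is reached.
#'
#' @param aln an [msa]
#' @param params a [curation_params] object
#' @return list `aln` (curated [msa]) and `report` (class `curation_report`:
#'   per-iteration actions, final dimensions, `converged` flag)
#' @export
curate <- function(aln, params = curation_params()) {
  stopifnot(inherits(params, "curation_params"))
  actions <- list()
  note <- function(iter, action, target, detail) {
    actions[[length(actions) + 1L]] <<- data.frame(
      iteration = iter, action = action, target = target, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (!is.null(params$segment)) {
    aln <- extract_segment(aln, params$segment)
    for (id in attr(aln, "dropped") %||% character()) {
      note(0L, "segment_drop_row", id, "all-gap inside segment")
    }
    note(0L, "extract_segment", paste(params$segment, collapse = ":"),
         paste0("columns ", ncol(msa_matrix(aln))))
  }
  converged <- FALSE
  iter <- 0L
  dims <- dim(aln)
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    before <- aln
    rr <- remove_redundant(aln, params$identity_threshold)
    for (id in rr$removed) note(iter, "remove_redundant", id,
                                sprintf(">= %.2f identity", params$identity_threshold))
    aln <- rr$aln
    if (length(aln$ids) >= 2L) {
      degapped <- setNames(gsub("-", "", aln$seqs), aln$ids)
      aln <- realign(degapped, params$gap_open, params$gap_extend)
      note(iter, "realign", "all", sprintf("%d columns", dim(aln)[2]))
    }
    st <- strip_rare_long_indels(aln, params$max_indel_len,
                                 params$indel_occupancy)
    if (nrow(st$removed_blocks)) {
      for (b in seq_len(nrow(st$removed_blocks))) {
        note(iter, "strip_indel_block",
             sprintf("%d:%d", st$removed_blocks$start[b], st$removed_blocks$end[b]),
             sprintf("occupancy < %.2f, len > %d", params$indel_occupancy,
                     params$max_indel_len))
      }
    }
    aln <- st$aln
    if (dim(aln)[2] == 0L) {
      stop("curation collapsed the alignment to 0 columns after iteration ", iter)
    }
    dims <- rbind(dims, dim(aln))
    if (identical(sort(before$ids), sort(aln$ids)) &&
        identical(before$seqs[order(before$ids)], aln$seqs[order(aln$ids)])) {
      converged <- TRUE
      break
    }
  }
  report <- structure(list(
    actions = if (length(actions)) do.call(rbind, actions) else
      data.frame(iteration = integer(), action = character(),
                 target = character(), detail = character()),
    dims = dims,
    iterations = iter,
    converged = converged,
    aligner = sprintf("internal progressive (BLOSUM62, open %g, extend %g)",
                      params$gap_open, params$gap_extend),
    final_dim = dim(aln)), class = "curation_report")
  list(aln = aln, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation report: ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("final dimensions: ", x$final_dim[1], " rows x ", x$final_dim[2],
      " columns\n", sep = "")
  cat("aligner: ", x$aligner, "\n", sep = "")
  if (nrow(x$actions)) print(head(x$actions, 20))
  invisible(x)
}
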