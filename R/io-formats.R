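# Readers and writers for the standard formats the pipeline touches:
# FASTA, aligned FASTA, Stockholm, HMMER-style tabular hits, habitat TSV.
# Internal coordinates are 0-based half-open; files use 1-based inclusive.

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; this wrapper adds
#' the validation the pipeline relies on: unique ids, a restricted alphabet
#' (20 standard residues plus B, Z, X, U, O, J), upper-casing, and stripping
#' of a terminal `*` stop codon.
#'
#' @param path path to a FASTA file
#' @return data.frame with columns `id`, `description`, `residues`
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected '>' header before sequence data")
  }
  # alphabet check with line numbers, before handing off to Biostrings
  seq_lines <- nonblank[!startsWith(trimws(lines[nonblank]), ">")]
  for (i in seq_lines) {
    chars <- strsplit(toupper(trimws(lines[i])), "")[[1]]
    chars <- chars[chars != "*"]
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("FASTA parse error at line ", i, ": illegal residue character '",
           bad[1], "'")
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": '",
         ids[duplicated(ids)][1], "'")
  }
  res <- toupper(as.character(aa))
  res <- sub("\\*$", "", res)
  if (any(!nzchar(res))) {
    stop("empty sequence for id '", ids[!nzchar(res)][1], "'")
  }
  data.frame(id = ids, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id`, `description`, `residues`
#' @param path output path
#' @param width line wrap width
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(records$residues)
  names(aa) <- ifelse(nzchar(records$description %||% ""),
                      paste(records$id, records$description),
                      records$id)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

# --- Msa container ----------------------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' @param ids unique row identifiers
#' @param seqs equal-length gapped strings, `-` as gap (`.` is normalised)
#' @return object of class `msa`
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate row id: '", ids[duplicated(ids)][1], "'")
  seqs <- chartr(".", "-", toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1]][1]
    stop("ragged alignment: row '", bad, "' has length ",
         widths[widths != widths[1]][1], ", expected ", widths[1])
  }
  if (any(gsub("-", "", seqs) == "")) {
    stop("all-gap row: '", ids[gsub("-", "", seqs) == ""][1], "'")
  }
  structure(list(ids = as.character(ids), seqs = unname(seqs)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$ids), " rows x ", nchar(x$seqs[1]), " columns\n", sep = "")
  n <- min(6L, length(x$ids))
  w <- min(60L, nchar(x$seqs[1]))
  for (i in seq_len(n)) {
    cat(format(x$ids[i], width = 14), substr(x$seqs[i], 1, w),
        if (nchar(x$seqs[1]) > w) "..." else "", "\n")
  }
  if (length(x$ids) > n) cat("  ... ", length(x$ids) - n, " more rows\n", sep = "")
  invisible(x)
}

#' @export
dim.msa <- function(x) c(length(x$ids), nchar(x$seqs[1]))

# character matrix view of an msa (rows x columns)
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

msa_from_matrix <- function(m) {
  msa(rownames(m), apply(m, 1L, paste, collapse = ""))
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm. `.` gaps are normalised to `-`.
#'
#' @param path input file
#' @param dialect `"fasta"`, `"stockholm"`, or `"auto"` (sniff first line)
#' @return an [msa] object
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (dialect == "fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1L, ends[i])][hdr[i] < ends[i] | TRUE], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    return(msa(ids, seqs))
  }
  # Stockholm: '# ' comments, '//' terminator, possibly interleaved blocks
  lines <- readLines(path, warn = FALSE)
  data <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  parts <- regmatches(data, regexpr("^\\S+", data))
  seqparts <- trimws(sub("^\\S+\\s+", "", data))
  ids <- unique(parts)
  seqs <- vapply(ids, function(id) paste(seqparts[parts == id], collapse = ""),
                 character(1))
  msa(ids, unname(seqs))
}

#' Write an alignment to aligned FASTA or Stockholm
#' @param aln an [msa]
#' @param path output path
#' @param dialect `"fasta"` or `"stockholm"`
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$ids), aln$seqs)), path)
  } else {
    w <- max(nchar(aln$ids)) + 2L
    writeLines(c("# STOCKHOLM 1.0",
                 paste0(formatC(aln$ids, width = -w), aln$seqs),
                 "//"), path)
  }
  invisible(path)
}

# --- Hit tables -------------------------------------------------------------

#' Read a tabular profile-search hit file
#'
#' Accepts HMMER per-target (`tblout`) and per-domain (`domtblout`) dialects
#' and a plain TSV with columns target_id, profile_id, bit_score, e_value,
#' start, end (1-based inclusive on file; converted to 0-based half-open).
#'
#' @param path input file
#' @param dialect one of `"tsv"`, `"tblout"`, `"domtblout"`
#' @return data.frame with columns `target_id`, `profile_id`, `bit_score`,
#'   `e_value`, `start`, `end` (0-based half-open)
#' @export
read_hit_table <- function(path, dialect = c("tsv", "tblout", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  if (dialect == "tsv") {
    f <- strsplit(lines, "\t", fixed = TRUE)
    ncol_bad <- which(lengths(f) < 6L)
    if (length(ncol_bad)) {
      stop("hit table line ", ncol_bad[1], ": expected 6 columns ",
           "(target_id, profile_id, bit_score, e_value, start, end)")
    }
    m <- do.call(rbind, f)
    out <- data.frame(target_id = m[, 1], profile_id = m[, 2],
                      bit_score = as.numeric(m[, 3]),
                      e_value = as.numeric(m[, 4]),
                      start = as.integer(m[, 5]) - 1L,
                      end = as.integer(m[, 6]),
                      stringsAsFactors = FALSE)
  } else {
    f <- strsplit(trimws(lines), "\\s+")
    if (dialect == "tblout") {
      # target(1) -(2) query(3) -(4) evalue(5) score(6); no coordinates
      out <- data.frame(
        target_id = vapply(f, `[`, "", 1L),
        profile_id = vapply(f, `[`, "", 3L),
        bit_score = as.numeric(vapply(f, `[`, "", 6L)),
        e_value = as.numeric(vapply(f, `[`, "", 5L)),
        start = NA_integer_, end = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      # domtblout: target(1) query(4) full-seq evalue(7) score(8),
      # envelope coordinates in columns 20 (from) and 21 (to), 1-based
      out <- data.frame(
        target_id = vapply(f, `[`, "", 1L),
        profile_id = vapply(f, `[`, "", 4L),
        bit_score = as.numeric(vapply(f, `[`, "", 8L)),
        e_value = as.numeric(vapply(f, `[`, "", 7L)),
        start = as.integer(vapply(f, `[`, "", 20L)) - 1L,
        end = as.integer(vapply(f, `[`, "", 21L)),
        stringsAsFactors = FALSE)
    }
  }
  if (any(!is.finite(out$bit_score))) stop("non-finite bit_score in ", path)
  if (any(out$e_value < 0, na.rm = TRUE)) stop("negative e_value in ", path)
  bad <- which(!is.na(out$start) & out$start >= out$end)
  if (length(bad)) stop("empty or inverted envelope for target '",
                        out$target_id[bad[1]], "'")
  out
}

empty_hits <- function() {
  data.frame(target_id = character(), profile_id = character(),
             bit_score = numeric(), e_value = numeric(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' Write hits as plain TSV (1-based inclusive coordinates on file)
#' @param hits data.frame as from [read_hit_table()]
#' @param path output path
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(target_id = hits$target_id, profile_id = hits$profile_id,
                    bit_score = hits$bit_score, e_value = hits$e_value,
                    start = hits$start + 1L, end = hits$end)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- Habitat tables ---------------------------------------------------------

#' Read a taxa-by-habitat annotation table
#'
#' TSV with a header line: first column the taxon id, an optional
#' `positive_protein_count` column, and one column per habitat trait with
#' values in 0/1/yes/no/NA. NA traits are recorded as unknown and are
#' excluded from any contingency built on that trait.
#'
#' @param path input TSV
#' @return data.frame: `taxon_id`, `positive_protein_count`, then one
#'   logical (NA-able) column per trait
#' @export
read_habitat_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  names(tab)[1] <- "taxon_id"
  if (anyDuplicated(tab$taxon_id)) {
    stop("duplicate taxon id: '", tab$taxon_id[duplicated(tab$taxon_id)][1], "'")
  }
  if (!"positive_protein_count" %in% names(tab)) {
    tab$positive_protein_count <- 0L
  }
  if (any(tab$positive_protein_count < 0, na.rm = TRUE)) {
    stop("negative positive_protein_count")
  }
  traits <- setdiff(names(tab), c("taxon_id", "positive_protein_count"))
  for (tr in traits) {
    v <- tolower(as.character(tab[[tr]]))
    ok <- v %in% c("0", "1", "yes", "no") | is.na(v)
    if (any(!ok)) stop("trait '", tr, "': illegal value '", v[!ok][1],
                       "' (want 0/1/yes/no/NA)")
    tab[[tr]] <- ifelse(is.na(v), NA, v %in% c("1", "yes"))
  }
  tab[c("taxon_id", "positive_protein_count", traits)]
}
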