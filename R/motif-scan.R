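# PROSITE-style pattern subset: literals, x wildcards with repeat ranges,
# [..] classes and {..} negated classes, '-' separated. Used for the zincin
# HEXXH and gluzincin HEXXHX(8,28)E catalytic motifs.

#' Parse a PROSITE-style pattern
#'
#' Supported grammar: single-letter literals, `x`, `x(n)`, `x(n,m)`,
#' `[ABC]` residue classes, `{ABC}` negated classes, elements joined by
#' `-`. Anchors (`<`, `>`) and class repeats are not supported.
#'
#' @param text pattern text, e.g. `"H-E-x-x-H-x(8,28)-E"`
#' @param pattern_id identifier attached to matches (default: the text)
#' @return object of class `motif_pattern`
#' @export
parse_pattern <- function(text, pattern_id = text) {
  tokens <- strsplit(gsub("\\s|\\.$", "", text), "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0L) stop("empty pattern")
  elements <- vector("list", length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (grepl("^[A-WYZ]$", tok) && tok %in% AA20) {
      elements[[k]] <- list(kind = "literal", residues = tok, min = 1L, max = 1L)
    } else if (grepl("^[xX]$", tok)) {
      elements[[k]] <- list(kind = "wildcard", residues = NULL, min = 1L, max = 1L)
    } else if (grepl("^[xX]\\(\\d+\\)$", tok)) {
      n <- as.integer(sub("^[xX]\\((\\d+)\\)$", "\\1", tok))
      elements[[k]] <- list(kind = "wildcard", residues = NULL, min = n, max = n)
    } else if (grepl("^[xX]\\(\\d+,\\d+\\)$", tok)) {
      nm <- as.integer(strsplit(sub("^[xX]\\((\\d+,\\d+)\\)$", "\\1", tok), ",")[[1]])
      if (nm[1] > nm[2]) {
        stop("pattern element ", k, " ('", tok, "'): min repeat exceeds max")
      }
      elements[[k]] <- list(kind = "wildcard", residues = NULL,
                            min = nm[1], max = nm[2])
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      res <- strsplit(gsub("\\[|\\]", "", tok), "")[[1]]
      bad <- setdiff(res, AA20)
      if (length(bad)) stop("pattern element ", k, ": non-standard residue '",
                            bad[1], "' in class")
      elements[[k]] <- list(kind = "class", residues = res, min = 1L, max = 1L)
    } else if (grepl("^\\{[A-Z]+\\}$", tok)) {
      res <- strsplit(gsub("\\{|\\}", "", tok), "")[[1]]
      bad <- setdiff(res, AA20)
      if (length(bad)) stop("pattern element ", k, ": non-standard residue '",
                            bad[1], "' in negated class")
      elements[[k]] <- list(kind = "negated", residues = res, min = 1L, max = 1L)
    } else {
      stop("pattern parse error at element ", k, ": '", tok, "'")
    }
  }
  structure(list(pattern_id = pattern_id, elements = elements),
            class = "motif_pattern")
}

#' Canonical text of a parsed pattern
#' @param pattern a `motif_pattern`
#' @return character scalar that re-parses to the same pattern
#' @export
pattern_to_text <- function(pattern) {
  paste(vapply(pattern$elements, function(el) {
    switch(el$kind,
      literal = el$residues,
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      negated = paste0("{", paste(el$residues, collapse = ""), "}"),
      wildcard = if (el$min == 1L && el$max == 1L) "x"
                 else if (el$min == el$max) sprintf("x(%d)", el$min)
                 else sprintf("x(%d,%d)", el$min, el$max))
  }, character(1)), collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern '", x$pattern_id, "': ", pattern_to_text(x), "\n", sep = "")
  invisible(x)
}

#' The minimal zincin metallopeptidase motif HEXXH
#' @return a `motif_pattern`
#' @export
zincin_pattern <- function() parse_pattern("H-E-x-x-H", pattern_id = "zincin")

#' The gluzincin-like motif HEXXH followed by a third-ligand glutamate
#'
#' The downstream glutamate sits 8 to 28 residues after the second
#' histidine by default; the range is a parameter because published
#' descriptions of this family vary between (8,28) and (8,24).
#'
#' @param spacer length-2 integer range for the H-to-E spacer
#' @return a `motif_pattern`
#' @export
gluzincin_pattern <- function(spacer = c(8L, 28L)) {
  parse_pattern(sprintf("H-E-x-x-H-x(%d,%d)-E", spacer[1], spacer[2]),
                pattern_id = "gluzincin")
}

# does one sequence character satisfy one fixed element?
# ambiguity letters satisfy wildcards only, never literals or classes.
element_ok <- function(el, ch) {
  switch(el$kind,
    wildcard = ch %in% AA_ALPHABET,
    literal = ch == el$residues,
    class = ch %in% el$residues,
    negated = (ch %in% AA20) && !(ch %in% el$residues))
}

#' Scan a sequence for all occurrences of a pattern
#'
#' Exhaustive sliding evaluation: every start position and every expansion
#' of variable-range wildcards that yields a match is reported once per
#' distinct interval, in deterministic left-to-right order.
#'
#' @param pattern a `motif_pattern`
#' @param record one-row data.frame (`id`, `residues`) or named string
#' @param collapse `"none"` reports every interval; `"shortest"` keeps only
#'   the shortest match per start position (one count per motif anchor)
#' @param region optional 0-based half-open interval restricting the scan
#'   (e.g. a profile hit envelope); reported coordinates stay sequence-wide
#' @return data.frame: `pattern_id`, `target_id`, `start`, `end` (0-based
#'   half-open), `matched`, `spacer_len` (residues consumed by the variable
#'   wildcard when the pattern has exactly one, else NA)
#' @export
scan_pattern <- function(pattern, record, collapse = c("none", "shortest"),
                         region = NULL) {
  collapse <- match.arg(collapse)
  if (is.character(record)) {
    record <- data.frame(id = names(record) %||% "seq",
                         residues = unname(record), stringsAsFactors = FALSE)
  }
  chars <- strsplit(toupper(record$residues), "")[[1]]
  offset <- 0L
  if (!is.null(region)) {
    stopifnot(region[1] >= 0, region[2] <= length(chars), region[1] < region[2])
    chars <- chars[(region[1] + 1L):region[2]]
    offset <- as.integer(region[1])
  }
  n <- length(chars)
  els <- pattern$elements
  var_el <- which(vapply(els, function(e) e$max > e$min, logical(1)))
  res <- list()
  # recursive expansion over elements; k = element index, pos = next char (1-based)
  walk <- function(k, pos, start, spacer) {
    if (k > length(els)) {
      res[[length(res) + 1L]] <<- c(start, pos, spacer %||% NA_integer_)
      return(invisible())
    }
    el <- els[[k]]
    for (take in el$min:el$max) {
      if (pos + take - 1L > n) break
      ok <- if (el$kind == "wildcard") {
        take == 0L || all(chars[pos:(pos + take - 1L)] %in% AA_ALPHABET)
      } else {
        element_ok(el, chars[pos])
      }
      if (!ok) next
      sp <- if (length(var_el) == 1L && k == var_el) take else spacer
      walk(k + 1L, pos + take, start, sp)
      if (el$kind != "wildcard") break
    }
  }
  for (s in seq_len(n)) {
    # fail fast on the first element before recursing
    if (els[[1]]$kind != "wildcard" && !element_ok(els[[1]], chars[s])) next
    walk(1L, s, s, NULL)
  }
  if (length(res) == 0L) {
    return(data.frame(pattern_id = character(), target_id = character(),
                      start = integer(), end = integer(), matched = character(),
                      spacer_len = integer(), stringsAsFactors = FALSE))
  }
  m <- unique(do.call(rbind, res))
  out <- data.frame(pattern_id = pattern$pattern_id, target_id = record$id,
                    start = m[, 1] - 1L + offset, end = m[, 2] - 1L + offset,
                    matched = vapply(seq_len(nrow(m)), function(i) {
                      paste(chars[m[i, 1]:(m[i, 2] - 1L)], collapse = "")
                    }, character(1)),
                    spacer_len = m[, 3], stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (collapse == "shortest") {
    out <- do.call(rbind, lapply(split(out, out$start), function(g) {
      g[which.min(g$end), , drop = FALSE]
    }))
    out <- out[order(out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify a protein's zinc-metallopeptidase motif status
#'
#' `"gluzincin"` when at least one gluzincin match exists, else
#' `"zincin_only"` when at least one HEXXH exists, else `"none"`.
#'
#' @param record one-row data.frame (`id`, `residues`) or named string
#' @param zincin,gluzincin the two patterns (defaults [zincin_pattern()] and
#'   [gluzincin_pattern()])
#' @param region optional 0-based half-open interval restricting the scan
#' @return character scalar
#' @export
classify_motif_status <- function(record, zincin = zincin_pattern(),
                                  gluzincin = gluzincin_pattern(),
                                  region = NULL) {
  if (nrow(scan_pattern(gluzincin, record, region = region)) > 0L) return("gluzincin")
  if (nrow(scan_pattern(zincin, record, region = region)) > 0L) return("zincin_only")
  "none"
}
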