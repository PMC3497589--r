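#' Glossary index
#'
#' Maps normalised phrases (one to four words; normalisation is case
#' folding plus whitespace collapse) to target URLs, with a stop-word set
#' of common single words that are never linked on their own even when the
#' index contains them - multi-word phrases containing a stop word still
#' match.
#'
#' @param entries Named character vector: names are phrases, values URLs.
#' @param stop_words Character vector of single words.
#' @return A `glossary_index`.
#' @examples
#' gi <- glossary_index(
#'   c("space group" = "https://example.org/space_group",
#'     "group" = "https://example.org/group",
#'     "group theory" = "https://example.org/group"),
#'   stop_words = "group")
#' @export
glossary_index <- function(entries, stop_words = character(0)) {
  stopifnot(is.character(entries), !is.null(names(entries)))
  phrases <- normalize_phrase(names(entries))
  nw <- lengths(strsplit(phrases, " ", fixed = TRUE))
  if (any(nw < 1L | nw > 4L))
    stop("glossary phrases must be 1-4 words")
  names(entries) <- phrases
  if (anyDuplicated(phrases)) stop("duplicate glossary phrase")
  structure(list(entries = entries,
                 stop_words = normalize_phrase(stop_words)),
            class = "glossary_index")
}

normalize_phrase <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Read a glossary index from a two-column TSV file
#' @param path File with tab-separated `phrase<TAB>url` lines; lines
#'   starting `#stop<TAB>word` declare stop words.
#' @return A `glossary_index`.
#' @export
read_glossary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stop_words <- character(0)
  phrases <- character(0)
  urls <- character(0)
  for (p in parts) {
    if (identical(p[[1L]], "#stop")) {
      stop_words <- c(stop_words, p[[2L]])
    } else if (length(p) >= 2L) {
      phrases <- c(phrases, p[[1L]])
      urls <- c(urls, p[[2L]])
    }
  }
  glossary_index(stats::setNames(urls, phrases), stop_words)
}

# tokenize text into words with original character offsets; punctuation is
# stripped at token edges for matching, but spans keep original offsets of
# the stripped core
tokenize_words <- function(text) {
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      core = character(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- regmatches(text, list(m))[[1L]]
  lead <- nchar(sub("^([^[:alnum:]]*).*$", "\\1", toks))
  trail <- nchar(sub("^.*?([^[:alnum:]]*)$", "\\1", toks))
  core_start <- starts + lead
  core_end <- starts + lens - trail          # exclusive
  core <- substring(text, core_start, core_end - 1L)
  keep <- core_end > core_start
  data.frame(start = core_start[keep], end = core_end[keep],
             core = tolower(core[keep]), stringsAsFactors = FALSE)
}

#' Annotate text against a glossary index
#'
#' Scans left to right with a shrinking word window: at each position the
#' four-word phrase is tried first, then three, two and one; the first
#' (longest) hit wins, the annotation covers the matched words, and the
#' scan resumes after them.  Single words on the stop-word list are never
#' matched at window size one.  Every occurrence of a phrase is annotated,
#' annotations never overlap, and spans lie on word boundaries.
#'
#' @param text A character scalar.
#' @param index A [glossary_index].
#' @return A data frame with columns `start`, `end` (1-based character
#'   offsets, half-open: `substring(text, start, end - 1)` is the matched
#'   text), `phrase` (matched text as it appears) and `target` (URL).
#' @export
annotate <- function(text, index) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(index, "glossary_index"))
  words <- tokenize_words(text)
  n <- nrow(words)
  out <- list()
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (w in 4:1) {
      if (i + w - 1L > n) next
      phrase <- paste(words$core[i:(i + w - 1L)], collapse = " ")
      if (w == 1L && phrase %in% index$stop_words) next
      target <- index$entries[phrase]
      if (!is.na(target)) {
        s <- words$start[i]
        e <- words$end[i + w - 1L]
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e,
          phrase = substring(text, s, e - 1L),
          target = unname(target), stringsAsFactors = FALSE)
        i <- i + w
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      phrase = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

GEOM_LABEL_RE <- "[A-Z][a-z]?[0-9]+['\u2032]*"
GEOM_SEP_RE <- "(?:---|\u2014|\u2013|\\.{3}|\u22ef|-)"

#' Scan text for molecular-geometry mentions
#'
#' Detects the typographic pattern of geometry references in structure
#' reports: chains of two to four atom labels (element symbol, digits,
#' optional primes) joined by dashes (`C2---C21---C22---C221`) or, for
#' non-bonded contacts, by three dots.  The kind follows the label count -
#' two labels give a distance (or contact with the dots separator), three
#' an angle, four a torsion.  An immediately following printed value with
#' optional parenthesised standard uncertainty and unit is captured.
#'
#' @param text A character scalar.
#' @return A data frame with columns `kind`, `labels` (list column),
#'   `value`, `su`, `value_text`, `start`, `end` (offsets of the label
#'   chain, half-open).
#' @export
scan_geometry <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- paste0("(?<![A-Za-z0-9'\u2032])", GEOM_LABEL_RE,
                "(?:", GEOM_SEP_RE, GEOM_LABEL_RE, "){1,3}",
                "(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  empty <- data.frame(kind = character(0), value = numeric(0),
                      su = numeric(0), value_text = character(0),
                      start = integer(0), end = integer(0))
  empty$labels <- list()
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  chains <- regmatches(text, list(m))[[1L]]
  rows <- list()
  for (i in seq_along(chains)) {
    chain <- chains[[i]]
    labels <- regmatches(chain,
                         gregexpr(GEOM_LABEL_RE, chain, perl = TRUE))[[1L]]
    seps <- regmatches(chain, gregexpr(GEOM_SEP_RE, chain, perl = TRUE))[[1L]]
    contact <- any(seps %in% c("...", "\u22ef"))
    kind <- switch(as.character(length(labels)),
                   "2" = if (contact) "contact" else "distance",
                   "3" = "angle", "4" = "torsion", NA_character_)
    if (is.na(kind)) next
    rest <- substring(text, starts[i] + lens[i])
    vm <- regmatches(rest, regexec(
      "^[ \t]*=?[ \t]*(-?[0-9]+(?:\\.[0-9]+)?)(?:[ \t]*\\(([0-9]+)\\))?",
      rest))[[1L]]
    value <- NA_real_; su <- NA_real_; value_text <- NA_character_
    if (length(vm) && nzchar(vm[2L])) {
      value <- as.numeric(vm[2L])
      value_text <- trimws(vm[1L], which = "left")
      value_text <- sub("^=[ \t]*", "", value_text)
      if (nzchar(vm[3L])) {
        mant <- vm[2L]
        dot <- regexpr(".", mant, fixed = TRUE)
        ndec <- if (dot > 0L) nchar(mant) - dot else 0L
        su <- as.vector(as.numeric(vm[3L]) * 10^(-ndec))
      }
    }
    row <- data.frame(kind = kind, value = value, su = su,
                      value_text = value_text,
                      start = starts[i], end = starts[i] + lens[i],
                      stringsAsFactors = FALSE)
    row$labels <- list(labels)
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

geom_table_spec <- function(kind) {
  switch(kind,
    distance = list(labels = paste0("_geom_bond_atom_site_label_", 1:2),
                    value = "_geom_bond_distance"),
    contact = list(labels = paste0("_geom_contact_atom_site_label_", 1:2),
                   value = "_geom_contact_distance"),
    angle = list(labels = paste0("_geom_angle_atom_site_label_", 1:3),
                 value = "_geom_angle"),
    torsion = list(labels = paste0("_geom_torsion_atom_site_label_", 1:4),
                   value = "_geom_torsion"))
}

#' Resolve geometry mentions against a block's tabulated geometry
#'
#' A mention binds to a table row when the kinds agree and the label
#' sequences agree forwards or reversed.  Mentions with no tabulated
#' counterpart are dropped from the actionable output (they were only
#' typographic coincidences); a unique match is bound directly; several
#' matches are all returned and flagged ambiguous so the reader can pick
#' the feature of interest.
#'
#' @param mentions A data frame from [scan_geometry()].
#' @param block A [cif_block] holding `_geom_*` loops, or a list of blocks
#'   (e.g. several structures discussed in one article).
#' @return A list, one element per resolvable mention: `mention` (one-row
#'   data frame), `matches` (data frame with `block`, `row`, `value`) and
#'   `ambiguous` (flag).
#' @export
resolve_mentions <- function(mentions, block) {
  blocks <- if (inherits(block, "cif_block")) list(block) else block
  out <- list()
  for (i in seq_len(nrow(mentions))) {
    mrow <- mentions[i, , drop = FALSE]
    labels <- mrow$labels[[1L]]
    spec <- geom_table_spec(mrow$kind)
    matches <- data.frame(block = character(0), row = integer(0),
                          value = numeric(0))
    for (b in blocks) {
      cols <- lapply(spec$labels, function(t) cif_loop_column(b, t))
      if (any(vapply(cols, is.null, logical(1L)))) next
      vals <- cif_loop_column(b, spec$value)
      nrows <- length(cols[[1L]])
      for (r in seq_len(nrows)) {
        seq_r <- vapply(cols, function(cl) cl[[r]]$raw, "")
        if (identical(seq_r, labels) || identical(rev(seq_r), labels)) {
          matches <- rbind(matches, data.frame(
            block = b$name, row = r,
            value = if (is.null(vals)) NA_real_ else cif_numeric(vals[[r]])))
        }
      }
    }
    if (nrow(matches) > 0L) {
      out[[length(out) + 1L]] <- list(mention = mrow, matches = matches,
                                      ambiguous = nrow(matches) > 1L)
    }
  }
  out
}
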