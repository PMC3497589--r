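parse_error <- function(msg, line = NA_integer_) {
  full <- if (is.na(line)) msg else sprintf("line %d: %s", line, msg)
  stop(structure(class = c("cifsem_parse_error", "error", "condition"),
                 list(message = full, call = sys.call(-1))))
}

# Tokenize CIF text into a list of tokens:
# list(type = "data"|"loop"|"tag"|"value", text, quoted, textblock, line)
tokenize_cif <- function(lines) {
  tokens <- vector("list", 64L)
  ntok <- 0L
  push <- function(type, text, quoted = FALSE, textblock = FALSE, line = 0L) {
    ntok <<- ntok + 1L
    if (ntok > length(tokens)) tokens[[2L * ntok]] <<- NULL
    tokens[[ntok]] <<- list(type = type, text = text, quoted = quoted,
                            textblock = textblock, line = line)
  }
  ws <- c(" ", "\t", "\r")
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      # semicolon text block: opened by ';' in column 1
      first <- substring(line, 2L)
      open_line <- i
      body <- character(0)
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        if (startsWith(lines[[i]], ";")) { closed <- TRUE; break }
        body <- c(body, lines[[i]])
        i <- i + 1L
      }
      if (!closed) parse_error("unterminated text block", open_line)
      content <- if (nzchar(first)) paste(c(first, body), collapse = "\n")
                 else paste(body, collapse = "\n")
      push("value", content, textblock = TRUE, line = open_line)
      # anything after the closing ';' continues as ordinary tokens
      rest <- substring(lines[[i]], 2L)
      i <- i + 1L
      if (nzchar(trimws(rest))) {
        tokenize_line(rest, i - 1L, push, ws)
      }
      next
    }
    tokenize_line(line, i, push, ws)
    i <- i + 1L
  }
  tokens[seq_len(ntok)]
}

# Tokenize one physical line (no leading-column semicolon).
tokenize_line <- function(line, lineno, push, ws) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  nc <- length(chars)
  pos <- 1L
  while (pos <= nc) {
    ch <- chars[[pos]]
    if (ch %in% ws) { pos <- pos + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      # closing quote must be followed by white space or end of line
      j <- pos + 1L
      close <- NA_integer_
      while (j <= nc) {
        if (chars[[j]] == ch && (j == nc || chars[[j + 1L]] %in% ws)) {
          close <- j; break
        }
        j <- j + 1L
      }
      if (is.na(close)) parse_error("unterminated quoted string", lineno)
      txt <- if (close > pos + 1L)
        paste(chars[(pos + 1L):(close - 1L)], collapse = "") else ""
      push("value", txt, quoted = TRUE, line = lineno)
      pos <- close + 1L
      next
    }
    j <- pos
    while (j <= nc && !(chars[[j]] %in% ws) && chars[[j]] != "#") j <- j + 1L
    # '#' only starts a comment when preceded by white space
    if (j <= nc && chars[[j]] == "#") {
      while (j <= nc && !(chars[[j]] %in% ws)) j <- j + 1L
    }
    tok <- paste(chars[pos:(j - 1L)], collapse = "")
    low <- tolower(tok)
    if (startsWith(tok, "_")) {
      push("tag", tok, line = lineno)
    } else if (startsWith(low, "data_")) {
      nm <- substring(tok, 6L)
      if (!nzchar(nm)) parse_error("data_ keyword without a block name", lineno)
      push("data", nm, line = lineno)
    } else if (low == "loop_") {
      push("loop", tok, line = lineno)
    } else if (low %in% c("global_", "stop_") || startsWith(low, "save_")) {
      parse_error(paste0("unsupported STAR keyword '", tok, "'"), lineno)
    } else {
      push("value", tok, line = lineno)
    }
    pos <- j
  }
}

#' Parse CIF text into a document
#'
#' Reads the classic CIF 1.1 tag-value/loop syntax: named `data_` blocks,
#' `_tag value` items, `loop_` tables with interleaved rows, single- and
#' double-quoted strings, semicolon-delimited text blocks and `#` comments.
#' Layout is irrelevant outside quoted regions; comments are discarded.
#' Bare tokens that look like numbers are typed numerically, with trailing
#' parenthesised integers read as standard uncertainties; `?` is the
#' unknown-value token and `.` the inapplicable-value token.  Duplicate tags
#' within a block are an error (this package exists to validate files, so it
#' is strict rather than last-wins).
#'
#' @param text A character scalar (possibly with embedded newlines), a
#'   character vector of lines, or a file path to read (when `file = TRUE`).
#' @param file If `TRUE`, `text` names a file to read.
#' @return A [cif_document].
#' @seealso [write_cif()], [lex_number()]
#' @examples
#' doc <- parse_cif("data_x\n_cell_length_a 5.12(3)")
#' cif_get(doc$blocks[[1]], "_cell_length_a")
#' @export
parse_cif <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) lines <- ""
  bad <- grep("[^\x01-\x7F]", lines)
  if (length(bad))
    parse_error("non-ASCII character in input", bad[[1L]])

  tokens <- tokenize_cif(lines)
  blocks <- list()
  cur <- NULL        # list(name, items, loops, line)
  seen_tags <- NULL  # lowercase tags already used in current block

  flush_block <- function() {
    if (is.null(cur)) return()
    blocks[[length(blocks) + 1L]] <<-
      structure(list(name = cur$name, items = cur$items, loops = cur$loops),
                class = "cif_block")
  }
  claim_tag <- function(tag, line) {
    low <- tolower(tag)
    if (low %in% seen_tags)
      parse_error(paste0("duplicate tag ", tag, " in block '", cur$name, "'"),
                  line)
    seen_tags <<- c(seen_tags, low)
  }

  i <- 1L
  ntok <- length(tokens)
  while (i <= ntok) {
    tk <- tokens[[i]]
    if (tk$type == "data") {
      flush_block()
      if (tolower(tk$text) %in% tolower(vapply(blocks, `[[`, "", "name")))
        parse_error(paste0("duplicate data block '", tk$text, "'"), tk$line)
      cur <- list(name = tk$text, items = list(), loops = list())
      seen_tags <- character(0)
      i <- i + 1L
    } else if (is.null(cur)) {
      parse_error("content before the first data_ block", tk$line)
    } else if (tk$type == "tag") {
      if (i + 1L > ntok || tokens[[i + 1L]]$type != "value")
        parse_error(paste0("tag ", tk$text, " has no value"), tk$line)
      claim_tag(tk$text, tk$line)
      vt <- tokens[[i + 1L]]
      cur$items[[tk$text]] <-
        cif_value(vt$text, quoted = vt$quoted, textblock = vt$textblock)
      i <- i + 2L
    } else if (tk$type == "loop") {
      loop_line <- tk$line
      i <- i + 1L
      tags <- character(0)
      while (i <= ntok && tokens[[i]]$type == "tag") {
        claim_tag(tokens[[i]]$text, tokens[[i]]$line)
        tags <- c(tags, tokens[[i]]$text)
        i <- i + 1L
      }
      if (length(tags) == 0L)
        parse_error("loop_ without any tags", loop_line)
      vals <- list()
      while (i <= ntok && tokens[[i]]$type == "value") {
        vt <- tokens[[i]]
        vals[[length(vals) + 1L]] <-
          cif_value(vt$text, quoted = vt$quoted, textblock = vt$textblock)
        i <- i + 1L
      }
      if (length(vals) == 0L)
        parse_error("loop_ with no values", loop_line)
      if (length(vals) %% length(tags) != 0L)
        parse_error(sprintf(
          "loop value count (%d) is not a multiple of header length (%d)",
          length(vals), length(tags)), loop_line)
      nrows <- length(vals) %/% length(tags)
      rows <- vector("list", nrows)
      for (r in seq_len(nrows)) {
        rows[[r]] <- vals[((r - 1L) * length(tags) + 1L):(r * length(tags))]
      }
      cur$loops[[length(cur$loops) + 1L]] <-
        structure(list(tags = tags, rows = rows), class = "cif_loop")
    } else {
      parse_error(paste0("unexpected value '", tk$text, "'"), tk$line)
    }
  }
  flush_block()
  cif_document(blocks)
}
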