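RESERVED_WORD_RE <- "^(data_|loop_$|global_$|stop_$|save_)"

# Does a value need quoting to survive a round trip as the same kind?
needs_quoting <- function(v) {
  raw <- v$raw
  if (v$kind %in% c("unknown", "inapplicable")) return(FALSE)
  if (!nzchar(raw)) return(TRUE)
  if (grepl("[ \t]", raw)) return(TRUE)
  first <- substring(raw, 1L, 1L)
  if (first %in% c("_", "#", "$", "'", "\"", ";", "[", "]")) return(TRUE)
  if (grepl(RESERVED_WORD_RE, tolower(raw))) return(TRUE)
  # literal "?" / "." strings and number-like strings must stay strings
  if (raw %in% c("?", ".")) return(TRUE)
  if (is.null(v$numeric) && !is.null(lex_number(raw))) return(TRUE)
  FALSE
}

# Render one value as a CIF token, or return a text-block marker.
# A quote character is usable unless the content contains that quote
# followed by white space (or at the end), which would close the string.
text_block_token <- function(raw) {
  if (grepl("(^|\n);", raw))
    stop("write_cif: text-block value contains a line starting with ';'")
  # a leading newline needs an explicit empty first body line to round trip
  open <- if (startsWith(raw, "\n")) ";\n" else ";"
  list(text = paste0(open, raw, "\n;"), block = TRUE)
}

format_value <- function(v) {
  raw <- v$raw
  if (grepl("\n", raw, fixed = TRUE) || v$kind == "text-block") {
    return(text_block_token(raw))
  }
  if (v$kind == "unknown") return(list(text = "?", block = FALSE))
  if (v$kind == "inapplicable") return(list(text = ".", block = FALSE))
  if (!needs_quoting(v)) return(list(text = raw, block = FALSE))
  if (!grepl("'([ \t]|$)", raw)) {
    return(list(text = paste0("'", raw, "'"), block = FALSE))
  }
  if (!grepl("\"([ \t]|$)", raw)) {
    return(list(text = paste0("\"", raw, "\""), block = FALSE))
  }
  text_block_token(raw)
}

#' Write a CIF document as text
#'
#' Emits classic CIF 1.1 syntax reproducing the data model exactly:
#' `parse_cif(write_cif(doc))` equals `doc` in tags, value kinds, numeric
#' interpretations and loop structure.  Values containing white space or
#' other syntactically active characters are quoted; multi-line values are
#' emitted as semicolon-delimited text blocks.  Lines are wrapped at 80
#' columns where the syntax allows.
#'
#' @param doc A [cif_document] (or a single [cif_block], which is wrapped).
#' @param file Optional path; when given the text is also written there.
#' @return The CIF text as a single character scalar (invisibly when `file`
#'   is given).
#' @examples
#' doc <- parse_cif("data_x\n_a 1.5(2)\n_b 'two words'")
#' cat(write_cif(doc))
#' @export
write_cif <- function(doc, file = NULL) {
  if (inherits(doc, "cif_block")) doc <- cif_document(list(doc))
  out <- character(0)
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  for (block in doc$blocks) {
    emit("data_", block$name)
    if (length(block$items)) {
      width <- max(nchar(names(block$items))) + 1L
      for (tag in names(block$items)) {
        fv <- format_value(block$items[[tag]])
        if (fv$block) {
          emit(tag)
          emit(fv$text)
        } else if (nchar(tag) + 1L + nchar(fv$text) > 80L) {
          emit(tag)
          emit(fv$text)
        } else {
          emit(formatC(tag, width = -width), fv$text)
        }
      }
    }
    for (lp in block$loops) {
      emit("loop_")
      for (tag in lp$tags) emit(" ", tag)
      for (row in lp$rows) {
        line <- ""
        for (v in row) {
          fv <- format_value(v)
          if (fv$block) {
            if (nzchar(line)) { emit(line); line <- "" }
            emit(fv$text)
          } else if (nzchar(line) &&
                     nchar(line) + 1L + nchar(fv$text) > 80L) {
            emit(line)
            line <- fv$text
          } else {
            line <- if (nzchar(line)) paste(line, fv$text) else fv$text
          }
        }
        if (nzchar(line)) emit(line)
      }
    }
    emit("")
  }
  text <- paste(out, collapse = "\n")
  if (grepl("[^\x01-\x7F]", text))
    stop("write_cif: non-ASCII content in document")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}
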