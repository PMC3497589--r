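#' Lex a bare token as a CIF number
#'
#' CIF data typing is lexical: "if it looks like a number, treat it as a
#' number".  A bare token is numeric when it matches an integer, decimal or
#' exponential form, optionally followed by a parenthesised trailing integer
#' giving the standard uncertainty (su) in units of the place value of the
#' last digit of the mantissa, e.g. `"1.234(5)"` means 1.234 with su 0.005.
#' Quoted tokens are never numeric; this function only ever sees bare tokens.
#'
#' @param token A single character string (one bare CIF value token).
#' @return A list with components `value` and `su` (`su` is `NA_real_` when
#'   no uncertainty is attached), or `NULL` when the token is not numeric.
#'   Never raises: any non-matching token simply returns `NULL`.
#' @examples
#' lex_number("1.234(5)")   # value 1.234, su 0.005
#' lex_number("-12")        # value -12, no su
#' lex_number("P21/c")      # NULL
#' @export
lex_number <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) return(NULL)
  m <- regmatches(token, regexec(
    "^([+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+))(?:[eE]([+-]?[0-9]+))?(?:\\(([0-9]+)\\))?$",
    token))[[1L]]
  if (length(m) == 0L) return(NULL)
  mant <- m[2L]
  expo <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
  value <- as.numeric(mant) * 10^expo
  if (!is.finite(value)) return(NULL)
  su <- NA_real_
  if (nzchar(m[4L])) {
    # place value of the last mantissa digit, scaled by any exponent
    dot <- regexpr(".", mant, fixed = TRUE)
    ndec <- if (dot > 0L) nchar(mant) - dot else 0L
    su <- as.numeric(m[4L]) * 10^(-ndec + expo)
  }
  list(value = as.vector(value), su = as.vector(su))
}

#' Construct a CIF value
#'
#' A `cif_value` carries the raw character string as it appears in the file,
#' a `kind` distinguishing ordinary strings, semicolon text blocks and the
#' special tokens `"?"` (unknown) and `"."` (inapplicable), and, for bare
#' tokens that lex as numbers, the numeric interpretation with optional
#' standard uncertainty.
#'
#' @param raw Character scalar, the value text (without delimiters).
#' @param quoted Was the token quoted in the source (or should it be treated
#'   as a deliberate string)?  Quoted values are never numeric and `"?"`/
#'   `"."` keep their literal string meaning.
#' @param textblock Is this a multi-line semicolon text block?
#' @return An object of class `cif_value` with fields `raw`, `kind`
#'   (`"string"`, `"text-block"`, `"unknown"` or `"inapplicable"`) and
#'   `numeric` (a `list(value, su)` or `NULL`).
#' @export
cif_value <- function(raw, quoted = FALSE, textblock = FALSE) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  if (textblock) {
    kind <- "text-block"
    num <- NULL
  } else if (quoted) {
    kind <- "string"
    num <- NULL
  } else if (identical(raw, "?")) {
    kind <- "unknown"
    num <- NULL
  } else if (identical(raw, ".")) {
    kind <- "inapplicable"
    num <- NULL
  } else {
    kind <- "string"
    num <- lex_number(raw)
  }
  structure(list(raw = raw, kind = kind, numeric = num), class = "cif_value")
}

#' Coerce to a CIF value
#'
#' Numbers are formatted with up to 12 significant digits (so round trips
#' through text preserve them to well below typical experimental precision);
#' existing `cif_value` objects pass through unchanged.
#'
#' @param x A `cif_value`, single number, or single character string.
#' @return A `cif_value`.
#' @export
as_cif_value <- function(x) {
  if (inherits(x, "cif_value")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(cif_value(format_cif_number(x)))
  }
  if (is.character(x) && length(x) == 1L) {
    # strings that happen to look numeric stay strings: mark as quoted
    v <- cif_value(x)
    return(v)
  }
  stop("cannot coerce to cif_value: ", paste(class(x), collapse = "/"))
}

# Format a number as a bare CIF token that lexes back to the same double
# (within 1e-12 relative).
format_cif_number <- function(x) {
  s <- format(x, digits = 12, scientific = FALSE, trim = TRUE)
  if (abs(x) >= 1e15 || (x != 0 && abs(x) < 1e-6)) {
    s <- format(x, digits = 12, scientific = TRUE, trim = TRUE)
    s <- sub("e", "E", s, fixed = TRUE)
  }
  s
}

#' @export
print.cif_value <- function(x, ...) {
  num <- if (is.null(x$numeric)) "" else {
    su <- if (is.na(x$numeric$su)) "" else paste0(" su=", x$numeric$su)
    paste0(" [", x$numeric$value, su, "]")
  }
  cat(sprintf("<cif_value %s: %s%s>\n", x$kind, x$raw, num))
  invisible(x)
}

#' Numeric value of a CIF value
#'
#' @param x A `cif_value` (or `NULL`).
#' @return The lexed numeric value, or `NA_real_` when `x` is missing or
#'   non-numeric.
#' @export
cif_numeric <- function(x) {
  if (is.null(x) || is.null(x$numeric)) return(NA_real_)
  x$numeric$value
}
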