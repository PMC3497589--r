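#' CIF dictionaries: machine-readable semantics for tags
#'
#' A dictionary is itself a CIF document in which each data block defines
#' one or more tags using a small bootstrap set of attribute tags (a
#' deliberate reduction of DDL1):
#'
#' * `_name` - the tag being defined (may be looped to define several tags
#'   with one block),
#' * `_category` - grouping identifier,
#' * `_type` - `numb` or `char`,
#' * `_units` - preferred unit (declarative only; no conversion is done),
#' * `_enumeration` - allowed values (usually looped),
#' * `_enumeration_range` - closed numeric range as a `"min:max"` string
#'   with either side optionally empty,
#' * `_list` - `yes` (tag must appear in a loop), `no` (must not), `both`,
#' * `_type_conditions` - `su` when a parenthesised standard uncertainty is
#'   permitted on values,
#' * `_definition` - human-readable prose.
#'
#' Unknown attribute tags are preserved in the parsed document but ignored.
#' The bootstrap set is itself defined, in the same formalism, in the
#' shipped dictionary `system.file("extdata", "ddl_bootstrap.dic", package =
#' "cifsem")`, which validates against itself with zero violations.
#'
#' @param doc A [cif_document] parsed from dictionary text.
#' @param prefixes Character vector of registered namespace prefixes that
#'   definition names may carry in addition to the core namespace.
#' @return A `cif_dictionary` with fields `title`, `definitions` (named by
#'   lower-case tag) and `namespace_prefixes`.
#' @examples
#' dic <- parse_dictionary(parse_cif(
#'   "data_cell_length_a\n_name _cell_length_a\n_type numb\n_units angstroms"))
#' names(dic$definitions)
#' @export
parse_dictionary <- function(doc, prefixes = character(0)) {
  stopifnot(inherits(doc, "cif_document"))
  attr_tags <- c("_category", "_type", "_units", "_enumeration",
                 "_enumeration_range", "_list", "_definition",
                 "_type_conditions")
  defs <- list()
  title <- NULL
  for (block in doc$blocks) {
    dn <- cif_get(block, "_dictionary_name")
    if (!is.null(dn) && is.null(title)) title <- dn$raw

    names_col <- cif_loop_column(block, "_name")
    if (is.null(names_col)) {
      v <- cif_get(block, "_name")
      if (!is.null(v)) names_col <- list(v)
    }
    has_attrs <- any(tolower(attr_tags) %in% tolower(cif_tags(block)))
    if (is.null(names_col)) {
      if (has_attrs)
        stop("dictionary block '", block$name, "' has definition attributes ",
             "but no _name")
      next
    }

    item_or_null <- function(tag) {
      v <- cif_get(block, tag)
      if (is.null(v) || v$kind %in% c("unknown", "inapplicable")) NULL
      else v$raw
    }
    type_code <- item_or_null("_type")
    if (is.null(type_code)) type_code <- "char"
    if (!type_code %in% c("numb", "char"))
      stop("definition in block '", block$name, "': _type must be numb or char")

    enum <- NULL
    ec <- cif_loop_column(block, "_enumeration")
    if (!is.null(ec)) {
      enum <- vapply(ec, `[[`, "", "raw")
    } else {
      e1 <- item_or_null("_enumeration")
      if (!is.null(e1)) enum <- e1
    }

    range <- NULL
    rs <- item_or_null("_enumeration_range")
    if (!is.null(rs)) {
      m <- regmatches(rs, regexec("^([^:]*):([^:]*)$", rs))[[1L]]
      if (length(m) == 0L)
        stop("definition in block '", block$name,
             "': bad _enumeration_range '", rs, "'")
      lo <- if (nzchar(m[2L])) as.numeric(m[2L]) else NA_real_
      hi <- if (nzchar(m[3L])) as.numeric(m[3L]) else NA_real_
      range <- c(min = lo, max = hi)
    }
    if (!is.null(enum) && !is.null(range))
      stop("definition in block '", block$name,
           "': enumeration and range are mutually exclusive")
    if (!is.null(range) && type_code != "numb")
      stop("definition in block '", block$name,
           "': _enumeration_range requires _type numb")

    lc <- item_or_null("_list")
    list_context <- switch(if (is.null(lc)) "both" else lc,
                           yes = "required-in-loop",
                           no = "forbidden-in-loop",
                           both = "either",
                           stop("definition in block '", block$name,
                                "': _list must be yes, no or both"))
    su_ok <- identical(item_or_null("_type_conditions"), "su")

    for (nv in names_col) {
      nm <- nv$raw
      if (!startsWith(nm, "_"))
        stop("definition name '", nm, "' does not begin with '_'")
      key <- tolower(nm)
      if (!is.null(defs[[key]]))
        stop("tag ", nm, " is defined twice")
      defs[[key]] <- structure(list(
        name = nm,
        category = item_or_null("_category"),
        type_code = type_code,
        units = item_or_null("_units"),
        enumeration = enum,
        range = range,
        list_context = list_context,
        su_allowed = su_ok,
        definition_text = item_or_null("_definition")
      ), class = "cif_definition")
    }
  }
  if (is.null(title)) {
    title <- if (length(doc$blocks)) doc$blocks[[1L]]$name else ""
  }
  structure(list(title = title, definitions = defs,
                 namespace_prefixes = prefixes),
            class = "cif_dictionary")
}

#' @export
print.cif_dictionary <- function(x, ...) {
  cat(sprintf("<cif_dictionary '%s': %d definitions>\n",
              x$title, length(x$definitions)))
  invisible(x)
}

#' Load a dictionary shipped with the package
#'
#' @param which `"core"` for the packaged core crystallographic dictionary
#'   or `"ddl"` for the self-defining bootstrap attribute dictionary.
#' @return A `cif_dictionary`.
#' @export
load_dictionary <- function(which = c("core", "ddl")) {
  which <- match.arg(which)
  fname <- switch(which, core = "cifsem_core.dic", ddl = "ddl_bootstrap.dic")
  path <- system.file("extdata", fname, package = "cifsem")
  parse_dictionary(parse_cif(path, file = TRUE))
}

new_violation <- function(tag, block, code, message) {
  structure(list(tag = tag, block = block, code = code, message = message),
            class = "cif_violation")
}

#' @export
print.cif_violation <- function(x, ...) {
  cat(sprintf("[%s] %s (%s): %s\n", x$code, x$tag, x$block, x$message))
  invisible(x)
}

# validate a single value occurrence against a definition
check_value <- function(v, def, tag, blockname, where) {
  out <- list()
  add <- function(code, msg) out[[length(out) + 1L]] <<-
    new_violation(tag, blockname, code, msg)
  if (v$kind %in% c("unknown", "inapplicable")) return(out)
  if (def$type_code == "numb") {
    if (is.null(v$numeric)) {
      add("type-mismatch",
          sprintf("value '%s' %s is not numeric for numb-typed tag",
                  v$raw, where))
      return(out)
    }
    if (!is.na(v$numeric$su) && !isTRUE(def$su_allowed)) {
      add("missing-su-disallowed",
          sprintf("value '%s' %s carries a standard uncertainty but the %s",
                  v$raw, where, "definition does not permit one"))
    }
    if (!is.null(def$range)) {
      x <- v$numeric$value
      lo <- def$range[["min"]]; hi <- def$range[["max"]]
      if ((!is.na(lo) && x < lo) || (!is.na(hi) && x > hi)) {
        add("range-violation",
            sprintf("value %s %s outside range %s:%s", v$raw, where,
                    ifelse(is.na(lo), "", lo), ifelse(is.na(hi), "", hi)))
      }
    }
  }
  if (!is.null(def$enumeration) && !(v$raw %in% def$enumeration)) {
    add("enum-violation",
        sprintf("value '%s' %s not in enumeration {%s}", v$raw, where,
                paste(def$enumeration, collapse = ", ")))
  }
  out
}

#' Validate a data block against a dictionary
#'
#' Applies, in document order, the checks encoded in the dictionary: tag
#' existence (when `strict_unknown`), numeric typing, enumerations, closed
#' numeric ranges, list context (tags restricted to loops or to single
#' items) and standard-uncertainty permission.  The unknown (`?`) and
#' inapplicable (`.`) tokens satisfy every value-level check.  Findings are
#' returned as data, never raised.
#'
#' @param block A [cif_block].
#' @param dict A `cif_dictionary` from [parse_dictionary()].
#' @param strict_unknown Flag: report tags absent from the dictionary.
#' @return A list of `cif_violation` objects (fields `tag`, `block`, `code`,
#'   `message`), in stable document order.
#' @export
validate_block <- function(block, dict, strict_unknown = FALSE) {
  stopifnot(inherits(block, "cif_block"), inherits(dict, "cif_dictionary"))
  out <- list()
  push <- function(v) out <<- c(out, v)
  lookup <- function(tag) dict$definitions[[tolower(tag)]]

  for (tag in names(block$items)) {
    def <- lookup(tag)
    if (is.null(def)) {
      if (strict_unknown)
        push(list(new_violation(tag, block$name, "unknown-tag",
                                "tag not defined in dictionary")))
      next
    }
    if (def$list_context == "required-in-loop")
      push(list(new_violation(tag, block$name, "loop-context",
                              "tag must appear in a loop")))
    push(check_value(block$items[[tag]], def, tag, block$name, "(item)"))
  }
  for (lp in block$loops) {
    for (j in seq_along(lp$tags)) {
      tag <- lp$tags[[j]]
      def <- lookup(tag)
      if (is.null(def)) {
        if (strict_unknown)
          push(list(new_violation(tag, block$name, "unknown-tag",
                                  "tag not defined in dictionary")))
        next
      }
      if (def$list_context == "forbidden-in-loop")
        push(list(new_violation(tag, block$name, "loop-context",
                                "tag must not appear in a loop")))
      for (r in seq_along(lp$rows)) {
        push(check_value(lp$rows[[r]][[j]], def, tag, block$name,
                         sprintf("(loop row %d)", r)))
      }
    }
  }
  out
}

#' Validate every block of a document
#' @inheritParams validate_block
#' @param doc A [cif_document].
#' @return A list of `cif_violation` objects.
#' @export
validate_document <- function(doc, dict, strict_unknown = FALSE) {
  out <- list()
  for (b in doc$blocks) out <- c(out, validate_block(b, dict, strict_unknown))
  out
}
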