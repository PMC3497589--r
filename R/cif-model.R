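#' CIF data model: loops, data blocks and documents
#'
#' A CIF document is an ordered list of named data blocks.  Each block holds
#' an ordered map of single-valued items (tag to [cif_value]) and a list of
#' loops (tabular constructs: a header of tags plus interleaved rows).  Tags
#' always begin with an underscore and are compared case-insensitively while
#' being stored as given.  A tag may appear at most once across a block's
#' items and loop headers.
#'
#' @param tags Character vector of tag names (each starting with `_`).
#' @param rows List of rows; each row is a list of [cif_value] objects with
#'   length equal to `length(tags)`.
#' @return `cif_loop`, `cif_block` and `cif_document` objects respectively.
#' @name cif-model
NULL

#' @rdname cif-model
#' @export
cif_loop <- function(tags, rows = list()) {
  stopifnot(is.character(tags), length(tags) >= 1L)
  if (!all(startsWith(tags, "_"))) stop("loop tags must begin with '_'")
  if (anyDuplicated(tolower(tags))) stop("duplicate tag within loop header")
  for (r in rows) {
    if (length(r) != length(tags)) stop("loop row length does not match header")
  }
  structure(list(tags = tags, rows = rows), class = "cif_loop")
}

#' @rdname cif-model
#' @param name Block name (the part after `data_`).
#' @param items Named list of [cif_value] objects; names are tags.
#' @param loops List of `cif_loop` objects.
#' @export
cif_block <- function(name, items = list(), loops = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(items) && (is.null(names(items)) || any(!nzchar(names(items)))))
    stop("items must be a named list")
  tags <- c(tolower(names(items)),
            tolower(unlist(lapply(loops, `[[`, "tags"), use.names = FALSE)))
  if (anyDuplicated(tags))
    stop("duplicate tag in block '", name, "': ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "))
  if (length(items) && !all(startsWith(names(items), "_")))
    stop("tags must begin with '_'")
  structure(list(name = name, items = items, loops = loops),
            class = "cif_block")
}

#' @rdname cif-model
#' @param blocks List of `cif_block` objects with unique names.
#' @export
cif_document <- function(blocks = list()) {
  nm <- tolower(vapply(blocks, `[[`, "", "name"))
  if (anyDuplicated(nm)) stop("duplicate data block name")
  structure(list(blocks = blocks), class = "cif_document")
}

#' Look up a single-valued item in a block (case-insensitive)
#'
#' @param block A `cif_block`.
#' @param tag Tag name.
#' @return The [cif_value], or `NULL` when the tag is not present as an item.
#' @export
cif_get <- function(block, tag) {
  i <- match(tolower(tag), tolower(names(block$items)))
  if (is.na(i)) NULL else block$items[[i]]
}

#' Numeric value of an item, or NA
#' @inheritParams cif_get
#' @export
cif_get_num <- function(block, tag) cif_numeric(cif_get(block, tag))

#' Set or replace a single-valued item
#'
#' @inheritParams cif_get
#' @param value A [cif_value], number or string (coerced via [as_cif_value]).
#' @return The updated block.
#' @export
cif_set <- function(block, tag, value) {
  value <- as_cif_value(value)
  i <- match(tolower(tag), tolower(names(block$items)))
  if (is.na(i)) {
    if (!is.null(cif_loop_column(block, tag)))
      stop("tag ", tag, " already present in a loop")
    block$items[[tag]] <- value
  } else {
    block$items[[i]] <- value
  }
  block
}

#' Remove an item (no-op when absent)
#' @inheritParams cif_get
#' @export
cif_remove <- function(block, tag) {
  i <- match(tolower(tag), tolower(names(block$items)))
  if (!is.na(i)) block$items[[i]] <- NULL
  block
}

#' Extract a loop column by tag (case-insensitive)
#'
#' @inheritParams cif_get
#' @return A list of [cif_value] objects (one per row), or `NULL` when no
#'   loop carries the tag.
#' @export
cif_loop_column <- function(block, tag) {
  for (lp in block$loops) {
    j <- match(tolower(tag), tolower(lp$tags))
    if (!is.na(j)) return(lapply(lp$rows, `[[`, j))
  }
  NULL
}

# index of the loop containing a tag, or NA
loop_index_of <- function(block, tag) {
  for (k in seq_along(block$loops)) {
    if (tolower(tag) %in% tolower(block$loops[[k]]$tags)) return(k)
  }
  NA_integer_
}

#' All tags present in a block, in document order
#' @param block A `cif_block`.
#' @export
cif_tags <- function(block) {
  c(names(block$items),
    unlist(lapply(block$loops, `[[`, "tags"), use.names = FALSE))
}

#' Fetch a block by name (case-insensitive)
#' @param doc A `cif_document`.
#' @param name Block name.
#' @export
cif_block_get <- function(doc, name) {
  i <- match(tolower(name), tolower(vapply(doc$blocks, `[[`, "", "name")))
  if (is.na(i)) NULL else doc$blocks[[i]]
}

#' @export
print.cif_block <- function(x, ...) {
  cat(sprintf("<cif_block '%s': %d items, %d loops>\n",
              x$name, length(x$items), length(x$loops)))
  invisible(x)
}

#' @export
print.cif_document <- function(x, ...) {
  cat(sprintf("<cif_document: %d blocks>\n", length(x$blocks)))
  for (b in x$blocks) print(b)
  invisible(x)
}

value_equal <- function(a, b) {
  if (!identical(a$raw, b$raw) || !identical(a$kind, b$kind)) return(FALSE)
  if (is.null(a$numeric) != is.null(b$numeric)) return(FALSE)
  if (!is.null(a$numeric)) {
    if (!isTRUE(all.equal(a$numeric$value, b$numeric$value))) return(FALSE)
    if (is.na(a$numeric$su) != is.na(b$numeric$su)) return(FALSE)
    if (!is.na(a$numeric$su) &&
        !isTRUE(all.equal(a$numeric$su, b$numeric$su))) return(FALSE)
  }
  TRUE
}

#' Structural equality of CIF documents
#'
#' Compares blocks, items, loops, value kinds and numeric interpretations;
#' tag and block-name comparison is case-sensitive on the stored spelling
#' (a round trip preserves spelling exactly).
#'
#' @param a,b `cif_document` objects.
#' @return `TRUE` or `FALSE`.
#' @export
cif_equal <- function(a, b) {
  if (length(a$blocks) != length(b$blocks)) return(FALSE)
  for (i in seq_along(a$blocks)) {
    ba <- a$blocks[[i]]; bb <- b$blocks[[i]]
    if (!identical(ba$name, bb$name)) return(FALSE)
    if (!identical(names(ba$items), names(bb$items))) return(FALSE)
    for (j in seq_along(ba$items)) {
      if (!value_equal(ba$items[[j]], bb$items[[j]])) return(FALSE)
    }
    if (length(ba$loops) != length(bb$loops)) return(FALSE)
    for (j in seq_along(ba$loops)) {
      la <- ba$loops[[j]]; lb <- bb$loops[[j]]
      if (!identical(la$tags, lb$tags)) return(FALSE)
      if (length(la$rows) != length(lb$rows)) return(FALSE)
      for (r in seq_along(la$rows)) {
        for (cidx in seq_along(la$tags)) {
          if (!value_equal(la$rows[[r]][[cidx]], lb$rows[[r]][[cidx]]))
            return(FALSE)
        }
      }
    }
  }
  TRUE
}
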