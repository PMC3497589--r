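#' Derivation methods and dependency graphs
#'
#' A derivation method is an executable rule that computes the value of one
#' tag from the values of other tags, in the spirit of dictionaries that
#' carry algorithmic method definitions.  The engine here keeps the same
#' dependency-resolution semantics - recursive, stored-value-first,
#' memoised - while representing each method as a registered R function
#' rather than interpreted dictionary text.
#'
#' @param output Tag the method derives.
#' @param inputs Character vector of input tags (non-empty, must not
#'   contain `output`).
#' @param compute A function `function(values, block)` where `values` is a
#'   named list of resolved numeric inputs (scalars for items, numeric
#'   vectors for loop columns) and `block` the data block being processed.
#'   Must return a numeric scalar or vector.
#' @return `cif_method` returns a method object; `derivation_graph` an
#'   empty graph.
#' @export
cif_method <- function(output, inputs, compute) {
  stopifnot(is.character(output), length(output) == 1L,
            is.character(inputs), length(inputs) >= 1L,
            is.function(compute))
  if (tolower(output) %in% tolower(inputs))
    stop("method output must not be among its inputs")
  structure(list(output = output, inputs = inputs, compute = compute),
            class = "cif_method")
}

#' @rdname cif_method
#' @export
derivation_graph <- function() {
  structure(list(methods = list()), class = "derivation_graph")
}

# all tags reachable from `tag` by following method inputs
reachable_inputs <- function(methods, tag) {
  seen <- character(0)
  stack <- tolower(tag)
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    m <- methods[[t]]
    if (!is.null(m)) stack <- c(stack, tolower(m$inputs))
  }
  seen
}

#' Register a derivation method
#'
#' Registration fails if the output tag already has a method or if adding
#' the method would create a dependency cycle.
#'
#' @param graph A `derivation_graph`.
#' @param method A [cif_method].
#' @return The updated graph.
#' @examples
#' g <- register_method(derivation_graph(), cif_method(
#'   "_cell_volume",
#'   c("_cell_length_a", "_cell_length_b", "_cell_length_c",
#'     "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"),
#'   function(v, block) with(v, cell_volume(unit_cell(
#'     `_cell_length_a`, `_cell_length_b`, `_cell_length_c`,
#'     `_cell_angle_alpha`, `_cell_angle_beta`, `_cell_angle_gamma`)))))
#' @export
register_method <- function(graph, method) {
  stopifnot(inherits(graph, "derivation_graph"), inherits(method, "cif_method"))
  key <- tolower(method$output)
  if (!is.null(graph$methods[[key]]))
    stop("a method for ", method$output, " is already registered")
  trial <- graph$methods
  trial[[key]] <- method
  for (inp in method$inputs) {
    if (key %in% reachable_inputs(trial, inp))
      stop("registering a method for ", method$output,
           " would create a dependency cycle through ", inp)
  }
  graph$methods <- trial
  graph
}

#' Get the registered method for a tag (or NULL)
#' @inheritParams register_method
#' @param tag Output tag name.
#' @export
get_method <- function(graph, tag) graph$methods[[tolower(tag)]]

# Resolve a tag to numeric content from the block itself.
# Returns list(found, value) where value is scalar or vector, or NULL
# when the tag is present but not numeric.
stored_numeric <- function(block, tag) {
  v <- cif_get(block, tag)
  if (!is.null(v)) {
    if (is.null(v$numeric)) return(list(found = TRUE, value = NULL, item = v))
    return(list(found = TRUE, value = v$numeric$value, item = v))
  }
  col <- cif_loop_column(block, tag)
  if (!is.null(col)) {
    vals <- vapply(col, cif_numeric, numeric(1L))
    if (anyNA(vals)) return(list(found = TRUE, value = NULL, item = NULL))
    return(list(found = TRUE, value = vals, item = NULL))
  }
  list(found = FALSE)
}

underivable_error <- function(tag, leaves) {
  stop(structure(
    class = c("cifsem_underivable", "error", "condition"),
    list(message = sprintf(
      "%s cannot be derived; missing leaves: %s",
      tag, paste(sort(unique(leaves)), collapse = ", ")),
      call = NULL, tag = tag, leaves = sort(unique(leaves)))))
}

#' Derive a data item, stored values taking precedence
#'
#' Resolves a tag against a block: a stored value (item or loop column) is
#' always returned as-is; otherwise, if a method is registered for the tag
#' and every input is resolvable (recursively, stored-first), the value is
#' computed.  Evaluation is memoised within the call, and repeated
#' derivation of the same block is deterministic.
#'
#' @param block A [cif_block].
#' @param tag Tag to resolve.
#' @param graph A `derivation_graph`.
#' @return A list with components `value` (a [cif_value] for scalars, or a
#'   list of them for derived loop columns), `numeric` (the numeric
#'   content), `provenance` (`"stored"` or `"derived"`) and, for derived
#'   values, `inputs` (the input tags used).
#' @export
derive_item <- function(block, tag, graph) {
  stopifnot(inherits(block, "cif_block"), inherits(graph, "derivation_graph"))
  memo <- new.env(parent = emptyenv())

  resolve <- function(t) {
    key <- tolower(t)
    if (exists(key, envir = memo, inherits = FALSE)) return(memo[[key]])
    st <- stored_numeric(block, t)
    res <- if (st$found) {
      list(ok = TRUE, numeric = st$value, item = st$item,
           provenance = "stored", leaves = character(0))
    } else {
      m <- get_method(graph, t)
      if (is.null(m)) {
        list(ok = FALSE, leaves = t)
      } else {
        ins <- lapply(m$inputs, resolve)
        bad <- !vapply(ins, `[[`, logical(1L), "ok")
        if (any(bad)) {
          list(ok = FALSE,
               leaves = unlist(lapply(ins[bad], `[[`, "leaves")))
        } else {
          nums <- lapply(ins, `[[`, "numeric")
          if (any(vapply(nums, is.null, logical(1L)))) {
            nn <- m$inputs[vapply(nums, is.null, logical(1L))]
            list(ok = FALSE, leaves = nn)
          } else {
            names(nums) <- m$inputs
            out <- m$compute(nums, block)
            list(ok = TRUE, numeric = out, item = NULL,
                 provenance = "derived", inputs = m$inputs,
                 leaves = character(0))
          }
        }
      }
    }
    memo[[key]] <- res
    res
  }

  res <- resolve(tag)
  if (!res$ok) underivable_error(tag, res$leaves)
  value <- if (res$provenance == "stored") {
    if (!is.null(res$item)) res$item
    else lapply(res$numeric, function(x) cif_value(format_cif_number(x)))
  } else if (length(res$numeric) == 1L) {
    cif_value(format_cif_number(res$numeric))
  } else {
    lapply(res$numeric, function(x) cif_value(format_cif_number(x)))
  }
  out <- list(value = value, numeric = res$numeric,
              provenance = res$provenance)
  if (res$provenance == "derived") out$inputs <- res$inputs
  out
}

#' Cross-check stored values against their derivations
#'
#' For every tag that is both stored in the block and derivable from the
#' registered methods (with the stored value itself set aside), reports
#' pairs whose relative discrepancy exceeds `rel_tol`.  Stored values are
#' never modified: conflicts are reported, not resolved.
#'
#' @param block A [cif_block].
#' @param graph A `derivation_graph`.
#' @param rel_tol Positive relative tolerance (default `1e-6`).
#' @return A data frame with columns `tag`, `stored`, `derived` and
#'   `rel_discrepancy`, one row per conflicting tag (zero rows when all
#'   stored values are consistent).
#' @export
check_consistency <- function(block, graph, rel_tol = 1e-6) {
  stopifnot(rel_tol > 0)
  out <- data.frame(tag = character(0), stored = numeric(0),
                    derived = numeric(0), rel_discrepancy = numeric(0))
  for (key in names(graph$methods)) {
    m <- graph$methods[[key]]
    st <- stored_numeric(block, m$output)
    if (!st$found || is.null(st$value)) next
    hidden <- cif_remove(block, m$output)
    der <- tryCatch(derive_item(hidden, m$output, graph),
                    cifsem_underivable = function(e) NULL)
    if (is.null(der)) next
    if (length(der$numeric) != length(st$value)) next
    denom <- pmax(abs(der$numeric), .Machine$double.eps)
    disc <- abs(st$value - der$numeric) / denom
    i <- which.max(disc)
    if (disc[[i]] > rel_tol) {
      out <- rbind(out, data.frame(
        tag = m$output, stored = st$value[[i]], derived = der$numeric[[i]],
        rel_discrepancy = disc[[i]]))
    }
  }
  out[order(out$tag), , drop = FALSE]
}

#' Default derivation methods
#'
#' Returns a graph preloaded with the package's standard rules:
#' * `_cell_volume` from the six cell parameters,
#' * `_cell_reciprocal_length_a|b|c` from cell edges, angles and the
#'   (possibly itself derived) `_cell_volume`,
#' * `_exptl_crystal_density_diffrn` from formula weight, Z and volume
#'   (`1.66053907 * FW * Z / V`, grams per cubic centimetre),
#' * `_refln_F_calc` - structure-factor moduli for the `_refln_index_h|k|l`
#'   loop, summed over the symmetry-expanded atom sites with
#'   electron-count scattering factors.
#'
#' Standard uncertainties are not propagated through derivations.
#'
#' @return A `derivation_graph`.
#' @export
default_methods <- function() {
  g <- derivation_graph()
  cell_tags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                 "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  cell_of <- function(v) unit_cell(v[[1L]], v[[2L]], v[[3L]],
                                   v[[4L]], v[[5L]], v[[6L]])
  g <- register_method(g, cif_method(
    "_cell_volume", cell_tags,
    function(v, block) cell_volume(cell_of(v))))
  recip <- function(idx) {
    # a* = b c sin(alpha) / V and cyclic permutations
    len <- cell_tags[setdiff(1:3, idx)]
    ang <- cell_tags[3L + idx]
    cif_method(
      paste0("_cell_reciprocal_length_", letters[idx]),
      c(len, ang, "_cell_volume"),
      function(v, block)
        v[[len[1L]]] * v[[len[2L]]] * sin(deg2rad(v[[ang]])) /
          v[["_cell_volume"]])
  }
  for (i in 1:3) g <- register_method(g, recip(i))
  g <- register_method(g, cif_method(
    "_exptl_crystal_density_diffrn",
    c("_chemical_formula_weight", "_cell_formula_units_Z", "_cell_volume"),
    function(v, block)
      1.66053907 * v[["_chemical_formula_weight"]] *
        v[["_cell_formula_units_Z"]] / v[["_cell_volume"]]))
  g <- register_method(g, cif_method(
    "_refln_F_calc",
    c("_refln_index_h", "_refln_index_k", "_refln_index_l"),
    function(v, block) {
      st <- structure_from_block(block)
      f <- electron_counts()
      h <- v[["_refln_index_h"]]; k <- v[["_refln_index_k"]]
      l <- v[["_refln_index_l"]]
      vapply(seq_along(h), function(i)
        Mod(structure_factor(c(h[[i]], k[[i]], l[[i]]),
                             st$sites, st$ops, f)), numeric(1L))
    }))
  g
}

#' Electron counts used as constant scattering factors
#' @return Named numeric vector (element symbol to atomic number).
#' @export
electron_counts <- function() {
  c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35)
}
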