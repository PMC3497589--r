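#' Covalent radii (single-bond, angstrom)
#'
#' Standard single-bond covalent radii for the light elements handled by
#' the toolkit (values of Cordero and co-workers).  Bond perception treats
#' two atoms as bonded when their separation does not exceed the sum of
#' their covalent radii plus a tolerance.
#'
#' @return Named numeric vector mapping element symbol to radius.
#' @export
covalent_radii <- function() {
  c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20)
}

# minimum-image Cartesian distance between fractional positions, searching
# the 27 neighbouring cells (safe for strongly oblique cells)
min_image_distance <- function(M, dx) {
  base <- dx - round(dx)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    v <- M %*% (base + c(i, j, k))
    d <- sqrt(sum(v * v))
    if (d < best) best <- d
  }
  best
}

# should a bond between two sites be suppressed by the disorder model?
cross_disorder <- function(s1, s2) {
  g1 <- s1$disorder_group; g2 <- s2$disorder_group
  if (is.na(g1) || is.na(g2) || g1 == g2) return(FALSE)
  a1 <- s1$disorder_assembly; a2 <- s2$disorder_assembly
  # differing groups conflict within one assembly; an absent assembly label
  # on both sides means the default (same) assembly
  (is.na(a1) && is.na(a2)) || (!is.na(a1) && !is.na(a2) && a1 == a2)
}

#' Infer chemical bonds from crystallographic coordinates
#'
#' Two sites are bonded when their minimum-image distance (and, when
#' `expand_symmetry` is set, their distance to any symmetry image within
#' one shell of neighbouring cells) does not exceed the sum of their
#' covalent radii plus `tol`.  Bonds between different disorder groups of
#' the same assembly are suppressed - such sites are alternative locations
#' of the same atoms, not neighbours.  All inferred bond orders are
#' `"unassigned"`: order assignment is an explicit editing step for the
#' author, not something coordinates alone can decide.
#'
#' @param cell A [unit_cell].
#' @param sites List of [atom_site] objects.
#' @param radii Named radius table, see [covalent_radii()].
#' @param tol Distance tolerance in angstrom (default 0.40).
#' @param expand_symmetry Also consider symmetry images of each site.
#' @param ops Symmetry operators (used only when `expand_symmetry`).
#' @return A `connectivity_graph`: list with `atoms` (the sites) and
#'   `bonds` (each a list with `atom1`, `atom2`, `length`, `order`).
#' @export
infer_bonds <- function(cell, sites, radii = covalent_radii(), tol = 0.40,
                        expand_symmetry = FALSE, ops = list()) {
  stopifnot(inherits(cell, "unit_cell"), tol >= 0)
  elems <- vapply(sites, `[[`, "", "element")
  missing <- setdiff(unique(elems), names(radii))
  if (length(missing))
    stop("no covalent radius for element(s): ",
         paste(missing, collapse = ", "))
  M <- orthogonalization(cell)
  n <- length(sites)
  bonds <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      si <- sites[[i]]; sj <- sites[[j]]
      if (cross_disorder(si, sj)) next
      limit <- radii[[si$element]] + radii[[sj$element]] + tol
      d <- min_image_distance(M, si$frac - sj$frac)
      if (expand_symmetry && length(ops)) {
        for (op in ops) {
          if (is_identity_op(op)) next
          d <- min(d, min_image_distance(M, si$frac - apply_symop(op, sj$frac)))
        }
      }
      if (d <= limit) {
        bonds[[length(bonds) + 1L]] <-
          list(atom1 = si$label, atom2 = sj$label,
               length = d, order = "unassigned")
      }
    }
  }
  structure(list(atoms = sites, bonds = bonds), class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph: %d atoms, %d bonds>\n",
              length(x$atoms), length(x$bonds)))
  invisible(x)
}

#' Split a connectivity graph into moieties
#'
#' Moieties are the connected components of the bond graph: discrete
#' molecules or ions.  Components are ordered largest first, ties broken by
#' the lexically smallest atom label.
#'
#' @param graph A `connectivity_graph`.
#' @return A list of components, each a list of [atom_site] objects.
#' @export
moieties <- function(graph) {
  labels <- vapply(graph$atoms, `[[`, "", "label")
  if (length(labels) == 0L) return(list())
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  if (length(graph$bonds)) {
    edges <- unlist(lapply(graph$bonds, function(b) c(b$atom1, b$atom2)))
    g <- igraph::add_edges(g, match(edges, labels))
  }
  comp <- igraph::components(g)$membership
  groups <- split(seq_along(labels), comp)
  key <- vapply(groups, function(ix) min(labels[ix]), "")
  ord <- order(-lengths(groups), key)
  lapply(groups[ord], function(ix) graph$atoms[ix])
}

#' Molecular formula of a component (Hill order)
#'
#' Occupancy-weighted atom counts rounded to the nearest integer, written
#' carbon first, hydrogen second, remaining elements alphabetically, with
#' single-space separation (`"C H4"`, `"Cl O4"`).  Elements whose rounded
#' count is zero are omitted.
#'
#' @param component A list of [atom_site] objects (one moiety).
#' @return A formula string (empty for an empty component).
#' @export
molecular_formula <- function(component) {
  if (length(component) == 0L) return("")
  el <- vapply(component, `[[`, "", "element")
  occ <- vapply(component, `[[`, numeric(1L), "occupancy")
  counts <- round(tapply(occ, el, sum))
  counts <- counts[counts >= 1]
  if (length(counts) == 0L) return("")
  nm <- names(counts)
  ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  counts <- counts[ord]
  paste(ifelse(counts == 1L, names(counts),
               paste0(names(counts), counts)), collapse = " ")
}

conn_order_to_cif <- function(order) {
  switch(order, single = "sing", double = "doub", triple = "trip",
         unassigned = "?",
         stop("unknown bond order '", order, "'"))
}

conn_order_from_cif <- function(v) {
  if (v$kind == "unknown") return("unassigned")
  switch(v$raw, sing = "single", doub = "double", trip = "triple",
         stop("unknown connection-table bond type '", v$raw, "'"))
}

#' Write and read the chemical connection table of a block
#'
#' Serialises a connectivity graph to the core chemical-connectivity
#' loops: `_chemical_conn_atom_number`, `_chemical_conn_atom_label`,
#' `_chemical_conn_atom_type_symbol` for atoms, and
#' `_chemical_conn_bond_atom_1`, `_chemical_conn_bond_atom_2`,
#' `_chemical_conn_bond_type` for bonds (atoms referenced by number,
#' unassigned orders written as `?`).  An existing connection table is
#' replaced with a warning.  `read_connection_table` inverts the mapping;
#' the round trip is the identity on labels, bonds and orders.
#'
#' @param block A [cif_block].
#' @param graph A `connectivity_graph`.
#' @return `write_connection_table` returns the updated block;
#'   `read_connection_table` a `connectivity_graph` (atom coordinates are
#'   not part of the connection table and come back as `NA`).
#' @export
write_connection_table <- function(block, graph) {
  labels <- vapply(graph$atoms, `[[`, "", "label")
  for (b in graph$bonds) {
    if (!(b$atom1 %in% labels) || !(b$atom2 %in% labels))
      stop("bond cites unknown atom label: ", b$atom1, "-", b$atom2)
  }
  has_conn <- function(lp) any(startsWith(tolower(lp$tags), "_chemical_conn_"))
  if (any(vapply(block$loops, has_conn, logical(1L)))) {
    warning("replacing existing connection table in block '",
            block$name, "'")
    block$loops <- Filter(function(lp) !has_conn(lp), block$loops)
  }
  if (length(graph$atoms) == 0L) return(block)
  atom_rows <- lapply(seq_along(graph$atoms), function(i) {
    s <- graph$atoms[[i]]
    list(cif_value(as.character(i)), cif_value(s$label),
         cif_value(s$element))
  })
  block$loops[[length(block$loops) + 1L]] <- cif_loop(
    c("_chemical_conn_atom_number", "_chemical_conn_atom_label",
      "_chemical_conn_atom_type_symbol"), atom_rows)
  if (length(graph$bonds)) {
    bond_rows <- lapply(graph$bonds, function(b) {
      list(cif_value(as.character(match(b$atom1, labels))),
           cif_value(as.character(match(b$atom2, labels))),
           cif_value(conn_order_to_cif(b$order)))
    })
    block$loops[[length(block$loops) + 1L]] <- cif_loop(
      c("_chemical_conn_bond_atom_1", "_chemical_conn_bond_atom_2",
        "_chemical_conn_bond_type"), bond_rows)
  }
  block
}

#' @rdname write_connection_table
#' @export
read_connection_table <- function(block) {
  nums <- cif_loop_column(block, "_chemical_conn_atom_number")
  if (is.null(nums))
    return(structure(list(atoms = list(), bonds = list()),
                     class = "connectivity_graph"))
  labs <- cif_loop_column(block, "_chemical_conn_atom_label")
  syms <- cif_loop_column(block, "_chemical_conn_atom_type_symbol")
  n <- length(nums)
  order_of <- integer(n)
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    num <- as.integer(cif_numeric(nums[[i]]))
    order_of[num] <- i
    atoms[[num]] <- atom_site(label = labs[[i]]$raw, element = syms[[i]]$raw,
                              frac = rep(NA_real_, 3L))
  }
  labels <- vapply(atoms, `[[`, "", "label")
  bonds <- list()
  b1 <- cif_loop_column(block, "_chemical_conn_bond_atom_1")
  if (!is.null(b1)) {
    b2 <- cif_loop_column(block, "_chemical_conn_bond_atom_2")
    bt <- cif_loop_column(block, "_chemical_conn_bond_type")
    for (i in seq_along(b1)) {
      i1 <- as.integer(cif_numeric(b1[[i]]))
      i2 <- as.integer(cif_numeric(b2[[i]]))
      if (is.na(i1) || is.na(i2) || i1 > length(labels) || i2 > length(labels))
        stop("connection-table bond cites an unknown atom number")
      bonds[[length(bonds) + 1L]] <-
        list(atom1 = labels[[i1]], atom2 = labels[[i2]],
             length = NA_real_,
             order = if (is.null(bt)) "unassigned"
                     else conn_order_from_cif(bt[[i]]))
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "connectivity_graph")
}
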