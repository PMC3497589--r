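#' Read crystallographic model components from a data block
#'
#' These readers use the core CIF tag spellings adopted throughout this
#' package: `_cell_length_a|b|c` and `_cell_angle_alpha|beta|gamma` for the
#' cell; a `_symmetry_equiv_pos_as_xyz` loop (or the newer
#' `_space_group_symop_operation_xyz`) for symmetry operators; and the
#' `_atom_site_*` loop (label, type_symbol, fract_x/y/z, occupancy,
#' U_iso_or_equiv, disorder_assembly, disorder_group) plus the
#' `_atom_site_aniso_*` loop (label, U_11, U_22, U_33, U_12, U_13, U_23)
#' for the sites.
#'
#' @param block A [cif_block].
#' @return `cell_from_block` returns a [unit_cell]; `symops_from_block` a
#'   list of `symop` (the identity alone when no symmetry loop is present);
#'   `sites_from_block` a list of [atom_site]; `structure_from_block` a list
#'   with components `cell`, `ops`, `sites`.
#' @name structure-readers
NULL

#' @rdname structure-readers
#' @export
cell_from_block <- function(block) {
  tags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  vals <- vapply(tags, function(t) cif_get_num(block, t), numeric(1L))
  if (anyNA(vals))
    stop("block '", block$name, "' is missing or has non-numeric cell tags: ",
         paste(tags[is.na(vals)], collapse = ", "))
  unit_cell(vals[1L], vals[2L], vals[3L], vals[4L], vals[5L], vals[6L])
}

#' @rdname structure-readers
#' @export
symops_from_block <- function(block) {
  col <- cif_loop_column(block, "_symmetry_equiv_pos_as_xyz")
  if (is.null(col))
    col <- cif_loop_column(block, "_space_group_symop_operation_xyz")
  if (is.null(col)) {
    v <- cif_get(block, "_symmetry_equiv_pos_as_xyz")
    if (!is.null(v)) col <- list(v)
  }
  if (is.null(col)) return(list(symop_identity()))
  lapply(col, function(v) parse_symop(v$raw))
}

#' @rdname structure-readers
#' @export
sites_from_block <- function(block) {
  labels <- cif_loop_column(block, "_atom_site_label")
  if (is.null(labels)) stop("block '", block$name, "' has no _atom_site_ loop")
  n <- length(labels)
  col <- function(tag) cif_loop_column(block, tag)
  num_col <- function(tag) {
    x <- col(tag)
    if (is.null(x)) return(rep(NA_real_, n))
    vapply(x, cif_numeric, numeric(1L))
  }
  chr_col <- function(tag) {
    x <- col(tag)
    if (is.null(x)) return(rep(NA_character_, n))
    vapply(x, function(v)
      if (v$kind %in% c("unknown", "inapplicable")) NA_character_ else v$raw,
      character(1L))
  }
  elem <- chr_col("_atom_site_type_symbol")
  fx <- num_col("_atom_site_fract_x")
  fy <- num_col("_atom_site_fract_y")
  fz <- num_col("_atom_site_fract_z")
  occ <- num_col("_atom_site_occupancy")
  uiso <- num_col("_atom_site_U_iso_or_equiv")
  dass <- chr_col("_atom_site_disorder_assembly")
  dgrp <- num_col("_atom_site_disorder_group")
  if (anyNA(c(fx, fy, fz)))
    stop("block '", block$name, "' has missing fractional coordinates")

  # anisotropic displacement loop, matched by label
  aniso <- list()
  alab <- col("_atom_site_aniso_label")
  if (!is.null(alab)) {
    comp <- lapply(c("_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
                     "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
                     "_atom_site_aniso_U_13", "_atom_site_aniso_U_23"),
                   num_col_of <- function(tag) {
                     x <- col(tag)
                     if (is.null(x)) stop("incomplete aniso loop: missing ", tag)
                     vapply(x, cif_numeric, numeric(1L))
                   })
    for (i in seq_along(alab)) {
      u <- vapply(comp, `[[`, numeric(1L), i)
      U <- matrix(c(u[1L], u[4L], u[5L],
                    u[4L], u[2L], u[6L],
                    u[5L], u[6L], u[3L]), 3L, 3L)
      aniso[[alab[[i]]$raw]] <- U
    }
  }

  labs <- vapply(labels, `[[`, "", "raw")
  if (anyDuplicated(labs)) stop("duplicate atom site labels")
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    el <- elem[[i]]
    if (is.na(el)) el <- gsub("[^A-Za-z].*$", "", labs[[i]])
    sites[[i]] <- atom_site(
      label = labs[[i]],
      element = el,
      frac = c(fx[[i]], fy[[i]], fz[[i]]),
      occupancy = if (is.na(occ[[i]])) 1 else occ[[i]],
      u_iso = if (is.na(uiso[[i]])) NULL else uiso[[i]],
      u_aniso = aniso[[labs[[i]]]],
      disorder_group = if (is.na(dgrp[[i]])) NA_integer_
                       else as.integer(dgrp[[i]]),
      disorder_assembly = dass[[i]]
    )
  }
  sites
}

#' @rdname structure-readers
#' @export
structure_from_block <- function(block) {
  list(cell = cell_from_block(block),
       ops = symops_from_block(block),
       sites = sites_from_block(block))
}

#' Reciprocal cell edge lengths
#'
#' `a* = b c sin(alpha) / V` and cyclic permutations; units 1/angstrom.
#'
#' @param cell A [unit_cell].
#' @return Named numeric vector `c(a_star, b_star, c_star)`.
#' @export
reciprocal_lengths <- function(cell) {
  V <- cell_volume(cell)
  c(a_star = cell$b * cell$c * sin(deg2rad(cell$alpha)) / V,
    b_star = cell$a * cell$c * sin(deg2rad(cell$beta)) / V,
    c_star = cell$a * cell$b * sin(deg2rad(cell$gamma)) / V)
}

#' Transform a CIF-convention ADP tensor to Cartesian axes
#'
#' Anisotropic displacement parameters in CIF files are referred to the
#' reciprocal basis (the dimensionless `U^ij` convention).  The Cartesian
#' tensor is the similarity transform `U_cart = (A N) U (A N)^T` where `A`
#' is the [orthogonalization()] matrix and `N = diag(a*, b*, c*)`.  For an
#' orthogonal cell this reduces to the identity transform.
#'
#' @param cell A [unit_cell].
#' @param u_aniso Symmetric 3x3 CIF-convention tensor (A^2).
#' @return The symmetric 3x3 Cartesian tensor (A^2).
#' @export
u_cif_to_cartesian <- function(cell, u_aniso) {
  U <- as.matrix(u_aniso)
  stopifnot(all(dim(U) == c(3L, 3L)))
  if (max(abs(U - t(U))) > 1e-8)
    stop("u_aniso must be symmetric")
  A <- orthogonalization(cell)
  N <- diag(reciprocal_lengths(cell))
  X <- A %*% N %*% U %*% N %*% t(A)
  (X + t(X)) / 2
}

# inverse transform: Cartesian tensor -> CIF convention
u_cartesian_to_cif <- function(cell, u_cart) {
  A <- orthogonalization(cell)
  Ninv <- diag(1 / reciprocal_lengths(cell))
  Ainv <- solve(A)
  X <- Ninv %*% Ainv %*% u_cart %*% t(Ainv) %*% Ninv
  (X + t(X)) / 2
}
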