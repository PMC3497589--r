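#' Unit cell
#'
#' Triclinic unit-cell parameters: three edge lengths in angstroms and three
#' inter-axial angles in degrees.  Construction checks that the implied
#' metric tensor is positive definite (i.e. the six numbers describe a real
#' parallelepiped).
#'
#' @param a,b,c Cell edge lengths (angstrom), all positive.
#' @param alpha,beta,gamma Cell angles (degrees), each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(10, 10, 10, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a, b, c, alpha, beta, gamma)
  stopifnot(length(vals) == 6L, all(is.finite(vals)))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (volume_factor(cell) <= 0)
    stop("cell metric is not positive definite")
  cell
}

deg2rad <- function(x) x * pi / 180

# sqrt(1 - ca^2 - cb^2 - cg^2 + 2 ca cb cg); <= 0 marks a degenerate metric
volume_factor <- function(cell) {
  ca <- cos(deg2rad(cell$alpha))
  cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(arg)
  sqrt(arg)
}

#' Unit-cell volume
#'
#' `V = abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'  + 2 cos(alpha) cos(beta) cos(gamma))`.
#'
#' @param cell A [unit_cell].
#' @return Volume in cubic angstroms.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  vf <- volume_factor(cell)
  if (vf <= 0) stop("cell metric is not positive definite")
  cell$a * cell$b * cell$c * vf
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Returns the 3x3 matrix `M` mapping fractional coordinates to Cartesian
#' angstroms under the common crystallographic convention: the `a` axis
#' along Cartesian x and `b` in the xy plane.  `det(M)` equals the cell
#' volume and `M %*% c(1,0,0)` has length `a`.
#'
#' @param cell A [unit_cell].
#' @return A 3x3 numeric matrix.
#' @export
orthogonalization <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(deg2rad(cell$alpha))
  cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  sg <- sin(deg2rad(cell$gamma))
  vf <- volume_factor(cell)
  if (vf <= 0) stop("cell metric is not positive definite")
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * vf / sg
  ), nrow = 3L, byrow = TRUE)
}

#' Convert fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell].
#' @param x Fractional coordinates: a length-3 vector or an n-by-3 matrix.
#' @return Cartesian coordinates (angstrom) of the same shape.
#' @export
frac_to_cart <- function(cell, x) {
  M <- orthogonalization(cell)
  if (is.matrix(x)) t(M %*% t(x)) else drop(M %*% x)
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Interatomic distance, angle and torsion from fractional coordinates
#'
#' All three measures are evaluated on the Cartesian images of the supplied
#' fractional coordinates exactly as given - no symmetry expansion and no
#' minimum-image wrapping is applied.  The torsion angle follows the IUPAC
#' right-hand sign convention and lies in (-180, 180].
#'
#' @param cell A [unit_cell].
#' @param x1,x2,x3,x4 Fractional coordinate vectors (length 3).
#' @return `cif_distance` returns angstroms; `cif_angle` and `cif_torsion`
#'   return degrees.
#' @export
cif_distance <- function(cell, x1, x2) {
  vnorm(frac_to_cart(cell, x2) - frac_to_cart(cell, x1))
}

#' @rdname cif_distance
#' @export
cif_angle <- function(cell, x1, x2, x3) {
  p1 <- frac_to_cart(cell, x1)
  p2 <- frac_to_cart(cell, x2)
  p3 <- frac_to_cart(cell, x3)
  u <- p1 - p2
  v <- p3 - p2
  if (vnorm(u) < 1e-12 || vnorm(v) < 1e-12)
    stop("coincident points: angle is undefined")
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' @rdname cif_distance
#' @export
cif_torsion <- function(cell, x1, x2, x3, x4) {
  p <- lapply(list(x1, x2, x3, x4), function(x) frac_to_cart(cell, x))
  b1 <- p[[2L]] - p[[1L]]
  b2 <- p[[3L]] - p[[2L]]
  b3 <- p[[4L]] - p[[3L]]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12)
    stop("collinear points: torsion is undefined")
  u2 <- b2 / vnorm(b2)
  ang <- atan2(sum(cross3(n1, n2) * u2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Symmetry operators as coordinate triplets
#'
#' A space-group symmetry operation is represented by a 3x3 rotation part
#' (integer or simple-fraction entries, determinant +/-1) and a translation
#' vector with components reduced mod 1 into \code{[0, 1)}.  `parse_symop`
#' reads the conventional `"x,y,z"`-style triplet (terms in x, y, z plus
#' rational or decimal constants); `format_symop` writes it back so that
#' `parse_symop(format_symop(op))` is the identity.
#'
#' @param text A coordinate triplet such as `"-x,y+1/2,-z+1/2"`.
#' @return A `symop` object with fields `rot` (3x3 matrix) and `trans`
#'   (length-3 vector).
#' @export
parse_symop <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(gsub("[ \t]", "", text), ",", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || any(!nzchar(parts)))
    parse_error(paste0("malformed symmetry triplet: '", text, "'"))
  rot <- matrix(0, 3L, 3L)
  trans <- numeric(3L)
  term_re <- "([+-]?)(?:([0-9]+)/([0-9]+)|([0-9]*\\.?[0-9]+))?([xyzXYZ])?"
  for (i in 1:3) {
    s <- parts[[i]]
    pos <- 1L
    nc <- nchar(s)
    while (pos <= nc) {
      m <- regexpr(paste0("^", term_re), substring(s, pos), perl = TRUE)
      frag <- regmatches(substring(s, pos),
                         regexec(paste0("^", term_re), substring(s, pos),
                                 perl = TRUE))[[1L]]
      if (m == -1L || attr(m, "match.length") == 0L)
        parse_error(paste0("malformed symmetry triplet: '", text, "'"))
      sign <- if (identical(frag[2L], "-")) -1 else 1
      coef <- if (nzchar(frag[3L])) {
        as.numeric(frag[3L]) / as.numeric(frag[4L])
      } else if (nzchar(frag[5L])) {
        as.numeric(frag[5L])
      } else NA_real_
      var <- frag[6L]
      if (nzchar(var)) {
        j <- match(tolower(var), c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + sign * (if (is.na(coef)) 1 else coef)
      } else if (!is.na(coef)) {
        trans[i] <- trans[i] + sign * coef
      } else {
        parse_error(paste0("malformed symmetry triplet: '", text, "'"))
      }
      pos <- pos + attr(m, "match.length")
    }
  }
  trans <- trans %% 1
  op <- structure(list(rot = rot, trans = trans), class = "symop")
  if (abs(abs(det(rot)) - 1) > 1e-9)
    parse_error(paste0("rotation part of '", text, "' has |det| != 1"))
  op
}

# express t as "n/d" with the smallest denominator <= 24, or a decimal
format_fraction <- function(t) {
  for (d in 1:24) {
    n <- round(t * d)
    if (abs(t - n / d) < 1e-9) {
      if (d == 1L) return(as.character(n))
      return(paste0(n, "/", d))
    }
  }
  format(t, digits = 10)
}

#' @rdname parse_symop
#' @param op A `symop`.
#' @export
format_symop <- function(op) {
  stopifnot(inherits(op, "symop"))
  vars <- c("x", "y", "z")
  rows <- character(3L)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rot[i, j]
      if (abs(r) < 1e-12) next
      sgn <- if (r < 0) "-" else if (nzchar(s)) "+" else ""
      coef <- if (abs(abs(r) - 1) < 1e-12) "" else format_fraction(abs(r))
      s <- paste0(s, sgn, coef, vars[j])
    }
    t <- op$trans[i] %% 1
    if (abs(t) > 1e-12 && abs(t - 1) > 1e-12) {
      s <- paste0(s, if (nzchar(s)) "+" else "", format_fraction(t))
    }
    if (!nzchar(s)) s <- "0"
    rows[i] <- s
  }
  paste(rows, collapse = ",")
}

#' @export
print.symop <- function(x, ...) {
  cat("<symop ", format_symop(x), ">\n", sep = "")
  invisible(x)
}

symop_identity <- function() {
  structure(list(rot = diag(3), trans = numeric(3L)), class = "symop")
}

is_identity_op <- function(op, tol = 1e-9) {
  max(abs(op$rot - diag(3))) < tol &&
    max(abs(op$trans - round(op$trans))) < tol
}

apply_symop <- function(op, x) drop(op$rot %*% x) + op$trans

# minimum-image separation (fractional metric) between fractional positions
min_image_frac <- function(p, q) {
  d <- p - q
  vnorm(d - round(d))
}

#' Symmetry orbit of a site
#'
#' Applies every operator to the fractional position, reduces mod 1, and
#' merges images closer than `tol` under the minimum-image fractional
#' metric.  The orbit size is the site multiplicity: atoms on special
#' positions (sites through which a symmetry operation passes) have smaller
#' orbits, and the orbit size always divides the number of operators when
#' they form a group.
#'
#' @param ops List of `symop` objects; must contain the identity.
#' @param x Fractional coordinates (length 3).
#' @param tol Special-position tolerance in fractional units (default 1e-4).
#' @return A matrix with one distinct orbit position per row.
#' @export
site_orbit <- function(ops, x, tol = 1e-4) {
  stopifnot(length(ops) >= 1L, tol > 0)
  if (!any(vapply(ops, is_identity_op, logical(1L))))
    stop("operator list does not contain the identity")
  kept <- list()
  for (op in ops) {
    p <- apply_symop(op, x) %% 1
    dup <- FALSE
    for (q in kept) {
      if (min_image_frac(p, q) <= tol) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  do.call(rbind, kept)
}

#' Site multiplicity under an operator list
#' @inheritParams site_orbit
#' @export
site_multiplicity <- function(ops, x, tol = 1e-4) nrow(site_orbit(ops, x, tol))

#' Atom site
#'
#' A fractional atom site with optional displacement and disorder metadata.
#' `u_aniso` uses the CIF convention (components referred to the reciprocal
#' basis, in square angstroms).
#'
#' @param label Unique site label, e.g. `"C1"`.
#' @param element Element symbol.
#' @param frac Fractional coordinates (length 3).
#' @param occupancy Site occupancy in (0, 1].
#' @param u_iso Optional isotropic displacement parameter (A^2).
#' @param u_aniso Optional symmetric 3x3 CIF-convention tensor (A^2).
#' @param disorder_group Optional integer disorder group.
#' @param disorder_assembly Optional disorder assembly identifier.
#' @return An `atom_site` object.
#' @export
atom_site <- function(label, element, frac, occupancy = 1,
                      u_iso = NULL, u_aniso = NULL,
                      disorder_group = NA_integer_,
                      disorder_assembly = NA_character_) {
  stopifnot(is.character(label), length(frac) == 3L,
            occupancy > 0, occupancy <= 1)
  if (!is.null(u_aniso)) {
    u_aniso <- as.matrix(u_aniso)
    stopifnot(all(dim(u_aniso) == c(3L, 3L)))
  }
  structure(list(label = label, element = element, frac = as.numeric(frac),
                 occupancy = occupancy, u_iso = u_iso, u_aniso = u_aniso,
                 disorder_group = disorder_group,
                 disorder_assembly = disorder_assembly),
            class = "atom_site")
}

#' Structure-factor summation
#'
#' `F(hkl) = sum over symmetry-expanded, occupancy-weighted atoms of
#' f(element) * exp(2 pi i h.x)`.  Scattering factors are constants per
#' element (no angle dependence) and no displacement damping is applied;
#' symmetry expansion uses [site_orbit()] so atoms on special positions are
#' not double counted.
#'
#' @param hkl Integer reflection indices (length 3).
#' @param sites List of [atom_site] objects.
#' @param ops List of `symop` objects (must contain the identity).
#' @param f Named numeric vector or list mapping element symbol to a
#'   scattering factor.
#' @param tol Special-position tolerance passed to [site_orbit()].
#' @return A complex scalar.
#' @export
structure_factor <- function(hkl, sites, ops = list(symop_identity()),
                             f, tol = 1e-4) {
  stopifnot(length(hkl) == 3L)
  f <- unlist(f)
  F <- complex(real = 0, imaginary = 0)
  for (s in sites) {
    if (!(s$element %in% names(f)))
      stop("no scattering factor for element ", s$element)
    orbit <- site_orbit(ops, s$frac, tol)
    phase <- exp(2i * pi * drop(orbit %*% hkl))
    F <- F + s$occupancy * f[[s$element]] * sum(phase)
  }
  F
}
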