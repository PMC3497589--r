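#' Fixture specification
#'
#' Describes a deterministic toy structure: a small alcohol-like organic
#' molecule (a carbon chain with a terminal hydroxyl and full hydrogen
#' complement) plus an unbonded chloride counter-ion, built at ideal
#' covalent geometry inside a triclinic cell large enough that periodic
#' images never touch.  `n_atoms` is a size hint - the chain is grown to
#' roughly that many atoms; the molecule always has at least four carbons
#' so a torsion table exists.
#'
#' @param seed Integer seed; the same seed always yields a byte-identical
#'   CIF.
#' @param n_atoms Approximate atom count (>= 1).
#' @param symmetry `"P1"` (identity only) or `"P-1"` (identity +
#'   inversion).
#' @param disorder Split the hydroxyl over a two-group disorder assembly.
#' @param defects Character vector of defect codes for [inject_defect()].
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_atoms = 12L,
                         symmetry = c("P1", "P-1"),
                         disorder = FALSE, defects = character(0)) {
  symmetry <- match.arg(symmetry)
  stopifnot(n_atoms >= 1L)
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 symmetry = symmetry, disorder = isTRUE(disorder),
                 defects = defects),
            class = "fixture_spec")
}

# evaluate expr under a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# place atom d so that |cd| = dist, angle(b,c,d) = ang (deg) and
# torsion(a,b,c,d) = tor (deg)
place_atom <- function(a, b, c, dist, ang, tor) {
  ang <- deg2rad(ang); tor <- deg2rad(tor)
  bc <- (c - b); bc <- bc / vnorm(bc)
  ab <- (b - a)
  n <- cross3(ab, bc); n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-dist * cos(ang), dist * sin(ang) * cos(tor),
         dist * sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

unit_perp <- function(u) {
  v <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- cross3(u, v)
  p / vnorm(p)
}

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   Cl = 35.45)

# build the toy molecule in Cartesian coordinates; returns a data frame
# label/element/x/y/z/occ/assembly/group
build_molecule <- function(spec) {
  nC <- max(3L, as.integer(round(spec$n_atoms / 3)))
  pos <- list(); lab <- character(0); el <- character(0)
  occ <- numeric(0); asm <- character(0); grp <- integer(0)
  add <- function(label, element, p, o = 1, a = NA_character_,
                  g = NA_integer_) {
    pos[[length(pos) + 1L]] <<- p
    lab <<- c(lab, label); el <<- c(el, element)
    occ <<- c(occ, o); asm <<- c(asm, a); grp <<- c(grp, g)
  }
  cc <- 1.52; co <- 1.43; ch <- 1.09; oh <- 0.96
  C <- list(c(0, 0, 0), c(cc, 0, 0))
  C[[3L]] <- C[[2L]] + cc * c(-cos(deg2rad(111)), sin(deg2rad(111)), 0)
  if (nC >= 4L) {
    for (i in 4:nC) {
      C[[i]] <- place_atom(C[[i - 3L]], C[[i - 2L]], C[[i - 1L]],
                           cc, 111, 180 + stats::runif(1, -8, 8))
    }
  }
  for (i in seq_len(nC)) add(paste0("C", i), "C", C[[i]])

  # hydroxyl oxygen on the last carbon (two orientations when disordered)
  tor0 <- 60 + stats::runif(1, -5, 5)
  O1 <- place_atom(C[[nC - 2L]], C[[nC - 1L]], C[[nC]], co, 109, tor0)
  H99 <- place_atom(C[[nC - 1L]], C[[nC]], O1, oh, 108,
                    180 + stats::runif(1, -10, 10))
  if (spec$disorder) {
    O1b <- place_atom(C[[nC - 2L]], C[[nC - 1L]], C[[nC]], co, 109,
                      tor0 + 25)
    H99b <- place_atom(C[[nC - 1L]], C[[nC]], O1b, oh, 108,
                       180 + stats::runif(1, -10, 10))
    add("O1", "O", O1, 0.5, "A", 1L)
    add("H99", "H", H99, 0.5, "A", 1L)
    add("O1'", "O", O1b, 0.5, "A", 2L)
    add("H99'", "H", H99b, 0.5, "A", 2L)
  } else {
    add("O1", "O", O1)
    add("H99", "H", H99)
  }

  # hydrogens: three on C1, two on each inner carbon, two on the last
  frame_h3 <- function(centre, u) {
    e1 <- unit_perp(u); e2 <- cross3(u, e1)
    a <- deg2rad(109.47)
    lapply(c(0, 120, 240), function(phi) {
      phi <- deg2rad(phi)
      centre + ch * (cos(a) * u + sin(a) * (cos(phi) * e1 + sin(phi) * e2))
    })
  }
  h2_pair <- function(centre, u1, u2) {
    bis <- -(u1 + u2); bis <- bis / vnorm(bis)
    p <- cross3(u1, u2); p <- p / vnorm(p)
    list(centre + ch * (bis + p) / sqrt(2),
         centre + ch * (bis - p) / sqrt(2))
  }
  unit_to <- function(from, to) { d <- to - from; d / vnorm(d) }
  hk <- 0L
  hadd <- function(p) { hk <<- hk + 1L; add(paste0("H", hk), "H", p) }
  for (p in frame_h3(C[[1L]], unit_to(C[[1L]], C[[2L]]))) hadd(p)
  if (nC >= 3L) {
    for (i in 2:(nC - 1L)) {
      for (p in h2_pair(C[[i]], unit_to(C[[i]], C[[i - 1L]]),
                        unit_to(C[[i]], C[[i + 1L]]))) hadd(p)
    }
  }
  for (p in h2_pair(C[[nC]], unit_to(C[[nC]], C[[nC - 1L]]),
                    unit_to(C[[nC]], O1))) hadd(p)

  # unbonded chloride counter-ion, well clear of the molecule
  M <- do.call(rbind, pos)
  add("Cl1", "Cl", c(max(M[, 1L]) + 4.0, mean(M[, 2L]) + 0.5,
                     mean(M[, 3L]) + 0.3))
  data.frame(label = lab, element = el,
             x = vapply(pos, `[[`, numeric(1L), 1L),
             y = vapply(pos, `[[`, numeric(1L), 2L),
             z = vapply(pos, `[[`, numeric(1L), 3L),
             occ = occ, asm = asm, grp = grp, stringsAsFactors = FALSE)
}

fmt <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

#' Generate a deterministic toy structure block
#'
#' Produces a complete, internally consistent data block: cell parameters
#' and `_cell_volume` computed from the printed (rounded) cell values, a
#' symmetry loop, an atom-site loop with a subset of anisotropic sites (and
#' a two-group disorder assembly when requested), geometry tables
#' recomputed from the printed coordinates, and formula/weight/Z items.
#' Defect-free output passes [validate_block()] against the shipped core
#' dictionary with zero violations and [run_checks()] with zero serious
#' alerts.
#'
#' @param spec A [fixture_spec].
#' @return A [cif_block].
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    mol <- build_molecule(spec)
    cart <- as.matrix(mol[, c("x", "y", "z")])

    extent <- apply(cart, 2L, function(v) diff(range(v)))
    buffer <- if (spec$symmetry == "P-1") 14 else 7
    angles <- round(c(91, 99, 95) + stats::runif(3, -3, 3), 4L)
    lengths <- round(extent + buffer, 4L)
    cell <- unit_cell(lengths[1L], lengths[2L], lengths[3L],
                      angles[1L], angles[2L], angles[3L])
    M <- orthogonalization(cell)
    frac <- t(solve(M) %*% t(cart))
    centre <- if (spec$symmetry == "P-1") c(0.25, 0.25, 0.25)
              else c(0.4, 0.4, 0.4)
    frac <- sweep(frac, 2L, colMeans(frac) - centre)
    frac <- round(frac, 6L)

    ops_xyz <- if (spec$symmetry == "P-1") c("x,y,z", "-x,-y,-z")
               else "x,y,z"

    items <- list()
    it <- function(tag, raw, quoted = FALSE)
      items[[tag]] <<- cif_value(raw, quoted = quoted)
    it("_symmetry_cell_setting", "triclinic")
    it("_cell_length_a", fmt(lengths[1L], 4L))
    it("_cell_length_b", fmt(lengths[2L], 4L))
    it("_cell_length_c", fmt(lengths[3L], 4L))
    it("_cell_angle_alpha", fmt(angles[1L], 4L))
    it("_cell_angle_beta", fmt(angles[2L], 4L))
    it("_cell_angle_gamma", fmt(angles[3L], 4L))
    it("_cell_volume", fmt(cell_volume(cell), 4L))
    it("_cell_formula_units_Z", as.character(length(ops_xyz)))

    n <- nrow(mol)
    # anisotropic tensors for the first three carbons: random orientation,
    # moderate anisotropy (axis ratio <= 3)
    aniso_labels <- mol$label[mol$element == "C"][1:3]
    aniso <- list()
    for (lb in aniso_labels) {
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
      ev <- sort(stats::runif(3, 0.015, 0.045))
      Ucart <- Q %*% diag(ev) %*% t(Q)
      aniso[[lb]] <- round(u_cartesian_to_cif(cell, Ucart), 5L)
    }
    uiso <- round(stats::runif(n, 0.03, 0.05), 4L)

    site_rows <- lapply(seq_len(n), function(i) {
      lb <- mol$label[i]
      list(cif_value(lb), cif_value(mol$element[i]),
           cif_value(fmt(frac[i, 1L], 6L)),
           cif_value(fmt(frac[i, 2L], 6L)),
           cif_value(fmt(frac[i, 3L], 6L)),
           cif_value(if (mol$occ[i] == 1) "1" else fmt(mol$occ[i], 2L)),
           cif_value(if (lb %in% aniso_labels) "." else fmt(uiso[i], 4L)),
           cif_value(if (is.na(mol$asm[i])) "." else mol$asm[i]),
           cif_value(if (is.na(mol$grp[i])) "." else
                       as.character(mol$grp[i])))
    })
    loops <- list(
      cif_loop("_symmetry_equiv_pos_as_xyz",
               lapply(ops_xyz, function(s) list(cif_value(s, quoted = TRUE)))),
      cif_loop(c("_atom_site_label", "_atom_site_type_symbol",
                 "_atom_site_fract_x", "_atom_site_fract_y",
                 "_atom_site_fract_z", "_atom_site_occupancy",
                 "_atom_site_U_iso_or_equiv",
                 "_atom_site_disorder_assembly",
                 "_atom_site_disorder_group"), site_rows),
      cif_loop(c("_atom_site_aniso_label",
                 "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
                 "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
                 "_atom_site_aniso_U_13", "_atom_site_aniso_U_23"),
               lapply(aniso_labels, function(lb) {
                 U <- aniso[[lb]]
                 c(list(cif_value(lb)),
                   lapply(c(U[1, 1], U[2, 2], U[3, 3],
                            U[1, 2], U[1, 3], U[2, 3]),
                          function(u) cif_value(fmt(u, 5L))))
               })))

    block <- structure(list(name = sprintf("fixture_%d", spec$seed),
                            items = items, loops = loops),
                       class = "cif_block")

    # geometry tables recomputed from the printed coordinates
    sites <- sites_from_block(block)
    graph <- infer_bonds(cell_from_block(block), sites)
    cellp <- cell_from_block(block)
    fr <- function(lb) sites[[match(lb, vapply(sites, `[[`, "", "label"))]]$frac
    bond_rows <- lapply(graph$bonds, function(b) {
      list(cif_value(b$atom1), cif_value(b$atom2),
           cif_value(fmt(b$length, 4L)))
    })
    if (length(bond_rows))
      block$loops[[length(block$loops) + 1L]] <- cif_loop(
        c("_geom_bond_atom_site_label_1", "_geom_bond_atom_site_label_2",
          "_geom_bond_distance"), bond_rows)

    nb <- list()   # adjacency by label, in bond order
    for (b in graph$bonds) {
      nb[[b$atom1]] <- c(nb[[b$atom1]], b$atom2)
      nb[[b$atom2]] <- c(nb[[b$atom2]], b$atom1)
    }
    angle_rows <- list()
    for (lb in names(nb)) {
      ns <- nb[[lb]]
      if (length(ns) < 2L) next
      for (i in seq_len(length(ns) - 1L)) {
        for (j in (i + 1L):length(ns)) {
          if (length(angle_rows) >= 40L) break
          ang <- cif_angle(cellp, fr(ns[i]), fr(lb), fr(ns[j]))
          angle_rows[[length(angle_rows) + 1L]] <-
            list(cif_value(ns[i]), cif_value(lb), cif_value(ns[j]),
                 cif_value(fmt(ang, 3L)))
        }
      }
    }
    if (length(angle_rows))
      block$loops[[length(block$loops) + 1L]] <- cif_loop(
        c("_geom_angle_atom_site_label_1", "_geom_angle_atom_site_label_2",
          "_geom_angle_atom_site_label_3", "_geom_angle"), angle_rows)

    torsion_rows <- list()
    for (b in graph$bonds) {       # paths a-b1-b2-d over the bond list
      for (a in setdiff(nb[[b$atom1]], b$atom2)) {
        for (d in setdiff(nb[[b$atom2]], c(b$atom1, a))) {
          if (length(torsion_rows) >= 10L) next
          tor <- tryCatch(
            cif_torsion(cellp, fr(a), fr(b$atom1), fr(b$atom2), fr(d)),
            error = function(e) NULL)
          if (is.null(tor)) next
          torsion_rows[[length(torsion_rows) + 1L]] <-
            list(cif_value(a), cif_value(b$atom1), cif_value(b$atom2),
                 cif_value(d), cif_value(fmt(tor, 3L)))
        }
      }
    }
    if (length(torsion_rows))
      block$loops[[length(block$loops) + 1L]] <- cif_loop(
        c("_geom_torsion_atom_site_label_1", "_geom_torsion_atom_site_label_2",
          "_geom_torsion_atom_site_label_3", "_geom_torsion_atom_site_label_4",
          "_geom_torsion"), torsion_rows)

    # formula, weight (per asymmetric unit formula) and a contact row
    parts <- moieties(graph)
    formula <- paste(vapply(parts, molecular_formula, ""), collapse = ", ")
    block <- cif_set(block, "_chemical_formula_sum", cif_value(formula,
                                                               quoted = TRUE))
    fw <- sum(ATOMIC_MASSES[mol$element] * mol$occ)
    block <- cif_set(block, "_chemical_formula_weight", fmt(fw, 3L))
    dcl <- min_image_distance(orthogonalization(cellp),
                              fr("O1") - fr("Cl1"))
    block$loops[[length(block$loops) + 1L]] <- cif_loop(
      c("_geom_contact_atom_site_label_1", "_geom_contact_atom_site_label_2",
        "_geom_contact_distance"),
      list(list(cif_value("O1"), cif_value("Cl1"),
                cif_value(fmt(dcl, 4L)))))
    block
  })
}

DEFECT_CODES <- c("elongated-adp", "bad-enum", "wrong-type",
                  "missing-required", "inconsistent-volume", "short-contact")

#' Inject a single localised defect into a fixture block
#'
#' Each code produces exactly one corruption and a descriptor naming the
#' finding the downstream module must raise:
#' * `elongated-adp` - one anisotropic site's Cartesian tensor replaced by
#'   a strongly prolate one (axis ratio > 10): expect a PLAT213-style
#'   class-A alert for that label.
#' * `bad-enum` - `_symmetry_cell_setting` set outside its enumeration:
#'   expect an `enum-violation`.
#' * `wrong-type` - `_chemical_formula_weight` set to prose: expect a
#'   `type-mismatch`.
#' * `missing-required` - `_chemical_formula_sum` deleted: expect a
#'   COMP001 completeness alert.
#' * `inconsistent-volume` - stored `_cell_volume` scaled by 1.1: expect a
#'   [check_consistency()] report with discrepancy about 0.1.
#' * `short-contact` - the hydroxyl hydrogen pulled to 0.55 A from its
#'   oxygen: expect a BOND002-style class-B alert for that bond.
#'
#' @param block A block from [generate_structure()].
#' @param code One of the codes above.
#' @return A list with `block` (corrupted) and `expected` (a list with
#'   `module`, `code`, `subject`).
#' @export
inject_defect <- function(block, code) {
  if (!(code %in% DEFECT_CODES)) stop("unknown defect code '", code, "'")
  if (code == "elongated-adp") {
    cell <- cell_from_block(block)
    Ubad <- round(u_cartesian_to_cif(cell, diag(c(0.12, 0.008, 0.008))), 5L)
    k <- loop_index_of(block, "_atom_site_aniso_label")
    lp <- block$loops[[k]]
    lb <- lp$rows[[1L]][[1L]]$raw
    lp$rows[[1L]] <- c(list(cif_value(lb)),
                       lapply(c(Ubad[1, 1], Ubad[2, 2], Ubad[3, 3],
                                Ubad[1, 2], Ubad[1, 3], Ubad[2, 3]),
                              function(u) cif_value(fmt(u, 5L))))
    block$loops[[k]] <- lp
    return(list(block = block,
                expected = list(module = "validation_alerts",
                                code = "PLAT213_ALERT_2_A", subject = lb)))
  }
  if (code == "bad-enum") {
    block <- cif_set(block, "_symmetry_cell_setting", cif_value("imaginary"))
    return(list(block = block,
                expected = list(module = "dictionary", code = "enum-violation",
                                subject = "_symmetry_cell_setting")))
  }
  if (code == "wrong-type") {
    block <- cif_set(block, "_chemical_formula_weight",
                     cif_value("heavy", quoted = TRUE))
    return(list(block = block,
                expected = list(module = "dictionary", code = "type-mismatch",
                                subject = "_chemical_formula_weight")))
  }
  if (code == "missing-required") {
    block <- cif_remove(block, "_chemical_formula_sum")
    return(list(block = block,
                expected = list(module = "validation_alerts",
                                code = "COMP001_ALERT_1_A",
                                subject = "_chemical_formula_sum")))
  }
  if (code == "inconsistent-volume") {
    v <- cif_get_num(block, "_cell_volume")
    block <- cif_set(block, "_cell_volume", fmt(v * 1.1, 4L))
    return(list(block = block,
                expected = list(module = "derivation",
                                code = "inconsistent", subject = "_cell_volume")))
  }
  # short-contact: pull H99 to 0.55 A from O1 along the O-H direction
  cell <- cell_from_block(block)
  sites <- sites_from_block(block)
  labs <- vapply(sites, `[[`, "", "label")
  io <- match("O1", labs); ih <- match("H99", labs)
  M <- orthogonalization(cell)
  po <- drop(M %*% sites[[io]]$frac)
  ph <- drop(M %*% sites[[ih]]$frac)
  newh <- po + 0.55 * (ph - po) / vnorm(ph - po)
  newf <- round(drop(solve(M) %*% newh), 6L)
  k <- loop_index_of(block, "_atom_site_label")
  lp <- block$loops[[k]]
  cols <- match(tolower(c("_atom_site_fract_x", "_atom_site_fract_y",
                          "_atom_site_fract_z")), tolower(lp$tags))
  for (j in 1:3) lp$rows[[ih]][[cols[j]]] <- cif_value(fmt(newf[j], 6L))
  block$loops[[k]] <- lp
  list(block = block,
       expected = list(module = "validation_alerts",
                       code = "BOND002_ALERT_2_B", subject = "O1-H99"))
}

#' Generate an article fragment keyed to a block's geometry tables
#'
#' Emits prose containing glossary-linkable phrases ("space group",
#' "group theory"), one mention of a tabulated bond, angle and torsion
#' (drawn with their printed values from the block's own tables), and a
#' decoy label chain guaranteed absent from every table.  The returned
#' ground truth lists exactly the resolvable mentions.
#'
#' @param block A block from [generate_structure()].
#' @param seed Integer seed (varies phrasing deterministically).
#' @return A list with `text` and `mentions` (data frame with `kind` and a
#'   `labels` list column for each resolvable mention).
#' @export
generate_article <- function(block, seed = 1L) {
  with_seed(seed, {
    row_of <- function(tags, value_tag) {
      cols <- lapply(tags, function(t) cif_loop_column(block, t))
      if (any(vapply(cols, is.null, logical(1L)))) return(NULL)
      vals <- cif_loop_column(block, value_tag)
      ok <- function(r) all(vapply(cols, function(cl) grepl(
        paste0("^", GEOM_LABEL_RE, "$"), cl[[r]]$raw, perl = TRUE),
        logical(1L)))
      rows <- Filter(ok, seq_along(cols[[1L]]))
      if (length(rows) == 0L) return(NULL)
      r <- rows[[1L + (seed %% length(rows))]]
      list(labels = vapply(cols, function(cl) cl[[r]]$raw, ""),
           value = vals[[r]]$raw)
    }
    bond <- row_of(paste0("_geom_bond_atom_site_label_", 1:2),
                   "_geom_bond_distance")
    ang <- row_of(paste0("_geom_angle_atom_site_label_", 1:3), "_geom_angle")
    tor <- row_of(paste0("_geom_torsion_atom_site_label_", 1:4),
                  "_geom_torsion")
    chain <- function(x) paste(x$labels, collapse = "---")
    sentences <- c(
      "The structure was refined in the space group P1 setting.",
      "The labelling follows no particular group theory convention.")
    mentions <- list()
    if (!is.null(bond)) {
      sentences <- c(sentences, sprintf(
        "The bond %s = %s (2) A is unexceptional.",
        chain(bond), bond$value))
      mentions[[length(mentions) + 1L]] <-
        list(kind = "distance", labels = bond$labels)
    }
    if (!is.null(ang)) {
      sentences <- c(sentences, sprintf(
        "The %s angle of %s (1) degrees is close to ideal.",
        chain(ang), ang$value))
      mentions[[length(mentions) + 1L]] <-
        list(kind = "angle", labels = ang$labels)
    }
    if (!is.null(tor)) {
      sentences <- c(sentences, sprintf(
        "The backbone adopts a %s torsion angle of %s (2) degrees.",
        chain(tor), tor$value))
      mentions[[length(mentions) + 1L]] <-
        list(kind = "torsion", labels = tor$labels)
    }
    sentences <- c(sentences,
                   "A hypothetical N8---N9 interaction is not observed.")
    md <- if (length(mentions)) {
      out <- data.frame(kind = vapply(mentions, `[[`, "", "kind"),
                        stringsAsFactors = FALSE)
      out$labels <- lapply(mentions, `[[`, "labels")
      out
    } else {
      out <- data.frame(kind = character(0))
      out$labels <- list()
      out
    }
    list(text = paste(sentences, collapse = " "), mentions = md)
  })
}
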