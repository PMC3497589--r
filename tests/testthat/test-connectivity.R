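big_cell <- unit_cell(20, 20, 20, 90, 90, 90)
site_at <- function(label, element, cart, ...)
  atom_site(label, element, cart / 20, ...)

test_that("bond perception is simple threshold arithmetic", {
  radii <- c(C = 0.77, H = 0.31, O = 0.66)
  s <- list(site_at("C1", "C", c(0, 0, 0)),
            site_at("C2", "C", c(1.50, 0, 0)))
  g <- infer_bonds(big_cell, s, radii, tol = 0.40)
  expect_length(g$bonds, 1L)                    # 1.50 <= 0.77+0.77+0.40
  expect_equal(g$bonds[[1]]$length, 1.50, tolerance = 1e-9)
  expect_equal(g$bonds[[1]]$order, "unassigned")

  s[[2]] <- site_at("C2", "C", c(3.0, 0, 0))
  expect_length(infer_bonds(big_cell, s, radii)$bonds, 0L)

  expect_error(infer_bonds(big_cell, list(site_at("X1", "Xx", c(0, 0, 0))),
                           radii), "covalent radius")
})

test_that("bonds across disorder groups of one assembly are suppressed", {
  radii <- covalent_radii()
  near <- function(g1, g2, a1 = "A", a2 = "A")
    list(site_at("O1", "O", c(0, 0, 0), occupancy = 0.5,
                 disorder_group = g1, disorder_assembly = a1),
         site_at("O2", "O", c(0.8, 0, 0), occupancy = 0.5,
                 disorder_group = g2, disorder_assembly = a2))
  expect_length(infer_bonds(big_cell, near(1L, 2L))$bonds, 0L)
  expect_length(infer_bonds(big_cell, near(1L, 1L))$bonds, 1L)
  # different assemblies do not conflict
  expect_length(infer_bonds(big_cell, near(1L, 2L, "A", "B"))$bonds, 1L)
  # absent assembly labels on both sides mean the same (default) assembly
  expect_length(infer_bonds(big_cell, near(1L, 2L, NA, NA))$bonds, 0L)
})

test_that("periodic images bond across cell boundaries", {
  s <- list(site_at("C1", "C", c(0.2, 0, 0)),
            site_at("C2", "C", c(18.9, 0, 0)))   # 1.3 A across the boundary
  expect_length(infer_bonds(big_cell, s)$bonds, 1L)
})

test_that("symmetry expansion finds bonds to images", {
  s <- list(atom_site("C1", "C", c(0.26, 0.25, 0.25)),
            atom_site("C2", "C", c(0.78, 0.75, 0.75)))
  cl <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_length(infer_bonds(cl, s)$bonds, 0L)
  ops <- op_sets()$`P-1`   # image of C2 at (0.22, 0.25, 0.25): 0.4 A from C1
  g <- infer_bonds(cl, s, expand_symmetry = TRUE, ops = ops)
  expect_length(g$bonds, 1L)
})

test_that("the edge set equals an all-pairs brute-force oracle", {
  for (seed in c(1, 2)) {
    blk <- generate_structure(fixture_spec(seed = seed, n_atoms = 40,
                                           disorder = TRUE))
    st <- structure_from_block(blk)
    expect_lte(length(st$sites), 50L)
    g <- infer_bonds(st$cell, st$sites)
    expect_identical(bond_key_set(g),
                     oracle_bond_set(st$cell, st$sites, covalent_radii(),
                                     0.40))
    # permutation invariance
    set.seed(seed)
    g2 <- infer_bonds(st$cell, sample(st$sites))
    expect_identical(bond_key_set(g2), bond_key_set(g))
  }
})

test_that("moieties partition the atoms, largest first", {
  blk <- generate_structure(fixture_spec(seed = 1))
  st <- structure_from_block(blk)
  g <- infer_bonds(st$cell, st$sites)
  parts <- moieties(g)
  expect_length(parts, 2L)                       # molecule + chloride
  all_labels <- unlist(lapply(parts, function(p)
    vapply(p, `[[`, "", "label")))
  expect_setequal(all_labels, vapply(st$sites, `[[`, "", "label"))
  expect_false(anyDuplicated(all_labels) > 0)
  expect_gte(length(parts[[1]]), length(parts[[2]]))
  expect_equal(vapply(parts[[2]], `[[`, "", "label"), "Cl1")
  expect_length(moieties(structure(list(atoms = list(), bonds = list()),
                                   class = "connectivity_graph")), 0L)
})

test_that("molecular formulas follow the Hill convention", {
  ch4 <- c(list(atom_site("C1", "C", c(0, 0, 0))),
           lapply(1:4, function(i) atom_site(paste0("H", i), "H",
                                             c(i / 10, 0, 0))))
  expect_equal(molecular_formula(ch4), "C H4")
  clo4 <- c(list(atom_site("Cl1", "Cl", c(0, 0, 0))),
            lapply(1:4, function(i) atom_site(paste0("O", i), "O",
                                              c(i / 10, 0, 0))))
  expect_equal(molecular_formula(clo4), "Cl O4")
  expect_equal(molecular_formula(list()), "")
  # occupancy weighting: two half-occupied alternates count once
  half <- list(atom_site("O1", "O", c(0, 0, 0), occupancy = 0.5),
               atom_site("O1b", "O", c(0.1, 0, 0), occupancy = 0.5))
  expect_equal(molecular_formula(half), "O")
})

test_that("connection tables round trip through the CIF loops", {
  blk <- generate_structure(fixture_spec(seed = 2))
  st <- structure_from_block(blk)
  g <- infer_bonds(st$cell, st$sites)
  blk2 <- write_connection_table(blk, g)
  g2 <- read_connection_table(blk2)
  expect_identical(vapply(g2$atoms, `[[`, "", "label"),
                   vapply(g$atoms, `[[`, "", "label"))
  expect_identical(bond_key_set(g2), bond_key_set(g))
  expect_identical(vapply(g2$bonds, `[[`, "", "order"),
                   vapply(g$bonds, `[[`, "", "order"))
  # the round trip survives serialisation to text
  g3 <- read_connection_table(parse_cif(write_cif(blk2))$blocks[[1]])
  expect_identical(bond_key_set(g3), bond_key_set(g))
  # rewriting replaces, with a warning
  expect_warning(write_connection_table(blk2, g), "replacing")
  # empty graphs emit no loops
  empty <- structure(list(atoms = list(), bonds = list()),
                     class = "connectivity_graph")
  blk3 <- write_connection_table(parse_cif("data_e\n_x 1")$blocks[[1]], empty)
  expect_length(blk3$loops, 0L)
  # bonds citing unknown labels are rejected
  bad <- structure(list(atoms = list(atom_site("C1", "C", c(0, 0, 0))),
                        bonds = list(list(atom1 = "C1", atom2 = "Zz9",
                                          length = 1, order = "unassigned"))),
                   class = "connectivity_graph")
  expect_error(write_connection_table(blk, bad), "unknown atom label")
})
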