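test_that("cell volume matches closed forms and the triple-product oracle", {
  expect_equal(cell_volume(unit_cell(10, 10, 10, 90, 90, 90)), 1000)
  expect_equal(cell_volume(unit_cell(5, 6, 7, 90, 90, 90)), 210)
  cl <- unit_cell(6.1, 7.3, 8.9, 91.2, 103.5, 95.0)
  expect_equal(cell_volume(cl), oracle_volume(cl), tolerance = 1e-12)
  expect_error(unit_cell(5, 5, 5, 10, 10, 170), "positive definite")
})

test_that("orthogonalization has the right determinant, norms and convention", {
  expect_equal(orthogonalization(unit_cell(2, 2, 2, 90, 90, 90)), 2 * diag(3))
  set.seed(7)
  for (i in 1:200) {
    cl <- random_cell()
    M <- orthogonalization(cl)
    expect_equal(det(M), cell_volume(cl), tolerance = 1e-9)
    expect_equal(sqrt(sum(M[, 1]^2)), cl$a, tolerance = 1e-12)
    # b in the xy plane with x-component b cos(gamma)
    expect_equal(M[1, 2], cl$b * cos(cl$gamma * pi / 180), tolerance = 1e-12)
    expect_equal(M[3, 2], 0)
  }
})

test_that("distance, angle and torsion match an independent Cartesian oracle", {
  cl <- unit_cell(4, 5, 6, 90, 90, 90)
  expect_equal(cif_distance(cl, c(0, 0, 0), c(0.5, 0, 0)), 2)
  # planar chains force torsion 180 (trans) and 0 (cis)
  cube <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_equal(cif_torsion(cube, c(0, 0.1, 0), c(0.1, 0, 0), c(0.2, 0, 0),
                           c(0.3, 0.1, 0)), 0)
  expect_equal(abs(cif_torsion(cube, c(0, 0.1, 0), c(0.1, 0, 0),
                               c(0.2, 0, 0), c(0.3, -0.1, 0))), 180)
  set.seed(11)
  for (i in 1:200) {
    cl <- random_cell()
    x <- lapply(1:4, function(k) runif(3))
    expect_equal(cif_distance(cl, x[[1]], x[[2]]),
                 oracle_distance(cl, x[[1]], x[[2]]), tolerance = 1e-9)
    expect_equal(cif_angle(cl, x[[1]], x[[2]], x[[3]]),
                 oracle_angle(cl, x[[1]], x[[2]], x[[3]]), tolerance = 1e-8)
    expect_equal(cif_torsion(cl, x[[1]], x[[2]], x[[3]], x[[4]]),
                 oracle_torsion(cl, x[[1]], x[[2]], x[[3]], x[[4]]),
                 tolerance = 1e-8)
    # symmetry properties
    expect_equal(cif_angle(cl, x[[1]], x[[2]], x[[3]]),
                 cif_angle(cl, x[[3]], x[[2]], x[[1]]))
    # IUPAC convention: order reversal preserves the signed torsion;
    # mirror inversion of the coordinates flips its sign
    expect_equal(cif_torsion(cl, x[[4]], x[[3]], x[[2]], x[[1]]),
                 cif_torsion(cl, x[[1]], x[[2]], x[[3]], x[[4]]),
                 tolerance = 1e-8)
    neg <- lapply(x, function(v) -v)
    expect_equal(cif_torsion(cl, neg[[1]], neg[[2]], neg[[3]], neg[[4]]),
                 -cif_torsion(cl, x[[1]], x[[2]], x[[3]], x[[4]]),
                 tolerance = 1e-8)
  }
  expect_error(cif_angle(cube, c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
  expect_error(cif_torsion(cube, c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0),
                           c(0.3, 0, 0)), "collinear")
})

test_that("symmetry triplets parse to exact rational operators", {
  id <- parse_symop("x,y,z")
  expect_equal(id$rot, diag(3))
  expect_equal(id$trans, c(0, 0, 0))
  op <- parse_symop("-x,y+1/2,-z+1/2")
  expect_equal(op$rot, diag(c(-1, 1, -1)))
  expect_equal(op$trans, c(0, 0.5, 0.5))
  expect_equal(parse_symop("1/2+X,-Y,Z")$trans, c(0.5, 0, 0))
  expect_equal(parse_symop("y-x,-x,z")$rot[1, ], c(-1, 1, 0))
  expect_error(parse_symop("x,y"), "malformed")
  expect_error(parse_symop("x,y,q"), "malformed")
  expect_error(parse_symop("x,y,2z"), "det")
  for (s in c("x,y,z", "-x,y+1/2,-z+1/2", "-y,x-y,z+1/3", "x-y,-y,-z")) {
    expect_equal(format_symop(parse_symop(s)), tolower(s), info = s)
  }
})

test_that("orbits have group-theoretic sizes and mod-1 invariance", {
  ops <- op_sets()
  expect_equal(nrow(site_orbit(ops$P1, c(0.3, 0.9, 0.2))), 1L)
  expect_equal(nrow(site_orbit(ops$`P-1`, c(0.1, 0.2, 0.3))), 2L)
  expect_equal(nrow(site_orbit(ops$`P-1`, c(0, 0, 0))), 1L)     # on centre
  expect_equal(nrow(site_orbit(ops$`P-1`, c(0.5, 0.5, 0.5))), 1L)
  expect_equal(site_orbit(ops$`P-1`, c(0.1, 0.2, 0.3)),
               site_orbit(ops$`P-1`, c(1.1, 0.2, 0.3)))
  expect_error(site_orbit(list(parse_symop("-x,-y,-z")), c(0.1, 0.1, 0.1)),
               "identity")
  set.seed(3)
  for (nm in names(ops)) {
    for (i in 1:25) {
      x <- runif(3)
      n <- nrow(site_orbit(ops[[nm]], x))
      expect_equal(n, oracle_orbit_size(ops[[nm]], x), info = nm)
      expect_equal(length(ops[[nm]]) %% n, 0L, info = nm)
    }
  }
})

test_that("structure factors obey counting, extinction and Friedel rules", {
  s1 <- atom_site("C1", "C", c(0, 0, 0))
  s2 <- atom_site("C2", "C", c(0.5, 0, 0))
  expect_equal(structure_factor(c(0, 0, 0), list(s1, s2), f = c(C = 1)),
               2 + 0i)
  expect_equal(structure_factor(c(3, -2, 5), list(s1), f = c(C = 1)), 1 + 0i)
  expect_lt(Mod(structure_factor(c(1, 0, 0), list(s1, s2), f = c(C = 1))),
            1e-12)
  expect_error(structure_factor(c(1, 0, 0), list(atom_site("N1", "N",
                                                           c(0, 0, 0))),
                                f = c(C = 1)), "scattering factor")
  ops <- op_sets()$`P-1`
  set.seed(5)
  sites <- lapply(1:4, function(i)
    atom_site(paste0("C", i), "C", runif(3), occupancy = runif(1, 0.5, 1)))
  for (i in 1:20) {
    hkl <- sample(-4:4, 3, replace = TRUE)
    Fp <- structure_factor(hkl, sites, ops, f = c(C = 6))
    Fm <- structure_factor(-hkl, sites, ops, f = c(C = 6))
    expect_equal(Mod(Fp), Mod(Fm), tolerance = 1e-10)    # Friedel pair
    expect_lt(abs(Im(Fp)), 1e-10)                        # centrosymmetric
  }
  # F(000) counts occupancy-weighted expanded atoms
  F000 <- structure_factor(c(0, 0, 0), sites, ops, f = c(C = 1))
  expect_equal(Re(F000),
               sum(vapply(sites, function(s)
                 s$occupancy * nrow(site_orbit(ops, s$frac)), numeric(1))))
})

test_that("CIF displacement tensors transform correctly to Cartesian", {
  cube <- unit_cell(8, 8, 8, 90, 90, 90)
  U <- diag(c(0.02, 0.02, 0.02))
  expect_equal(u_cif_to_cartesian(cube, U), U)
  ortho <- unit_cell(6, 9, 12, 90, 90, 90)
  U <- diag(c(0.01, 0.02, 0.03))
  expect_equal(u_cif_to_cartesian(ortho, U), U)    # orthogonal axes: identity
  expect_error(u_cif_to_cartesian(cube, matrix(runif(9), 3)), "symmetric")
  set.seed(9)
  for (i in 1:50) {
    cl <- random_cell()
    A <- matrix(rnorm(9), 3); U <- (A + t(A)) / 20
    X <- u_cif_to_cartesian(cl, U)
    expect_equal(X, t(X))
    # round trip through the inverse convention used by the fixtures
    expect_equal(cifsem:::u_cartesian_to_cif(cl, X), U, tolerance = 1e-9)
  }
})
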