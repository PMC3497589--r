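gi <- glossary_index(
  c("space group" = "u/space_group",
    "plane group" = "u/plane_group",
    "group theory" = "u/group",
    "group" = "u/group",
    "unit cell" = "u/unit_cell"),
  stop_words = c("group", "cell"))

test_that("glossary annotation prefers the longest phrase", {
  ann <- annotate("the space group P21 is common", gi)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$phrase, "space group")
  expect_equal(ann$target, "u/space_group")
  expect_equal(substring("the space group P21 is common",
                         ann$start, ann$end - 1), "space group")

  # a phrase that contains a stop word still links (to the stop word's entry)
  ann <- annotate("group theory is hard", gi)
  expect_equal(ann$phrase, "group theory")
  expect_equal(ann$target, "u/group")

  # the single stop-listed word never links on its own
  expect_equal(nrow(annotate("a group of molecules", gi)), 0L)

  # "space group" text never yields a bare "group" annotation
  ann <- annotate("space group", gi)
  expect_equal(ann$target, "u/space_group")
})

test_that("every occurrence is annotated, without overlaps, in order", {
  text <- "One space group, another space group; the unit cell twice, unit cell."
  ann <- annotate(text, gi)
  expect_equal(ann$target, c("u/space_group", "u/space_group",
                             "u/unit_cell", "u/unit_cell"))
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$end[-nrow(ann)] <= ann$start[-1]))
  # punctuation at window edges is stripped for matching, spans stay tight
  expect_equal(substring(text, ann$start[2], ann$end[2] - 1), "space group")
  # pure function: same input, same output
  expect_identical(annotate(text, gi), ann)
})

test_that("case folding and whitespace collapse drive matching", {
  ann <- annotate("THE Space   Group setting", gi)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$target, "u/space_group")
  expect_equal(nrow(annotate("", gi)), 0L)
})

test_that("glossary files load with stop words", {
  path <- system.file("extdata", "glossary.tsv", package = "cifsem")
  g <- read_glossary(path)
  expect_true("space group" %in% names(g$entries))
  expect_true("group" %in% g$stop_words)
  ann <- annotate("the space group and group theory", g)
  expect_equal(ann$phrase, c("space group", "group theory"))
})

test_that("geometry mentions are scanned with labels, kind and value", {
  sc <- scan_geometry("C2---C21---C22---C221")
  expect_equal(sc$kind, "torsion")
  expect_equal(sc$labels[[1]], c("C2", "C21", "C22", "C221"))

  sc <- scan_geometry("C1---C2 1.534 (2) A long")
  expect_equal(sc$kind, "distance")
  expect_equal(sc$value, 1.534)
  expect_equal(sc$su, 0.002)

  expect_equal(nrow(scan_geometry("the cell is large")), 0L)

  # dots mark contacts; other separators are equivalent dashes
  expect_equal(scan_geometry("O1...Cl1 3.20 (1)")$kind, "contact")
  expect_equal(scan_geometry("N1—C2–C3")$kind, "angle")
  expect_equal(scan_geometry("C4'-C5'")$labels[[1]], c("C4'", "C5'"))

  # label chains inside words do not match
  expect_equal(nrow(scan_geometry("xC1---C2x")), 0L)
  # five labels exceed the grammar: the first four match
  sc <- scan_geometry("C1-C2-C3-C4-C5")
  expect_equal(sc$kind[1], "torsion")
})

test_that("mentions resolve against tabulated geometry forwards or reversed", {
  blk <- parse_cif(paste(
    "data_s1",
    "loop_ _geom_torsion_atom_site_label_1 _geom_torsion_atom_site_label_2",
    " _geom_torsion_atom_site_label_3 _geom_torsion_atom_site_label_4",
    " _geom_torsion",
    "C2 C21 C22 C221 -64.5",
    "loop_ _geom_bond_atom_site_label_1 _geom_bond_atom_site_label_2",
    " _geom_bond_distance",
    "C1 C2 1.534",
    sep = "\n"))$blocks[[1]]

  res <- resolve_mentions(scan_geometry("C2---C21---C22---C221"), blk)
  expect_length(res, 1L)
  expect_false(res[[1]]$ambiguous)
  expect_equal(res[[1]]$matches$value, -64.5)

  # reversed order still binds
  res <- resolve_mentions(scan_geometry("C2---C1 bond"), blk)
  expect_length(res, 1L)
  expect_equal(res[[1]]$matches$value, 1.534)

  # unmatched mentions are dropped from the actionable output
  expect_length(resolve_mentions(scan_geometry("N8---N9"), blk), 0L)
  # kind must agree: a two-label mention never binds a torsion row
  expect_length(resolve_mentions(scan_geometry("C21---C22"), blk), 0L)

  # the same labels tabulated in two structures return both candidates
  blk2 <- blk; blk2$name <- "s2"
  res <- resolve_mentions(scan_geometry("C2---C21---C22---C221"),
                          list(blk, blk2))
  expect_length(res, 1L)
  expect_true(res[[1]]$ambiguous)
  expect_equal(nrow(res[[1]]$matches), 2L)
  expect_setequal(res[[1]]$matches$block, c("s1", "s2"))
})

test_that("generated articles resolve with perfect precision and recall", {
  for (seed in 1:10) {
    blk <- generate_structure(fixture_spec(seed = seed,
                                           disorder = seed %% 2 == 0))
    art <- generate_article(blk, seed)
    res <- resolve_mentions(scan_geometry(art$text), blk)
    got <- vapply(res, function(r)
      paste(r$mention$kind, paste(r$mention$labels[[1]], collapse = "-")), "")
    want <- vapply(seq_len(nrow(art$mentions)), function(i)
      paste(art$mentions$kind[i],
            paste(art$mentions$labels[[i]], collapse = "-")), "")
    expect_setequal(got, want)            # precision and recall both 1
  }
})
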