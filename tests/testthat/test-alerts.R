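test_that("ellipsoid elongation thresholds classify severities", {
  cube <- unit_cell(10, 10, 10, 90, 90, 90)
  cfg <- default_check_config()
  iso <- atom_site("C1", "C", c(0, 0, 0), u_aniso = diag(c(0.02, 0.02, 0.02)))
  expect_null(adp_elongation_check(cube, iso, cfg))

  mid <- atom_site("C2", "C", c(0, 0, 0), u_aniso = diag(c(0.05, 0.01, 0.01)))
  a <- adp_elongation_check(cube, mid, cfg)       # ratio 5: class B
  expect_equal(a$severity, "B")
  expect_equal(a$code, "PLAT213_ALERT_2_B")
  expect_equal(a$subject, "C2")

  hot <- atom_site("C3", "C", c(0, 0, 0), u_aniso = diag(c(0.09, 0.01, 0.01)))
  a <- adp_elongation_check(cube, hot, cfg)       # ratio 9: class A
  expect_equal(a$severity, "A")
  expect_equal(a$code, "PLAT213_ALERT_2_A")

  npd <- atom_site("C4", "C", c(0, 0, 0), u_aniso = diag(c(0.02, 0.02, 0)))
  a <- adp_elongation_check(cube, npd, cfg)
  expect_equal(a$code, "PLAT211_ALERT_2_A")
})

test_that("clean fixtures raise no serious alerts; defects raise theirs", {
  dict <- load_dictionary("core")
  for (seed in c(1, 5)) {
    blk <- generate_structure(fixture_spec(seed = seed, disorder = TRUE))
    rep <- run_checks(blk, dict)
    expect_length(serious_alerts(rep), 0L)
  }
  blk <- generate_structure(fixture_spec(seed = 3))

  d <- inject_defect(blk, "elongated-adp")
  rep <- run_checks(d$block, dict)
  ser <- serious_alerts(rep)
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$code, d$expected$code)
  expect_equal(ser[[1]]$subject, d$expected$subject)

  d <- inject_defect(blk, "missing-required")
  ser <- serious_alerts(run_checks(d$block, dict))
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$code, "COMP001_ALERT_1_A")
  expect_equal(ser[[1]]$subject, "_chemical_formula_sum")

  d <- inject_defect(blk, "short-contact")
  ser <- serious_alerts(run_checks(d$block, dict))
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$code, "BOND002_ALERT_2_B")
  expect_equal(ser[[1]]$subject, d$expected$subject)
})

test_that("solvent sites excluded by configuration skip the ADP check", {
  dict <- load_dictionary("core")
  blk <- generate_structure(fixture_spec(seed = 3))
  d <- inject_defect(blk, "elongated-adp")
  cfg <- default_check_config(excluded_labels = d$expected$subject)
  expect_length(serious_alerts(run_checks(d$block, dict, cfg)), 0L)
})

test_that("alerts are invariant under atom-order permutation", {
  dict <- load_dictionary("core")
  blk <- generate_structure(fixture_spec(seed = 6, disorder = TRUE))
  blk <- inject_defect(blk, "elongated-adp")$block
  key <- function(rep) sort(vapply(rep$alerts, function(a)
    paste(a$code, a$subject), ""))
  k <- loop_index_of(blk, "_atom_site_label")
  perm <- blk
  set.seed(1)
  perm$loops[[k]]$rows <- sample(perm$loops[[k]]$rows)
  expect_equal(key(run_checks(perm, dict)), key(run_checks(blk, dict)))
})

test_that("gating holds over the full severity/response truth table", {
  mk <- function(sev, i) cifsem:::new_alert(sprintf("TEST%03d", i), 1L, sev,
                                            "synthetic", "x")
  sevs <- c("A", "B", "C")
  alerts <- lapply(seq_along(sevs), function(i) mk(sevs[i], i))
  for (mask in 0:7) {      # which of the three alerts get responses
    responded <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    resp <- lapply(which(responded), function(i)
      alert_response(alerts[[i]]$code, "explained in the text"))
    rep <- gate_submission(alerts, resp)
    expect_equal(rep$admitted, all(responded[1:2]),
                 info = paste("mask", mask))
  }
  # C alerts alone never block; serious alerts without responses do
  expect_true(gate_submission(list(mk("C", 9)), list())$admitted)
  expect_false(gate_submission(list(mk("B", 8)), list())$admitted)
  expect_warning(
    gate_submission(list(mk("C", 9)),
                    list(alert_response("NOPE001_ALERT_1_A", "hm"))),
    "non-existent")
})

test_that("responses travel inside the CIF as _vrf_ items", {
  dict <- load_dictionary("core")
  blk <- generate_structure(fixture_spec(seed = 3))
  d <- inject_defect(blk, "elongated-adp")
  rep <- gate_submission(run_checks(d$block, dict), d$block)
  expect_false(rep$admitted)
  answered <- cif_set(d$block, paste0("_vrf_", d$expected$code),
                      cif_value("Localised disorder; discussed in the text.",
                                quoted = TRUE))
  rep <- gate_submission(run_checks(answered, dict), answered)
  expect_true(rep$admitted)
})

test_that("reports render with explanations and adjacent responses", {
  empty <- gate_submission(list(), list())
  expect_match(render_report(empty), "no alerts")
  a <- cifsem:::new_alert("PLAT213", 2L, "B", "ADP of C4' elongated", "C4'")
  rep <- gate_submission(list(a),
                         list(alert_response(a$code, "localised disorder")))
  txt <- render_report(rep)
  lines <- strsplit(txt, "\n")[[1]]
  i <- grep("PLAT213_ALERT_2_B", lines)
  expect_match(lines[i + 1], "unresolved disorder")       # generic explanation
  expect_match(lines[i + 2], "localised disorder")        # adjacent response
  html <- render_report(rep, "html")
  expect_match(html, "href=\"#PLAT213\"")
  # unknown codes render without an explanation link
  b <- cifsem:::new_alert("ZZZZ999", 1L, "C", "mystery", "y")
  b$explanation <- NULL
  html <- render_report(gate_submission(list(b), list()), "html")
  expect_false(grepl("href=\"#ZZZZ999\"", html))
})
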