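#' Alert catalogue
#'
#' The checks in this package emit alerts with PLAT/checkcif-style codes of
#' the form `NAMEnnn_ALERT_t_S` where `S` is the severity class: `A`
#' (extreme outlier) and `B` (significant outlier) are "serious" and gate
#' submission; `C` is a minor note.  Each code base has a generic
#' explanation used when rendering reports.
#'
#' @return Named character vector mapping code base to explanation prose.
#' @export
alert_explanations <- function() {
  c(
    COMP001 = paste("A data item required by the journal profile is missing",
                    "from the submission."),
    DICT001 = "The tag is not defined in the governing dictionary.",
    DICT002 = "A numeric-typed tag carries a non-numeric value.",
    DICT003 = "The value is outside the enumerated set allowed by the dictionary.",
    DICT004 = "The numeric value lies outside the range allowed by the dictionary.",
    DICT005 = "The tag appears in the wrong list context (looped vs single item).",
    DICT006 = paste("The value carries a standard uncertainty although the",
                    "definition does not permit one."),
    PLAT211 = paste("The anisotropic displacement tensor of this atom is not",
                    "positive definite and cannot describe a physical",
                    "probability distribution."),
    PLAT213 = paste("This atom has an unusually elongated displacement",
                    "ellipsoid; this may indicate unresolved disorder in the",
                    "crystal."),
    BOND001 = paste("An inferred bond length deviates noticeably from the",
                    "sum of the covalent radii of its atoms."),
    BOND002 = paste("An inferred bond length deviates strongly from the sum",
                    "of the covalent radii of its atoms; the geometry or the",
                    "element assignment may be wrong."),
    OCCU001 = paste("The occupancies of the disorder groups of an assembly",
                    "do not sum to unity.")
  )
}

violation_code_map <- c(
  "unknown-tag" = "DICT001", "type-mismatch" = "DICT002",
  "enum-violation" = "DICT003", "range-violation" = "DICT004",
  "loop-context" = "DICT005", "missing-su-disallowed" = "DICT006")

new_alert <- function(base, check_class, severity, message, subject) {
  structure(list(
    code = sprintf("%s_ALERT_%d_%s", base, check_class, severity),
    base = base, severity = severity, message = message,
    subject = subject,
    explanation = unname(alert_explanations()[base])),
    class = "cif_alert")
}

#' @export
print.cif_alert <- function(x, ...) {
  cat(sprintf("%s  %s : %s\n", x$code, x$subject, x$message))
  invisible(x)
}

#' Author response to an alert
#'
#' Machine-readable comments attached by the author to serious validation
#' alerts; carried in the submission file itself as `_vrf_<CODE>` items.
#'
#' @param code The alert code being answered.
#' @param text Non-empty response prose.
#' @return An `alert_response`.
#' @export
alert_response <- function(code, text) {
  stopifnot(is.character(code), length(code) == 1L,
            is.character(text), length(text) == 1L, nzchar(trimws(text)))
  structure(list(code = code, text = text), class = "alert_response")
}

#' Default configuration for structure checks
#'
#' @param adp_ratio_B,adp_ratio_A Eigenvalue-ratio thresholds of the
#'   Cartesian displacement tensor above which a B- or A-class elongation
#'   alert is raised (defaults 4 and 8; thresholds are journal policy, not
#'   physics, and are meant to be tuned per profile).
#' @param bond_tol Bond-perception tolerance in angstrom (default 0.40).
#' @param bond_dev_C,bond_dev_B Deviation bands (angstrom) of a bond length
#'   from the covalent-radius sum beyond which C- and B-class alerts are
#'   raised (defaults 0.15 and 0.30).
#' @param occupancy_tol Allowed deviation of a disorder assembly's group
#'   occupancy sum from 1 (default 0.02).
#' @param required_tags Journal-profile completeness list.
#' @param excluded_labels Atom labels skipped by the displacement checks
#'   (e.g. solvent ions deliberately left unrefined; recognising solvent is
#'   a policy decision, so exclusions must be listed explicitly).
#' @return A named list.
#' @export
default_check_config <- function(
    adp_ratio_B = 4.0, adp_ratio_A = 8.0,
    bond_tol = 0.40, bond_dev_C = 0.15, bond_dev_B = 0.30,
    occupancy_tol = 0.02,
    required_tags = c(
      "_cell_length_a", "_cell_length_b", "_cell_length_c",
      "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma",
      "_atom_site_label", "_atom_site_fract_x", "_atom_site_fract_y",
      "_atom_site_fract_z", "_chemical_formula_sum"),
    excluded_labels = character(0)) {
  list(adp_ratio_B = adp_ratio_B, adp_ratio_A = adp_ratio_A,
       bond_tol = bond_tol, bond_dev_C = bond_dev_C, bond_dev_B = bond_dev_B,
       occupancy_tol = occupancy_tol, required_tags = required_tags,
       excluded_labels = excluded_labels)
}

#' Displacement-ellipsoid elongation check
#'
#' Transforms the site's CIF-convention tensor to Cartesian axes, takes the
#' ratio `r` of the largest to smallest eigenvalue, and raises a
#' PLAT213-style alert at class B when `r` exceeds `adp_ratio_B` and class
#' A when it exceeds `adp_ratio_A`.  A non-positive-definite tensor gets
#' its own class-A alert.
#'
#' @param cell A [unit_cell].
#' @param site An [atom_site] with `u_aniso`.
#' @param config See [default_check_config()].
#' @return A `cif_alert`, or `NULL` when the ellipsoid is unremarkable.
#' @export
adp_elongation_check <- function(cell, site, config = default_check_config()) {
  stopifnot(!is.null(site$u_aniso))
  U <- u_cif_to_cartesian(cell, site$u_aniso)
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    return(new_alert("PLAT211", 2L, "A",
                     sprintf("ADP of %s is non-positive-definite", site$label),
                     site$label))
  }
  r <- max(ev) / min(ev)
  if (r > config$adp_ratio_A) {
    new_alert("PLAT213", 2L, "A",
              sprintf("ADP of %s unusually elongated (ratio %.2f)",
                      site$label, r), site$label)
  } else if (r > config$adp_ratio_B) {
    new_alert("PLAT213", 2L, "B",
              sprintf("ADP of %s elongated (ratio %.2f)", site$label, r),
              site$label)
  } else {
    NULL
  }
}

#' Run the structure checks on a data block
#'
#' Executes, in fixed order: (1) completeness against the journal-profile
#' required-tag list (class A per missing tag); (2) dictionary validation,
#' re-expressed as class-C alerts; (3) displacement-ellipsoid elongation
#' for every anisotropic site not excluded by the config; (4) plausibility
#' of inferred bond lengths against covalent-radius sums; (5) occupancy
#' sums over disorder assemblies.  Alert ordering is deterministic.
#'
#' @param block A [cif_block] that parses into a structure (cell + sites).
#' @param dict A `cif_dictionary` (defaults to the shipped core
#'   dictionary).
#' @param config See [default_check_config()].
#' @return A `validation_report` with the alerts; responses and the
#'   admitted flag are filled in by [gate_submission()].
#' @export
run_checks <- function(block, dict = load_dictionary("core"),
                       config = default_check_config()) {
  alerts <- list()
  add <- function(a) if (!is.null(a)) alerts[[length(alerts) + 1L]] <<- a

  present <- tolower(cif_tags(block))
  for (tag in config$required_tags) {
    if (!(tolower(tag) %in% present))
      add(new_alert("COMP001", 1L, "A",
                    sprintf("required item %s is missing", tag), tag))
  }
  for (v in validate_block(block, dict, strict_unknown = FALSE)) {
    add(new_alert(violation_code_map[[v$code]], 1L, "C", v$message, v$tag))
  }
  st <- structure_from_block(block)  # unparseable structure is an error
  for (site in st$sites) {
    if (is.null(site$u_aniso)) next
    if (site$label %in% config$excluded_labels) next
    add(adp_elongation_check(st$cell, site, config))
  }
  graph <- infer_bonds(st$cell, st$sites, tol = config$bond_tol)
  radii <- covalent_radii()
  elem <- setNames(lapply(st$sites, `[[`, "element"),
                   vapply(st$sites, `[[`, "", "label"))
  for (b in graph$bonds) {
    expected <- radii[[elem[[b$atom1]]]] + radii[[elem[[b$atom2]]]]
    dev <- b$length - expected
    subject <- paste0(b$atom1, "-", b$atom2)
    if (abs(dev) > config$bond_dev_B) {
      add(new_alert("BOND002", 2L, "B",
                    sprintf("bond %s = %.3f A deviates %.3f A from %.2f A",
                            subject, b$length, dev, expected), subject))
    } else if (abs(dev) > config$bond_dev_C) {
      add(new_alert("BOND001", 2L, "C",
                    sprintf("bond %s = %.3f A deviates %.3f A from %.2f A",
                            subject, b$length, dev, expected), subject))
    }
  }
  asm <- vapply(st$sites, `[[`, "", "disorder_assembly")
  grp <- vapply(st$sites, function(s) as.numeric(s$disorder_group),
                numeric(1L))
  occ <- vapply(st$sites, `[[`, numeric(1L), "occupancy")
  for (a in sort(unique(asm[!is.na(asm) & !is.na(grp)]))) {
    ix <- which(!is.na(asm) & asm == a & !is.na(grp))
    gsum <- sum(vapply(split(occ[ix], grp[ix]), mean, numeric(1L)))
    if (abs(gsum - 1) > config$occupancy_tol) {
      add(new_alert("OCCU001", 2L, "B",
                    sprintf("occupancies of assembly %s groups sum to %.3f",
                            a, gsum), a))
    }
  }
  structure(list(alerts = alerts, responses = list(), admitted = NA),
            class = "validation_report")
}

#' Collect machine-readable author responses from a block
#'
#' Responses live in the submission file itself as `_vrf_<CODE>` items
#' whose value is the author's prose.
#'
#' @param block A [cif_block].
#' @return A list of [alert_response] objects.
#' @export
collect_responses <- function(block) {
  out <- list()
  for (tag in names(block$items)) {
    if (startsWith(tolower(tag), "_vrf_")) {
      txt <- block$items[[tag]]$raw
      if (nzchar(trimws(txt)))
        out[[length(out) + 1L]] <- alert_response(substring(tag, 6L), txt)
    }
  }
  out
}

#' Gate a submission on responses to serious alerts
#'
#' A submission is admitted into review if and only if every class-A and
#' class-B alert code has a non-empty author response; class-C alerts
#' never block.  Responses citing codes that raised no alert are reported
#' with a warning and ignored for gating.
#'
#' @param report A `validation_report` from [run_checks()] (or a list of
#'   alerts).
#' @param responses A list of [alert_response] objects, or a [cif_block]
#'   whose `_vrf_` items should be read.
#' @return The report with `responses` attached and `admitted` set.
#' @export
gate_submission <- function(report, responses = list()) {
  if (inherits(report, "validation_report")) {
    alerts <- report$alerts
  } else {
    alerts <- report
    report <- structure(list(alerts = alerts, responses = list(),
                             admitted = NA), class = "validation_report")
  }
  if (inherits(responses, "cif_block")) responses <- collect_responses(responses)
  codes <- vapply(alerts, `[[`, "", "code")
  rcodes <- toupper(vapply(responses, `[[`, "", "code"))
  orphan <- setdiff(rcodes, toupper(codes))
  if (length(orphan))
    warning("response(s) cite non-existent alert code(s): ",
            paste(orphan, collapse = ", "))
  serious <- codes[vapply(alerts, function(a) a$severity %in% c("A", "B"),
                          logical(1L))]
  report$responses <- responses
  report$admitted <- all(toupper(serious) %in% rcodes)
  report
}

#' Render a validation report
#'
#' Lists every alert with its severity, message and generic explanation
#' (hyperlink-anchored by code in the HTML flavour), followed by the
#' author responses placed next to the alerts they answer.
#'
#' @param report A `validation_report`.
#' @param format `"text"` or `"html"`.
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("text", "html")) {
  format <- match.arg(format)
  expl <- alert_explanations()
  resp_for <- function(code) {
    hits <- Filter(function(r) toupper(r$code) == toupper(code),
                   report$responses)
    if (length(hits)) hits[[1L]]$text else NULL
  }
  if (format == "text") {
    if (length(report$alerts) == 0L) {
      out <- "Validation report: no alerts."
    } else {
      lines <- character(0)
      for (a in report$alerts) {
        lines <- c(lines, sprintf("%s  %s", a$code, a$message))
        if (!is.null(a$explanation))
          lines <- c(lines, paste0("    ", a$explanation))
        r <- resp_for(a$code)
        if (!is.null(r)) lines <- c(lines, paste0("    Author response: ", r))
      }
      out <- paste(c("Validation report:", lines), collapse = "\n")
    }
    if (!is.na(report$admitted))
      out <- paste0(out, "\nAdmitted to review: ",
                    if (report$admitted) "yes" else "no")
    return(out)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- if (length(report$alerts) == 0L) {
    "<p>No alerts.</p>"
  } else {
    items <- vapply(report$alerts, function(a) {
      code_html <- if (!is.null(a$explanation) && a$base %in% names(expl)) {
        sprintf("<a href=\"#%s\">%s</a>", a$base, esc(a$code))
      } else {
        esc(a$code)
      }
      r <- resp_for(a$code)
      resp_html <- if (is.null(r)) "" else
        sprintf("<p class=\"response\">Author response: %s</p>", esc(r))
      sprintf("<li>%s %s%s</li>", code_html, esc(a$message), resp_html)
    }, character(1L))
    anchors <- vapply(unique(vapply(report$alerts, `[[`, "", "base")),
                      function(b) {
                        if (!(b %in% names(expl))) return("")
                        sprintf("<p id=\"%s\"><b>%s</b>: %s</p>",
                                b, b, esc(expl[[b]]))
                      }, character(1L))
    paste0("<ul>", paste(items, collapse = ""), "</ul>",
           paste(anchors, collapse = ""))
  }
  paste0("<html><body><h1>Validation report</h1>", body, "</body></html>")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
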