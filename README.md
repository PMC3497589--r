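# cifsem

Semantic tools for Crystallographic Information Files (CIF), for people
who build or study data-driven publishing pipelines for crystal
structures: journal production systems, structure-validation services,
and research on machine-readable scientific records.

A CIF is a free-form ASCII tag-value format (`_cell_length_a 5.12(3)`,
`loop_` tables, `data_` blocks) whose semantics live in machine-readable
dictionaries written in the same syntax. On top of that substrate this
package implements the full stack a semantically rich publishing workflow
needs:

* **Syntax** — strict CIF 1.1-style parser and writer with lexical
  numeric typing and parenthesised standard uncertainties
  (`parse_cif()`, `write_cif()`, `lex_number()`); `parse∘write` is the
  identity on the data model.
* **Dictionaries** — a DDL-style bootstrap attribute set, itself defined
  in a self-validating dictionary, driving type/enumeration/range/
  list-context validation (`parse_dictionary()`, `validate_block()`).
* **Geometry & symmetry** — cell metrics
  (V = abc·√(1−cos²α−cos²β−cos²γ+2cosαcosβcosγ)), fractional↔Cartesian
  orthogonalization, distances/angles/torsions (IUPAC sign convention),
  exact symmetry-triplet algebra, site orbits/multiplicities, and the
  structure-factor sum F(hkl) = Σⱼ oⱼ fⱼ e^{2πi hkl·xⱼ}.
* **Derivation** — registered methods with recursive, stored-first,
  memoised resolution (`derive_item()`), plus stored-vs-derived
  consistency reports (`check_consistency()`).
* **Validation & gating** — checkcif-style alerts (classes A/B/C) with
  PLAT-style codes, machine-readable author responses carried as
  `_vrf_*` items, and the submission rule: no admission while a serious
  alert lacks a response (`run_checks()`, `gate_submission()`,
  `render_report()`).
* **Connectivity** — bond perception from covalent radii + tolerance
  with disorder-aware suppression, moieties, Hill formulas, and
  connection-table write-back into the CIF (`infer_bonds()`,
  `moieties()`, `write_connection_table()`).
* **Implied semantics in text** — glossary annotation with a shrinking
  4→1 word window and stop words (`annotate()`), and geometry-mention
  scanning resolved against the file's tabulated values
  (`scan_geometry()`, `resolve_mentions()`).
* **Fixtures** — deterministic toy structures, defect injection and
  article fragments so the whole stack is testable offline
  (`generate_structure()`, `inject_defect()`, `generate_article()`).

## A worked example

```r
library(cifsem)

block <- generate_structure(fixture_spec(seed = 5, disorder = TRUE))

# derive a missing item from related ones
derive_item(cif_remove(block, "_cell_volume"), "_cell_volume",
            default_methods())$numeric
#> [1] 1539.32

# inject a defect and watch the gate close
bad <- inject_defect(block, "elongated-adp")$block
report <- gate_submission(run_checks(bad), bad)
report$admitted
#> [1] FALSE
cat(render_report(report))
#> Validation report:
#> PLAT213_ALERT_2_A  ADP of C1 unusually elongated (ratio 15.01)
#>     This atom has an unusually elongated displacement ellipsoid; this
#>     may indicate unresolved disorder in the crystal.
#> Admitted to review: no

# answer the alert inside the CIF itself, and the gate opens
ok <- cif_set(bad, "_vrf_PLAT213_ALERT_2_A",
              cif_value("Localised disorder; discussed in the text.",
                        quoted = TRUE))
gate_submission(run_checks(ok), ok)$admitted
#> [1] TRUE

# chemistry from crystallography
st <- structure_from_block(block)
g  <- infer_bonds(st$cell, st$sites)
vapply(moieties(g), molecular_formula, "")
#> [1] "C4 H10 O" "Cl"
```

The elongation alert fires because the injected Cartesian displacement
tensor has an eigenvalue ratio of about 15, far beyond the class-A
threshold of 8; the two moieties are the toy alcohol molecule and its
unbonded chloride counter-ion.

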