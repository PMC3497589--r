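---
title: "Semantic CIF publishing: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic CIF publishing: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifsem)
```

cifsem implements the software stack behind semantically rich
crystallographic publishing: a strict CIF reader/writer, machine-readable
dictionaries with validation, a derivation engine, a checkcif-style alert
and gating workflow, bond perception, and the two "implied semantics"
text algorithms (glossary annotation and geometry-mention resolution).
This vignette records the models, the conventions the package fixes where
the CIF ecosystem leaves latitude, and the reasoning behind the design
decisions, so that a maintainer can tell deliberate choice from accident.

## The syntax layer

CIF is a free-form, ASCII-only tag-value format: tags begin with an
underscore, white space delimits tokens, `loop_` introduces a table whose
rows interleave values in header order, and `data_` names a block.  Data
typing is purely lexical -- if a bare token looks like a number it is a
number, and a trailing parenthesised integer is a standard uncertainty
(su) in units of the place value of the last mantissa digit, so
`5.12(3)` means 5.12 +/- 0.03.

Conventions this package fixes:

* **Quote dialect.** Single quotes, double quotes and first-column
  semicolon text blocks, following classic CIF 1.1 practice.  A quote
  character closes a string only when followed by white space, so
  `'don't'` is the single token `don't`.
* **`?` and `.`** are modelled as distinct value kinds (*unknown* and
  *inapplicable*); their quoted forms are ordinary strings.  Both satisfy
  every dictionary value check, the conventional CIF reading.
* **Tags are case-insensitive** but stored as given; round trips preserve
  spelling exactly.
* **Duplicate tags are an error**, not last-wins: the package exists to
  validate files, so silent repair would defeat its purpose.
* **Number grammar.** Integer, decimal and exponential forms, with the
  su suffix accepted on all of them.  Accepting `1.2e3(4)` (su = 400) is
  an extension beyond what most writers emit; the lexer is total and
  never raises.
* The writer wraps at 80 columns where syntax allows and refuses
  non-ASCII content; there is no line-length limit on reading.  A value
  that cannot be quoted on one line (it contains both quote characters
  followed by spaces) is promoted to a text block; a text-block value
  containing a line that starts with a semicolon is not representable and
  is a write error rather than silent corruption.

## Dictionaries and validation

A dictionary is itself a CIF file; each block defines one or more tags
through a small bootstrap attribute set (`_name`, `_category`, `_type`,
`_units`, `_enumeration`, `_enumeration_range`, `_list`,
`_type_conditions`, `_definition`).  This is a deliberate reduction of
DDL1 to the attributes needed for type, units, enumeration, range and
list-context checking; unknown attributes are preserved but ignored, so
richer dictionaries still parse.  The attribute set is defined in its own
formalism in `ddl_bootstrap.dic`, which validates against itself with
zero violations -- the same bootstrapping closure that real CIF
dictionaries exhibit.  `_type_conditions su` (permission to carry a
standard uncertainty) is one attribute beyond the minimal set; it was
added so that the `missing-su-disallowed` check has a declarative source
rather than a hard-coded tag list.

Choices worth recording:

* **Ranges are closed.**  `_enumeration_range '0:180'` admits both
  bounds; either side may be empty.  The DDL1 literature is ambiguous
  here; closed intervals match how crystallographic limits (angles,
  occupancies) are quoted in practice.
* **Units are declarative only.**  Values are asserted to be in the
  dictionary's preferred unit; no conversion is ever attempted.
* Validation findings are data (ordered, stable, idempotent), never
  conditions; strict unknown-tag reporting is opt-in because responses
  (`_vrf_*`) and local extensions legitimately ride along in submissions.

## Geometry and symmetry

The cell is six numbers; its volume is
$V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
+2\cos\alpha\cos\beta\cos\gamma}$.
The fractional-to-Cartesian matrix uses the common crystallographic
convention (**a** along Cartesian *x*, **b** in the *xy* plane); its
determinant equals the volume, which the tests exploit by comparing
against an independently constructed basis with the *opposite*
convention (**c** along *z*) so that a shared formula error cannot
cancel.

Torsion angles follow the IUPAC right-hand convention with range
(-180, 180].  Note one property that is often misstated: reversing the
atom order *preserves* the signed torsion (tau(D,C,B,A) = tau(A,B,C,D));
it is mirror inversion that flips the sign.  The tests assert both.

Symmetry operators are parsed exactly from coordinate triplets
(`-x,y+1/2,-z+1/2`) into a rotation matrix and a translation reduced mod
1; formatting inverts parsing bit-for-bit, with translations rendered as
fractions up to denominator 24.  Site orbits deduplicate images under a
**minimum-image fractional metric with tolerance 1e-4** -- programs
genuinely disagree on special-position handling, so the rule is fixed,
exposed as a parameter, and the multiplicity is reported for exactly the
operator list supplied (no preferred-cell renormalisation).

The structure-factor sum $F(hkl)=\sum_j o_j f_j e^{2\pi i\,hkl\cdot x_j}$
runs over orbit-expanded, occupancy-weighted sites, with two documented
reductions: scattering factors are per-element constants (electron
counts by default) and no displacement damping is applied.  Orbit
expansion (rather than naive operator application) keeps special
positions from being double-counted, so F(000) equals the
occupancy-weighted atom count exactly.

## The derivation engine

Dictionary methods are represented as registered executable rules --
`cif_method(output, inputs, compute)` -- with the same resolution
semantics a dictionary-methods interpreter would provide: stored values
always win, missing items are derived recursively (memoised, and
registration rejects cycles), and failure names the missing leaf tags.
Interpreting actual method text embedded in dictionaries is out of
scope; the registry ships cell volume, reciprocal cell lengths, density
from formula weight and Z, and a structure-factor column for the
reflection loop (derived values may be whole loop columns, not only
scalars).  Standard uncertainties are *not* propagated through
derivations -- a documented limitation, not an oversight.

`check_consistency()` is a separate, opt-in pass that re-derives stored
items with the stored value set aside and reports relative discrepancies
above a tolerance (default 1e-6).  When stored and derived values
conflict, the package only ever reports; it never substitutes a derived
value for file content.

## Validation alerts and gating

`run_checks()` runs, in fixed order: completeness against a
journal-profile tag list, dictionary validation (class C), displacement-
ellipsoid elongation per anisotropic site, bond-length plausibility, and
disorder-assembly occupancy sums.  Alert codes follow the
`NAMEnnn_ALERT_t_S` shape familiar from checkcif output; the catalogue
here is the package's own, illustrative rather than a reproduction of
the real service's.

Parameters, all exposed in `default_check_config()`:

| parameter | default | meaning |
|---|---|---|
| `adp_ratio_B` / `adp_ratio_A` | 4 / 8 | Cartesian-U eigenvalue ratio raising a B / A elongation alert |
| `bond_tol` | 0.40 A | bond-perception tolerance over summed covalent radii |
| `bond_dev_C` / `bond_dev_B` | 0.15 / 0.30 A | deviation bands from the radius sum |
| `occupancy_tol` | 0.02 | allowed deviation of assembly occupancy sums from 1 |

The elongation thresholds are journal policy, not physics: no canonical
values exist, and 4/8 separates unremarkable thermal motion (ratios
around 2-3 in the generator's tensors) cleanly from the pathological
regime while remaining tunable per profile.  Solvent sites that are
deliberately left unrefined are skipped only when listed explicitly in
`excluded_labels`: recognising "solvent" automatically is a policy
heuristic the package refuses to guess at.

Gating is the submission rule: every class-A/B alert code must carry a
non-empty machine-readable author response (`_vrf_<CODE>` items in the
submission itself) before the file is admitted; class C never blocks.
Responses citing codes that raised no alert warn and are ignored.  The
truth table is tested exhaustively over severity and response
combinations.

## Connectivity

Two sites bond when their minimum-image separation (searching the 27
neighbouring cells, so strongly oblique cells are safe; optionally one
shell of symmetry images) is at most the sum of their covalent radii
(Cordero single-bond values) plus 0.40 A.  Bonds between different
disorder groups of one assembly are suppressed -- those sites are
alternative locations, not neighbours; an absent assembly label on both
sides means the default assembly, so bare groups still conflict.  All
inferred orders are `unassigned`: order perception from coordinates is
unreliable exactly where it matters (metal-organic complexes, polymers),
so assignment is left as an explicit editing step, and the connection
table written back into the CIF records `?` for such bonds.  Moieties
are connected components (via igraph), ordered largest-first; formulas
are Hill-ordered, occupancy-weighted counts.

## Implied semantics in article text

**Glossary annotation** scans left to right with a shrinking window
(four words, then three, two, one); the longest indexed phrase wins and
the scan resumes after it, so an indexed "space group" never degrades
into a bare "group" link.  Stop words suppress only window-1 matches.
Tokenisation splits on white space; punctuation is stripped at token
edges for matching while spans keep original character offsets (1-based,
half-open).  The annotator operates on plain text only -- skipping
already-linked HTML regions is out of scope.

**Geometry mentions** are typographic: chains of 2-4 atom labels
(`[A-Z][a-z]?[0-9]+'*`, primes included because disorder alternates are
conventionally primed) joined by `---`, em/en dash or hyphen, with
three dots marking non-bonded contacts, and an optional adjacent
`= value (su) unit`.  Typography alone is deliberately insufficient: a
mention becomes actionable only if its labels (forwards or reversed)
match a tabulated bond/angle/torsion/contact row of the same kind.
Unique matches bind directly; multiple matches (the same labels in two
structures of one article) are all returned, flagged ambiguous, for the
reader to choose.

## The fixture generator

`generate_structure()` builds a toy but internally consistent structure:
a carbon chain at ideal covalent geometry (C-C 1.52, C-O 1.43, C-H 1.09,
O-H 0.96 A, grown by internal-coordinate placement), a terminal hydroxyl
that can be split over a two-group disorder assembly (alternates about
0.6 A apart -- within bonding distance, so suppression is exercised), an
unbonded chloride counter-ion, anisotropic tensors of moderate
anisotropy (axis ratios up to 3, safely inside the alert threshold of
4) for three carbons, and a triclinic cell sized with enough buffer
(7 A in P1, 14 A in P-1) that periodic and symmetry images never touch.
All printed values are rounded *first* and every derived quantity (cell
volume, geometry tables) is recomputed from the printed values, so the
emitted file is self-consistent at full precision.  The same seed gives
a byte-identical file.

What the generator does **not** emulate: thermal-motion physics,
diffraction data, realistic packing, hydrogen-bond networks, charge
balance.  Passing checks on fixtures therefore demonstrates the
machinery (detection, gating, resolution), not chemical realism; on real
files the dictionary coverage and the alert catalogue would both need to
grow.

`inject_defect()` applies exactly one localised corruption per code
(elongated ADP, enumeration violation, type mismatch, missing required
tag, 10% volume inconsistency, shortened O-H bond), returning a
descriptor of the single finding the downstream module must raise, which
the tests match one-to-one.  `generate_article()` emits prose whose
geometry mentions are drawn from the block's own tables plus a decoy
chain absent from every table, so resolution precision and recall can be
scored exactly.

## Problem sizes and numerical tolerances

The test suite and `scripts/acceptance.R` use: 200 random documents for
round-trip identity; 1000 random cells for volume and metric-geometry
oracle agreement (1e-9 relative for volumes); 50 sites per operator set
for orbit/brute-force equality; 50 random reflections for Friedel and
centrosymmetry bounds (1e-10); fixtures of up to ~50 atoms for the
all-pairs bond oracle; and 50 article/table pairs for mention
resolution.  These sizes were chosen as the point where the properties
are exercised across the full parameter space while the whole suite
stays comfortably interactive.

## Known limitations

* CIF 2 / UTF-8 syntax, save frames and STAR extensions are out of
  scope, as are DDL2 relational features and dictionary method-text
  interpretation.
* su values do not propagate through derivations.
* The alert catalogue is illustrative; intensity-data checks are absent
  because no reflection data is in scope.
* Bond orders are never perceived automatically, and the package
  deliberately stops at the connectivity graph: a unique chemical
  description from crystal packing is an unsolved problem in the
  complicated cases.
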