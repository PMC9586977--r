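---
title: "Detecting and validating tandem BIR-like zinc-finger domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating tandem BIR-like zinc-finger domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldkit)
```

## The problem

The BIR (Baculovirus IAP Repeat) clan is a family of small Zn-binding
protein domains built around a Cys-Cys-His-Cys (CCHC) zinc finger and a
handful of conserved sequence anchors. Two clan members, the Pfam families
zf-C3HC and Rsm1, diverge from the canonical BIR domain in a way that is
almost invisible to profile-based sequence searches: the overall sequence
identity between family members is very low, and only a small set of key
residues is retained. In budding yeast, one zf-C3HC module and one Rsm1
module pack tightly, N- to C-terminally, into a single structural domain —
the Pml39 fold, named after the nuclear-basket protein that carries it —
and the same tandem architecture identifies structural orthologs in
fission yeast (Rsm1) and human (NIPA/ZC3HC1).

foldkit re-implements that identification pipeline as composable, tested R
functions: a spacer-aware motif grammar and scanner, an anchor detector, a
module classifier, a tandem-architecture caller with an 18-criterion
conservation checklist, coordinate-level validation (superposition, helix
tilt angles, Zn coordination, inter-module contacts), and the supporting
biophysics (single-site ITC fits, SEC-MALS Debye molecular weights).
Everything the pipeline consumes can be generated synthetically with known
ground truth, so each stage is testable end to end without external
downloads.

## The motif grammar

A CCHC zinc finger is written `C-x(a)-C-x(b)-H-x(c)-C`, where a spacer
counts the residues strictly between two Zn ligands (`spacer_length(i, j)
= j - i - 1`; between ligands at positions 137 and 172 there are 34
residues). The three families share the first two spacers and differ in
the last:

| family | C1–C2 | C2–H | H–C3 |
|---|---|---|---|
| canonical BIR | 1–3 | 10–160 | exactly 6 |
| zf-C3HC | 1–3 | 10–160 | exactly 3 |
| Rsm1 | 1–3 | 10–160 | exactly 3 |

The exact H–C3 spacer is the hard discriminator: 6 for canonical BIR, 3
for the two non-canonical families. The range defaults are deliberately
wide so that the grammar admits every published family member:

* **C1–C2 range 1–3, not exactly 2.** The human ortholog's zf-C3HC module
  pairs cysteines with a single intervening residue (a `C-x1-C`
  arrangement). Whether that spacing is typographical or genuine is
  unresolved; the grammar admits it, and the annotation records the
  spacer so non-canonical spacings remain visible to the user.
* **C2–H range 10–160.** Observed values run from 16 (canonical BIR and
  the reference Rsm1 module) through 34–37 (zf-C3HC modules) up to ~149
  (the human ortholog's Rsm1 module, which carries a ~135-residue
  insertion before the Zn-coordinating histidine).

`scan_znf()` enumerates *all* index quadruples satisfying the grammar;
overlap resolution is deliberately a separate, later concern so that the
scanner itself is trivially comparable against exhaustive enumeration (the
test suite does exactly that on 500 random sequences up to 200 residues).
`X` is tolerated in input but never matches a coordinating position, and
gap characters never satisfy any criterion.

## Anchors and module classification

Three anchors accompany the zinc finger in all clan members: the
`Rxx(S/T)Ω` motif in helix αA (Ω an aromatic, alphabet `{F, W, Y}` by
default; histidine is excluded), the invariant `GΩ` dipeptide in the turn
between helix αB and strand β1, and a final aromatic within three residues
after the last cysteine, which caps helix αB like a lid. `find_anchors()`
searches the nearest `Rxx(S/T)` upstream of C1 within a 100-residue window
(wide enough to span the long arginine-to-cysteine distances of Rsm1
modules, where an insertion intervenes; the exact window used in the
original analysis is not published, so it is a tunable argument), the
*last* `GΩ` between the arginine and C1, and the *first* aromatic after
C3. Absence of an anchor is a reported state, never an error — orthologs
are expected to have eroded anchors.

Classification of an `h_c3 = 3` match as zf-C3HC versus Rsm1 rests on the
one feature that separates them: the Rsm1 module carries an extra helix
(αAB′) and a Ser-rich insertion between the αA′ arginine and the `GΩ`
turn. The arginine-to-glycine distance is 29 in the reference zf-C3HC
module and 54 in the reference Rsm1 module, so the classifier uses a
threshold of 40 (configurable). When the arginine anchor is missing the
distance cannot be formed; the fallback then calls Rsm1 when the C2–H
spacer alone exceeds the same threshold, which captures orthologs whose
insertion sits before the histidine while leaving compact zf-C3HC modules
(C2–H of 33–37) untouched.

Overlapping module candidates are resolved greedily: highest conservation
score first, ties broken by the smaller C1 index — the checklist is the
evidence standard, so it also arbitrates overlaps. The module span runs
from the arginine anchor (or `C1 - 45` when absent, the anchor offset of
the reference fold) to the final aromatic plus a 15-residue tail
(bracketing the 11–17-residue carboxy-terminal extents of the two
reference modules).

`detect_pml39_fold()` requires the native N→C order: a zf-C3HC module
whose span ends before the first cysteine of a downstream Rsm1 module.
All three known carriers of the fold share this order, so a reversed
arrangement is reported but not called a fold.

## The conservation checklist

Candidate orthologs are scored against 18 criteria — 9 per module: the
arginine anchor, Ser/Thr at arginine + 3, the `GΩ` dipeptide, the four Zn
ligands with family-consistent spacing, the exact 3-residue H–C3 spacer,
and the post-C3 aromatic. Criteria are evaluated independently, which
makes the score monotone under information removal: deleting or mutating
one mapped residue can only lose the criteria that reference it. The
package ships reference residue maps for the three known carriers of the
fold; all three score 18/18.

## Coordinate-level validation

* **Superposition** is the closed-form Kabsch fit (SVD of the
  cross-covariance with reflection correction), validated in the tests
  against a brute-force numerical minimiser over rotations and against an
  independent established implementation. Collinear point sets and fewer
  than three pairs are rejected.
* **The Cα pairing is an explicit input** to `superpose_modules()`. The
  residue pairing behind the published module-versus-BIR superposition is
  not itself published; making the pairing a first-class argument lets
  users reproduce and compare alternatives instead of trusting a hidden
  alignment.
* **Helix axes** use the bisector cross-product construction: the
  bisector at each interior Cα points radially at the helix axis, and
  consecutive bisectors' cross products are exactly parallel to the axis
  for an ideal helix of any length. We chose this over the principal axis
  of inertia because the inertia axis of a short helix with an incomplete
  final turn is biased by a few degrees (about 2.3° for a 12-residue,
  3.3-turn helix), which would swamp the 1° recovery accuracy the package
  promises for 5–16-residue helices. A principal-axis fallback handles
  degenerate, nearly straight traces. Axes are oriented N→C.
* **Tilt angles** default to the unsigned convention `arccos(|a·b|)` in
  [0°, 90°], matching how inter-helix tilts are conventionally reported
  without sign; a signed variant ([0°, 180°]) is available by flag.
* **Zn coordination** uses a 2.8 Å cutoff (a typical upper bound for
  Zn–S/N bonds; configurable) over cysteine Sγ and histidine Nδ1/Nε2
  donors, and reports the ligand count as found even when it is not 4.
* **Interface contacts** report all inter-span residue pairs with minimum
  heavy-atom distance ≤ 4.5 Å. Hydrophobicity is a fixed residue set
  `{A, V, L, I, M, F, W, Y, P}`, not a numeric scale — the published
  interface description is qualitative.
* Coordinate handling keeps alternate location A only, drops waters,
  ignores hydrogens, and retains but flags occupancy < 0.5 atoms.

## The ITC model

The single-site isotherm is modelled as exact 1:1 mass action in a
perfusion-type cell. Each injection of volume *v* into the active volume
*V₀* first displaces an equal volume of the instantaneously mixed cell
content, then the cell re-equilibrates:

* totals after mixing: `X ← (X·V₀ + Xs·v)/(V₀+v)`, `M ← M·V₀/(V₀+v)`,
* bound complex `B` from the quadratic
  `B² − (nM + X + K_D)·B + nM·X = 0` (numerically stable smaller root),
* measured heat `q = ΔH · V₀ · (B − B_prev·V₀/(V₀+v))`.

This bookkeeping conserves titrant moles exactly (in-cell + displaced =
injected, verified to 10⁻¹² relative in the tests) and agrees with an
independent root-finding equilibrium solver to better than 10⁻⁹ relative.
In the infinitely tight limit the model predicts constant heats of
`ΔH · (moles injected) · V₀/(V₀+v)` until saturation — the `V₀/(V₀+v)`
factor is the displaced fraction of each injection, a real feature of
perfusion cells rather than a modelling artefact.

The default protocol mirrors the published experiment: 2 µL injections of
1.6 mM titrant into 350 µL of 70 µM cell species at 277.15 K. The number
of injections is not printed in the source protocol; the default of 20
reaches a final molar ratio of ≈ 2.6, the span a standard automated
titration covers, and is configurable. The cell species is the dimeric
binding partner, matching the 1:1 stoichiometry convention under which
the published value is reported.

`fit_itc()` runs Levenberg–Marquardt least squares over
`(log n, log K_D, ΔH)` — the log parameterisation enforces positivity —
from a multi-start grid (n ∈ {0.5, 1, 2}, K_D log-spaced 10⁻⁸–10⁻³ M, ΔH
seeded from the first-injection heat); the grid is screened by residual
sum of squares and the best three starts are polished. ΔG and TΔS are
then *computed*, not fitted, from the identities ΔG = −RT ln(1/K_D) and
TΔS = ΔH − ΔG with R = 1.99 cal (mol K)⁻¹ at the experiment temperature,
so the thermodynamic decomposition always satisfies both identities to
machine precision. A constant heat-of-dilution offset can optionally be
fitted (off by default; synthetic data has none). Non-convergence across
all starts yields a flagged fit with a warning, not an error.

The package's simulation study (100 replicates, 2% Gaussian heat noise,
the default protocol, planted K_D = 13 µM and n = 1) is what
`scripts/acceptance.R` reruns; the binding enthalpy is not printed in the
source and is set to a typical exothermic −10 kcal mol⁻¹ — it scales the
heats but does not move the K_D or n recovery. Noise is parameterised as
a fraction of the largest absolute predicted heat, so "2% noise" is the
same absolute perturbation on every injection.

## SEC-MALS molecular weights

In the dilute limit (second virial coefficient neglected) the Debye plot
`K·c/R(θ)` versus `sin²(θ/2)` has intercept 1/M. `debye_mw()` fits each
elution slice by ordinary least squares, takes the reciprocal intercept
as the slice mass, flags and excludes slices with non-positive intercepts,
and averages over each peak window weighted by concentration. Instrument
calibration constants and dn/dc (0.185 mL/g is the conventional protein
value) are folded into the optical constant `K` supplied with the data;
the result is invariant to any consistent rescaling of `K` and `R(θ)`,
and independent of the angle set when the planted angular dependence is
zero — both properties are asserted in the tests. `oligomeric_state()`
divides a measured mass by the sequence monomer mass and calls the
nearest integer within a 15% tolerance (ambiguous otherwise), the
rule by which an ~80 kDa measured species of a 41 kDa monomer is called
a dimer.

## What the synthetic data does and does not emulate

The generators plant exactly the features the analyses consume: motif
architectures at known positions, ideal helices at known angles,
tetrahedral Zn sites, 1:1 isotherms, Gaussian elution peaks. Two
deliberate simplifications matter for interpreting green tests:

* **Sequence background** is drawn from an alphabet that excludes every
  anchor-forming letter (C, H, R, G, S, T, F, W, Y), so planted-truth
  recovery is exact by construction. Real sequences contain decoy
  cysteines and arginines; `realistic_background = TRUE` re-enables the
  full alphabet for stress testing, and the scan-versus-enumeration
  property is tested on full-alphabet random sequences. Passing tests
  show the machinery is correct, not that the grammar's false-positive
  rate on real proteomes is low — measuring that would need a proteome
  survey, which is out of scope.
* **Synthetic structures** are Cα traces and isolated coordination
  shells, not packed domains: helix-tilt and contact tests validate
  geometry operations, not the biological realism of any particular
  fold model. Validation against the deposited crystal structure and its
  canonical BIR comparators is implemented (see
  `tests/testthat/test-acceptance.R`) but requires the PDB entries, which
  are not redistributed with the package; the corresponding test states
  the published expectations (2.4 ± 0.3 Å module RMSD, 42°/26° helix
  tilts, the two Zn ligand quadruples, the nine interface residues) and
  fails cleanly when the coordinate files are absent.

All generators require an explicit seed and are byte-reproducible from
it; all noise is Gaussian.

## Problem sizes used in the shipped validation

The test suite runs the scanner against exhaustive enumeration on 500
random sequences of 50–200 residues; the ITC study uses 100 simulated
titrations of 20 injections; helix and Zn-site properties are checked
over 100 seeds; the MALS traces hold 18 detector angles at 1-second
slices. These sizes were chosen to exercise every code path at the scale
of the corresponding published experiments.

## Known limitations

* No HMM/profile training and no database queries: the grammar encodes
  the clan's consensus directly, which is the point, but also means the
  scanner inherits the consensus's blind spots.
* Helix spans are inputs (defaulting to published spans where relevant);
  the package does not assign secondary structure.
* The ITC model is strictly 1:1; no multi-site, cooperative or
  displacement titrations.
* The Debye analysis neglects the second virial coefficient and any
  angular dependence — appropriate for small globular proteins at
  SEC-MALS concentrations, wrong for large or elongated scatterers.
* Instrument raw files (power traces, baseline integration) are out of
  scope; heats enter as baseline-corrected per-injection values.

## A worked example

```{r example, eval = FALSE}
# plant a tandem fold and call it
ts <- sim_tandem_sequence(seed = 42)
calls <- detect_pml39_fold("demo", annotate_modules(ts$sequence))
calls[, c("is_pml39_fold", "satisfied_count", "total")]

# score a candidate ortholog's residue map
ortholog_checklist(sprsm1_residue_map())

# fit a noisy synthetic titration and plot it
fit <- fit_itc(sim_itc(seed = 1, noise_sd = 0.02))
glance(fit)
autoplot(fit)
```
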