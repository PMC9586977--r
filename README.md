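# foldkit

Detection and validation of tandem BIR-like zinc-finger domains in R.

## The problem

The BIR (Baculovirus IAP Repeat) clan of Zn-binding domains includes two
families — zf-C3HC and Rsm1 — whose members retain almost nothing of each
other at the sequence level except a CCHC zinc finger and a few anchor
residues. One zf-C3HC module followed by one Rsm1 module packs into a
single structural domain (the *Pml39 fold*, after the budding-yeast
nuclear-basket protein that carries it), and recognising that tandem
architecture is how structural orthologs such as fission-yeast Rsm1 and
human NIPA/ZC3HC1 are identified despite negligible sequence identity.
foldkit is for structural bioinformaticians who want that identification
pipeline as composable, tested functions rather than a one-off analysis.

## What it computes

* **Motif grammar and scan** — the clan's zinc finger is
  `C-x(a)-C-x(b)-H-x(c)-C` with spacers counted strictly between ligands;
  `x(c)` is exactly 6 for canonical BIR and exactly 3 for zf-C3HC/Rsm1,
  while `x(a)` ∈ 1–3 and `x(b)` ∈ 10–160 admit every published family
  member. `scan_znf()` reports every quadruple satisfying a family
  grammar; `find_anchors()` locates the `Rxx(S/T)Ω` motif, the `GΩ` turn
  dipeptide and the post-finger aromatic around each match.
* **Fold calling** — `classify_module()` separates zf-C3HC from Rsm1 by
  the arginine-to-`GΩ` distance (the Rsm1 module carries an insertion
  there); `detect_pml39_fold()` requires the native N→C tandem order;
  `ortholog_checklist()` scores candidates against 18 conservation
  criteria (9 per module).
* **Structural geometry** — Kabsch superposition (SVD with reflection
  correction), helix axes by the bisector cross-product construction,
  unsigned inter-helix tilt angles, Zn coordination spheres (2.8 Å
  cutoff over Cys Sγ / His Nδ1/Nε2), and inter-module heavy-atom
  contacts (4.5 Å) with hydrophobicity flags.
* **Biophysics** — exact 1:1 mass-action ITC isotherms with
  per-injection displacement bookkeeping, multi-start Levenberg–Marquardt
  fits of (n, K_D, ΔH), and the identities ΔG = −RT ln(1/K_D),
  TΔS = ΔH − ΔG (R = 1.99 cal mol⁻¹ K⁻¹); SEC-MALS molecular weights
  from the Debye plot `KC/R(θ)` vs `sin²(θ/2)` with concentration-weighted
  peak averages and integer oligomeric-state calls.
* **Synthetic data** — seeded generators for every input class
  (sequences with planted motifs, ideal helices at known angles,
  tetrahedral Zn sites, noisy isotherms, MALS traces), each emitting its
  ground truth.

Functions take data frames (or paths to standard formats: FASTA,
PDB/mmCIF, CSV + YAML) and return tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(foldkit)

# plant a tandem zf-C3HC + Rsm1 architecture and call it
ts <- sim_tandem_sequence(seed = 42)
detect_pml39_fold("demo", annotate_modules(ts$sequence))
#>   sequence_id is_pml39_fold zf_start zf_end rsm1_start rsm1_end satisfied_count
#> 1        demo          TRUE       11    115        141      247              18

# score the human ortholog's residue map against the 18 criteria
ortholog_checklist(hsnipa_residue_map())
#> Ortholog conservation checklist: 18/18 criteria met

# fit a noisy synthetic titration (true K_D 13 uM, n = 1, dH = -10)
fit <- fit_itc(sim_itc(seed = 1, noise_sd = 0.02))
fit
#> single-site ITC fit:
#>   n    = 0.982
#>   K_D  = 13.22 uM
#>   dH   = -10.12 kcal/mol
#>   dG   = -6.20 kcal/mol
#>   -TdS = 3.92 kcal/mol
#>   rmse = 0.464 ucal

# molecular weight of a simulated 80 kDa SEC-MALS peak, and its state
m <- sim_mals(1, species = list(list(mw = 8e4, center = 100, width = 5,
                                     cmax = 1e-4)), noise = 0.01)
debye_mw(m$slices, m$peaks)
#> Debye-plot molecular weights (31 slices):
#>   peak 1 [90, 110]: 80.1 kDa over 21 slices
oligomeric_state(8e4, 4.1e4)
#> [1] 2
```

The fold call reports where each module sits and how many conservation
criteria the pair satisfies; the ITC fit recovers the planted binding
parameters with the thermodynamic decomposition computed from the stated
identities; the Debye analysis recovers the planted mass within the noise
and calls the 80/41 kDa pair a dimer.

A thin command-line wrapper is installed with the package
(`system.file("cli", "foldkit", package = "foldkit")`) with `run`, `scan`
and `fold-call` subcommands over the same functions.

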