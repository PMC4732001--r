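---
title: "Evidence-weighted candidate ranking from tandem mass spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-weighted candidate ranking from tandem mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrank)
```

## Scope and model

`fragrank` ranks candidate structures for an unknown measured by
high-resolution MS/MS. The candidates come from a local database (CSV or
SDF) selected by neutral monoisotopic mass, molecular formula or
identifier; the ranking combines several independent evidence terms into a
weighted sum. This vignette records the model, its assumptions, and the
design decisions that were genuinely open when the package was built.

### Combinatorial fragmentation

Fragmentation is modelled as successive removal of heavy-atom bonds from
the candidate's bond graph, up to `MaximumTreeDepth` removals (default 2).
Hydrogens are implicit per-atom counts, never graph nodes, so C–H bonds are
never cleaved; cleaving an acyclic bond splits a fragment in two, while
removing a ring bond yields an opened-ring intermediate with the same atom
set. Fragments are stored as index sets over the parent's atoms and bonds
together with the cumulative bond dissociation energy (BDE) of the bonds
cleaved along the path that produced them, which makes mass and formula
computation a simple sum over retained atoms and keeps memory linear in the
number of distinct fragments.

Three decisions here were interpretation calls:

* **Opened-ring intermediates are not matchable.** Their neutral mass
  equals their ancestor's, so emitting them would only duplicate peaks
  already explained; they do count against the tree depth, because the
  depth counts bond removals, and they are fragmented further.
* **Duplicate fragments keep the cheapest path.** The same (atom set, bond
  set) can arise through different removal orders with different cumulative
  energies; only the minimal energy can matter downstream, because the
  matcher always prefers the lowest-denominator fragment.
* **The BDE table** ships as an editable text file of mean bond enthalpies
  (kJ/mol) for single/double/triple bonds among H, C, N, O, F, P, S, Cl,
  Br, I; aromatic bonds use the mean of the pair's single and double
  entries and unknown pairs fall back to 348 kJ/mol (the C–C single
  value). Published tables of the method do not include the energy values,
  and because the fragmenter score is normalized within the candidate
  list, ranking is insensitive to the absolute scale; only relative
  cleavage costs matter.

### Peak matching

A peak at m/z `m` matches a fragment when the fragment's theoretical ion
m/z lies within `m · ppm · 1e-6 + Da` of it (additive relative and
absolute deviations, defaults 5 ppm and 0.001 Da, matching modern Orbitrap
practice). The theoretical ion m/z adds the precursor type's adduct mass
(electron mass folded in; ten singly charged types from [M+H]+ to
[M+CH3COO]- are supported) and an optional hydrogen shift. The default
shift set {−1, 0, +1} hydrogen atoms accommodates homolytic versus
heterolytic cleavage; it is configurable (`HydrogenShifts`), and the
synthetic evaluation below uses {0}. Each peak receives at most one
fragment: the one with minimal cumulative BDE, ties broken by smaller
absolute hydrogen shift, then smaller fragment mass, then generation
order — fixed tie-breaks keep runs bit-reproducible.

### Scoring terms

The fragmenter score is
`Σ_p RelMass_p^α · RelInt_p^β / (Σ_b BDE_b)^γ` with α = 1.84, β = 0.59,
γ = 0.47. The literature on this score family does not pin down the two
relative quantities, so the package defines them explicitly:
`RelMass_p` = peak m/z divided by the precursor *ion* m/z, and
`RelInt_p` = peak intensity divided by the spectrum's base-peak intensity.
Both lie in (0, 1], which bounds each peak's numerator at 1 and makes the
unit-input sanity case (RelMass = RelInt = ΣBDE = 1) score exactly 1.

Auxiliary terms:

* **Retention time.** Ordinary least squares calibrates
  `logP = a · RT + b` on user-provided training pairs (at least two
  required; fewer than ten warns, since sparse calibrations extrapolate
  badly). A candidate scores the Gaussian density, σ = 1.5 logP units by
  default, of `|logP_pred − logP_cand|`. σ is deliberately wide: logP
  predictions routinely err by a log unit. The candidate logP comes, in
  priority order, from a configured property column (e.g. `UserLogP`),
  else from the internal atom-contribution descriptor; the fitted model is
  tagged with its source and refuses candidates tagged otherwise, because
  mixing predictors invalidates the calibration.
* **References.** Selected per-source counts (e.g. patent and literature
  counts) are summed with unit selector weights and normalized; missing
  values count as zero (absent means unreferenced).
* **Substructures.** Each SMARTS pattern contributes at most 1 per
  candidate — presence, not occurrence count — so a candidate with two
  ethylamino groups still scores a single hit for the ethylamino pattern;
  overlapping patterns count independently. Exclusion scores invert the
  count against the pattern-list size.
* **Suspects.** Binary flag on InChIKey first-block membership in a user
  list; first blocks encode connectivity without stereochemistry.
* **User columns.** Any numeric column of a (re-imported, pipe-separated)
  results table can be declared a term; it is normalized and weighted like
  the built-ins, which is how externally computed probabilities or logD
  models enter.

Every term is normalized to the candidate-list maximum (zero lists stay
zero), so adding a candidate can lower but never raise the others'
normalized terms. Raw values are always emitted next to normalized ones so
the provenance of a ranking remains inspectable.

### Filters, deduplication and evaluation

The pipeline order is fixed: select → unconnected filter → element filter
(`only` / `must` / `exclude` modes) → SMARTS inclusion/exclusion filter →
suspect inclusion filter → fragmentation and scoring → normalization →
weighted combination → stereoisomer deduplication → ranking. Structural
filters run before fragmentation because they are cheap; deduplication
runs after scoring because it must keep the *best-scoring* stereoisomer
per InChIKey first block (score ties broken by ascending identifier).
Tautomers with differing first blocks are not collapsed.

For evaluation against known answers the package reports pessimistic ranks
(worst position within a score tie), expected ranks (uniform random
tie-breaking: strictly-better count plus half the tie group plus one
half), and the relative ranking position
`0.5 · (1 + (worse − better)/(n − 1))`, oriented so 1 is best. The RRP
formula itself is not printed in the sources that cite it; the
implementation follows the cited definition. Expected top-k counts
threshold the expected rank directly; fractional-credit accounting was
considered and not adopted. Weight exploration draws uniformly from the
weight simplex via sorted-uniform spacings (a flat Dirichlet), seeded.

## The synthetic-data generator

No external database or spectral library is available to tests, so the
`fixtures` layer builds everything: a deterministic ~34-molecule library
(isomer groups sharing an exact mass, a stereo pair, sulfonic
acids/esters for substructure work, one salt), simulated spectra, decoys,
retention training sets and reference counts. Design choices:

* **Decoys** emulate exact-mass database retrieval: 3–8 accepted random
  perturbations (degree-preserving bond rewires and element-label swaps)
  of the truth, each constrained to preserve the molecular formula, stay
  connected, and land on a new InChIKey first block. A single perturbation
  step proved too gentle — one-edit decoys share nearly all fragment
  masses with the truth and no scoring scheme could separate them — while
  several steps yield the structural diversity real isomer lists show.
  Decoys are chemically unreviewed graphs (the point is mass-identical
  confounders, not synthesizable molecules) and are labelled synthetic.
* **Spectra** sample distinct fragment neutral masses of the truth at the
  configured depth (default 8 signal peaks), apply the precursor adduct,
  Gaussian m/z jitter (default 0.0002 Da, far inside the matching
  tolerance) and uniform intensities, then add noise peaks at uniform
  random m/z that avoid ±0.02 Da windows around any theoretical fragment
  ion. Simulated ions carry no hydrogen rearrangements, so the synthetic
  end-to-end study matches with `HydrogenShifts = 0`; the real-data
  default remains {−1, 0, +1}.
* **Retention training** inverts the true line `logP = a·RT + b`
  (defaults a = 0.35 logP/min, b = −1, roughly a 15-min reverse-phase
  gradient spanning logP −1…4) at the structures' computed logP values and
  adds Gaussian noise (default 0.3) to the *reported logP*, modelling
  prediction error. Putting the noise on the retention times instead would
  make RT an error-laden regressor and bias the slope (errors in
  variables), which is neither how the calibration errs in practice nor
  compatible with standard-error-based recovery checks.
* **Reference counts** are Poisson (mean 20) for decoys with the truth
  boosted fivefold — a caricature of the empirical pattern that true
  positives in screening tend to be well-referenced compounds.
* All randomness derives from one master seed through fixed per-stage
  offsets, so each stage reproduces in isolation.

What passing the synthetic suite does **not** show: performance on real
spectra (no rearrangement chemistry, no collision-energy-dependent
intensities, no isotope patterns, no co-eluting interferences), behaviour
at database scale (tens of candidates, not thousands), or the calibration
quality of any particular logP predictor. The problem sizes used — 50
seeded cases of a truth plus 10 decoys at tree depth 2, 20 retention
calibrations at n = 50 — were chosen so the whole validation runs
comfortably on a laptop while still exercising every pipeline stage.

## Numerical and degenerate-input policy

* Masses come from an embedded monoisotopic isotope table; mass arithmetic
  is plain double sums, reproducible bit-for-bit, and agrees with the
  chemistry toolkit to 1e-4 Da on the shipped library.
* Normalization guards all-zero term lists (scores stay 0 rather than
  NaN); the exclusion score likewise guards a zero maximum.
* Candidates with net formal charge are rejected at load (retrieval is
  defined on neutral molecules); disconnected candidates are an error for
  the fragmenter and must be filtered first.
* An empty post-filter candidate list is a warning plus an empty result,
  not an error — in screening workflows an empty answer is an answer.
* Identifier-based queries lack a precursor mass; the relative-mass scale
  is then anchored on the median mass of the selected candidates.
* Metals never carry implicit hydrogens; implicit hydrogen counts
  otherwise follow smallest-sufficient standard valences with formal
  charge adjustments.

## Known limitations

Rearrangement reactions and neutral-loss rules are out of scope, as are
multiply charged ions and isotopologue peaks within MS/MS. The BDE table
is a coarse mean-enthalpy model, not a quantum-chemical one. Online
database retrieval is declared in the parameter dialect but deliberately
stubbed: runs are local and offline by construction.
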