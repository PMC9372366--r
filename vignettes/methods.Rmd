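---
title: "Allele-specific HLA surface accessibility: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific HLA surface accessibility: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowflake)
```

## The problem

Antibody-mediated rejection in solid-organ transplantation is driven by
recipient antibodies against mismatched donor HLA. An antibody can only engage
an amino-acid difference it can physically reach, so mismatch scoring should be
restricted to solvent-accessible positions — and accessibility is not a
property of a position in general but of the specific allele carrying it: a
residue exposed on one HLA Class I protein may be buried on another. This
package implements that idea end to end: compute per-residue
solvent-accessible surface area (SASA) from 3D structures, learn a
sequence-to-accessibility map so that accessibility can be inferred for the
thousands of alleles without structures, and count donor mismatches only at
positions that are accessible *on the donor allele* (the Snowflake epitope
mismatch score).

## Structure intake

Structures arrive as PDB files. A usable Class I structure has an alpha chain
(`A`), beta-2-microglobulin (`B`, checked against the mature P61769 sequence)
and a third chain (`C`); any extra chain of 8–11 residues is taken as the
bound peptide. The alpha chain is aligned against an allele database and kept
only when the best local-alignment raw score exceeds a cutoff (default 1300,
the intake cutoff for full-length Class I chains). The original pipeline used
BLAST for this step; here the same cutoff semantics are provided by
Smith–Waterman with BLOSUM62 and gap open/extend 11/1 — the standard
protein-BLAST penalties — so no external binary is needed and the threshold is
configurable for corpora of different lengths. Allele names are assigned by
maximum identity, ties broken by the lowest database identifier, which makes
assignment deterministic across database orderings.

Two further tolerances are deliberate choices rather than published values:
the B2M chain is accepted at ≥ 95% identity (engineered tags and point
mutants occur in deposited structures), and the residue-to-position mapping
fails below 80% identity, which in practice signals a wrong allele assignment
rather than a noisy structure. All positions are expressed in the mature
protein frame (signal peptide removed), the coordinate system eplet names such
as 127K use.

## Structure comparison without superimposition

Comparing structures by Euclidean distances requires superimposition and lets
a single hinge motion inflate distances at every downstream residue. Backbone
torsion angles avoid both problems. For two structures *a*, *b* and shared
position *i*:

- SDA_i = (φ_ai − φ_bi)² + (ψ_ai − ψ_bi)²
- RMSDA = sqrt( (1/2n) Σ_i SDA_i ) — an average over the 2n angle pairs, in degrees
- SSA_i = (SA_ai − SA_bi)²
- RMSSA = sqrt( (1/n) Σ_i SSA_i ) — the functional, surface-area counterpart

Angle differences are wrapped into (−180°, 180°] by default: a φ of 179° and
one of −179° are 2° apart, not 358°, and without wrapping the seam would
contribute a spurious ~129,000 deg² to SDA. A raw mode is retained for strict
formula replication. Positions missing either angle in either structure
(chain termini, unresolved backbone atoms) are excluded and *n* reduced;
the terminal residues of any chain necessarily lack φ (first) and ψ (last).

## Solvent-accessible surface area

SASA uses the Shrake–Rupley construction: each atom's sphere is inflated by
the probe radius (1.4 Å, a water molecule), test points are distributed
quasi-uniformly on it, and the accessible fraction is the share of points not
inside any neighbouring inflated sphere. Numerical choices:

- **Test points**: a golden-spiral lattice, 960 points by default
  (~1.3% error on an isolated atom). Cross-validation against the independent
  Monte-Carlo estimator uses 3840 points, where the worst per-atom deviation
  on random clusters drops below 1%.
- **Radii** (Å): C 1.70, N 1.55, O 1.52, S 1.80; hydrogens (1.20) are excluded
  by default since crystal structures rarely resolve them. The table is an
  argument, not a constant.
- **Neighbour search**: a spatial grid with cell size 2·max(r_vdw + probe);
  the grid prunes candidates only, so gridded and brute-force results are
  bit-identical.
- **Rotation sensitivity**: the point lattice is fixed in space, so
  translating a molecule changes nothing, while rotating it perturbs areas at
  the lattice resolution (≲ 0.5% at 960 points). This is a property of every
  deterministic Shrake–Rupley implementation, and the package's tests check
  translation invariance exactly and rotation stability at that resolution.

Alpha-chain residue areas are computed with beta-2-microglobulin and the
bound peptide present, so positions pressed against B2M or the peptide groove
come out small — occlusion by a partner chain can only reduce a residue's
area, never increase it. Per-residue area is the plain sum over the residue's
atoms in Å²; no reference-state normalisation is applied, because the
predictor's targets are capped and scaled instead (below).

## The accessibility predictor

The predictor maps a one-hot encoded alpha-chain sequence (20 amino acids +
one unknown channel) to per-position accessibility. The architecture is three
stacked bidirectional LSTM layers of 100, 64 and 32 units with rectified
linear activations and a linear output head. Targets are raw residue areas
capped at 100 Å² — roughly the 85th percentile of per-residue areas, so
protruding residues do not dominate the loss — then divided by 100 into
[0, 1]. Training minimises mean squared error over observed positions with
Adam.

Decisions the published description leaves open, fixed here:

- **Loss and masking**: MSE over unmasked positions. Sequences are padded to
  the longest training sequence; padded positions carry the recurrent state
  through unchanged and never enter the loss. Structure-derived targets are
  placed via the residue-to-position map and unresolved positions are masked.
- **Optimiser settings**: learning rate 1e-3, batch size 16, 400 epochs as
  package defaults. Gradients are clipped to a global norm of 5: with ReLU
  cell activations the cell state is unbounded above and an early oversized
  step can overflow; clipping removes that failure mode without affecting
  converged fits.
- **Each (structure, peptide) pair is one sample**, so peptide-specific
  occlusion differences enter as target noise for the same sequence — the
  model learns the average context rather than one peptide's shadow.
- **Determinism**: initialisation (Glorot uniform, forget-gate bias 1) and
  batch order derive from a single seed; identical data and seed give
  identical loss traces.
- **Output**: the linear head can overshoot [0, 1] slightly; predictions are
  clipped on output before any matching or classification.

The implementation (forward pass, backpropagation through time, Adam) is
written in R with BLAS-backed matrix operations; the network is small enough
that a full desk-scale training run takes minutes on one CPU. The gradients
are verified against numerical differentiation in the test suite.

### What the synthetic generator emulates — and what it does not

Because real training corpora (PDB structures, peptide-docking output) are
external, the package ships a generator that produces the same *shapes* of
data: ideal-geometry backbones with prescribed (φ, ψ) for the dihedral
oracle, random atom clusters with a brute-force Monte-Carlo SASA oracle, and
allele families — one base sequence, a handful of polymorphic positions with
2–4 variants each, loci rotating over A/B/C, identifiers assigned in order.
Ground-truth accessibility for a family is a deterministic function of each
residue and its two neighbours, drawn once from a seeded lookup: local enough
for a bidirectional recurrent network to represent exactly, allele-specific at
polymorphic positions. Parameter recovery on this rule (held-out MSE < 0.01,
Pearson r > 0.95 at 100 epochs, learning rate 0.01, batch 8 — settings chosen
for the 40-sequence regime; the production-scale defaults above are
unchanged) demonstrates that the training machinery works, **not** that the
predictor reaches any particular accuracy on real HLA structures: the
synthetic rule is strictly local and noise-free, whereas real accessibility
depends on long-range fold context and experimental variation.

Desk-scale problem sizes used throughout the tests and the acceptance script:
families of 12–40 alleles of length 30–60, clusters of 5–10 atoms, backbones
of 10–12 residues, 10⁵ Monte-Carlo directions per atom.

## Cross-predictor comparison

Third-party per-position accessibility tables (NetSurfP-like already in
[0, 1]; PaleAle-like percentages divided by 100) are parsed into the same
profile container. Profiles are mean-centered before pairwise comparison so
systematic offsets between predictors do not dominate; squared error is
reported per position and as the mean. A position is *accessible* for a
predictor when its score strictly exceeds that predictor's own mean — on a
constant profile nothing is accessible.

## Mismatch scoring

For each distinct donor allele, positions whose predicted accessibility
strictly exceeds the threshold are compared against the recipient: a position
mismatches when the donor residue does not occur at that position in any
reference allele. `intralocus` mode references recipient alleles of the donor
allele's locus; `interlocus` references all recipient Class I alleles — since
the interlocus reference set is a superset, its score can never exceed the
intralocus score. The default threshold is the donor allele's own mean
predicted accessibility, the same baseline as the classification rule; it is
a parameter, as is the mode. Further conventions: duplicate donor alleles
(homozygotes) are scored once; unknown residues (`X`) are skipped, never
counted as mismatches; raising the threshold can only remove positions, so
the score is monotone non-increasing in the threshold.

Eplet definitions (1–3 (position, residue) components) are profiled across
carrier alleles: for each component, the distribution of predicted
accessibility over the alleles that carry the full eplet. Distributions are
summarised into three patterns — consistently accessible (all component
medians high, spreads tight), partially accessible (at least one high-median
component), variable (any component with interquartile range at or above the
spread cutoff) — with defaults high = 0.5 and spread = 0.25; the published
taxonomy is qualitative, so the cutoffs are explicit parameters.

## Known limitations

- The alignment scorer reproduces the *semantics* of the published intake
  cutoff, not BLAST bit-for-bit; corpora of short chains need a proportionally
  lower threshold.
- Shrake–Rupley areas are lattice-resolution approximations; see the rotation
  note above.
- The predictor's accuracy guarantees are demonstrated on synthetic families
  only; real-structure accuracy depends on corpus size and diversity.
- Matching assumes all profiles and sequences share the mature-protein frame;
  no haplotype imputation, Class II chains, or antibody-assay integration is
  provided.
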