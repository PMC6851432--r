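---
title: "Torsion-space assessment of template-based protein models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-space assessment of template-based protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbmtools)
```

# Scope and model

Cartesian fold metrics (GDT, lDDT and relatives) saturate as predicted
models converge on the right fold: many models place most Cα atoms
acceptably while still disagreeing with the target in the fine degrees
of freedom that determine chemistry — the backbone torsions φ, ψ, ω and
the sidechain torsions χ₁, χ₂.  This package scores those degrees of
freedom directly, and adds the two downstream perspectives that matter
to structural biologists consuming predictions: whether a model (with
its self-estimated coordinate errors) is useful as a molecular
replacement (MR) search model, and whether the experimental template a
prediction started from deserved trust at all.

## Torsion comparison

Every angular deviation Δ is mapped through the chord-length score
Γ(Δ) = (1 − cos Δ)/2, the squared chord subtended on the unit circle,
normalized to [0, 1].  Unlike |Δ| it is smooth at 0 and 180°, and
small deviations — abundant, and often within experimental uncertainty —
are correspondingly discounted.

The backbone score of a residue is the mean of Γ over the defined
subset of {Δφ, Δψ, Δω}.  We renormalize over the defined subset rather
than dropping terminal residues: termini lack φ/ω by construction, and
discarding them would silently shrink coverage.  ω is attributed to the
residue whose N participates in the peptide bond (ω(i) spans
CA(i−1)–C(i−1)–N(i)–CA(i)), the common convention that a residue's ω
describes its preceding peptide.  Γ(Δω) enters the backbone mean with
the raw minimal delta, so a cis/trans flip costs up to one third of the
backbone score; flips and >30° twists are *additionally* flagged and
counted, since they are qualitatively different errors (stable twists
essentially never occur in experimental structures).

The sidechain score weights torsion agreement by burial,
β = min(n_close/(3·n_sc), 1), computed **on the target structure**: a
solvent-exposed sidechain frequently has no experimentally defined
"correct" rotamer, so a fully exposed residue (n_close = 0) contributes
nothing no matter how its model sidechain is posed.  The χ₂ term is
gated by e^−(Δχ₁/τ)² with τ = 30°: once χ₁ is wrong by ≳50° the
remaining sidechain geometry is meaningless and χ₂'s influence falls
below e^−(50/30)²/3 ≈ 0.02 (asserted numerically in the test suite).
Target χ torsions that cannot be constructed in the model — truncated
sidechains, or mutated template residues — count as Δχ = 180°, the
maximum; torsions present only in the model are ignored.  Residues
whose target has no χ (Gly, Ala, target-side truncations) receive no
sidechain score.

## Residue correspondence

Predicted models share the target's author numbering, so model–target
pairing defaults to (chain, seq number, insertion code) identity.
Templates come from unrelated depositions with arbitrary numbering, so
template–target pairing uses global sequence alignment per chain
(Needleman–Wunsch, BLOSUM62, via Biostrings).  Pairing is one-to-one
and total on target polymer residues; unmatched targets pair with
"absent" and are reported but not scored.  Alternate conformations are
resolved at parse time to the highest-occupancy altloc (ties:
lexicographically first), a convention we record rather than infer —
assessment pipelines rarely state how they treat experimental-target
altlocs.  MSE and a small set of common modified residues map to their
standard parent for scoring; other non-standard residues are kept but
flagged non-polymer and excluded.

## Ranking

Raw metrics are combined per target through adjusted z-scores: orient
(lower-is-better columns — clashscore, mean backbone/sidechain scores —
are negated), z-score against the model population, prune initial
z < −2 as potential outliers (one shot, not iterated), re-score
everyone against the pruned statistics, clip negatives to zero.  Group
scores sum the selected model's combined score over targets
(`model_1` by default; `best_of_5` optionally).

Two conventions are not recoverable from the protocol's prose and are
therefore configurable, with these defaults:

* **SD convention**: sample SD (n−1).  The protocol's own worked
  arithmetic (a 3-value example scoring to z = 1) implies the sample
  convention, and it is what R's `sd()` computes.  `sd_type =
  "population"` is available.
* **z population**: all submitted models for the target, with
  `population = "model_1"` as the alternative reading.

The combined schemes are fixed linear forms (weights asserted against
hard-coded constants in the tests): `S_CASP12` = ⅓ z_GDT_HA +
⅑(z_lDDT + z_CADaa + z_SG) + ⅓ z_ASE; `S_CASP12-ASE` drops ASE and
rescales to ½ / ⅙; `S_torsion` = ⅔ z_backbone + ⅓ z_sidechain;
`S_geom` = 1/16 (z_lDDT + z_CADaa + z_SG + z_sidechain) +
1/8 (z_clash + z_backbone) + ¼ (z_GDT_HA + z_ASE).  A metric absent
from a row contributes zero — consistent with the clip-to-zero
philosophy — and is logged.

## MR preparation

Submitted per-atom RMS error estimates ε (carried in the B-factor
column of prediction files) are converted to B-factor inflation
ΔB = (8π²/3)·ε², which smears each atom's density over its positional
uncertainty.  Three column interpretations are supported: constant B,
error-estimate inflation, and leave-as-B (control).  Models with
GDT_TS < 30 or median error estimate > 3 Å are rejected and assigned
LLG 0 (MR calculations are unstable for such models); boundary values
are accepted, matching the strict inequalities of the stated rule.  An
LLG gain of ≥ 60 predicts a successful search.  The LLG itself is
always an external input — this package never computes crystallographic
likelihoods.

Unstated constants chosen once: baseline B for inflation 0 Å² (the pure
error term) and constant-B default 20 Å², a typical well-ordered
protein value.  Median error uses all non-hydrogen atoms.  B values are
clamped to the PDB column maximum 999.99 on writing (with a warning) —
relevant when error estimates are orders of magnitude too large.

## Template triage

The MolProbity combination formula is reproduced from the MolProbity
literature (the assessment context uses the score without printing the
formula): 0.426·ln(1+clash) + 0.33·ln(1+max(0, rota%−1)) +
0.25·ln(1+max(0, rama%−2)) + 0.5.  Its native third input is the
Ramachandran **not-favored** percentage; validation tables often print
only the outlier percentage, which is smaller.  `rama_convention`
records which is being supplied; under `"outlier"` the result is a
lower bound (this is why published per-entry scores cannot always be
reproduced exactly from three printed numbers).

Resolution bands are half-open with the conventional cut points:
≥5 Å reject-tier, [3.5, 5) caution, [2.5, 3.5) transition, <2.5
trusted.  A MolProbity score above 3 escalates the advice one tier but
never into `reject` — within the 3.5–5 Å band a poor score yields a
"substantial caution" note rather than a tier change, and the reject
tier is reserved for very low resolution.  Recommendation among
candidates is lexicographic: best resolution, lowest MolProbity score,
newest release year, identifier — deterministic in candidate order.

# Synthetic data: what a green test establishes

`build_peptide()` constructs heavy-atom peptides from ideal internal
coordinates by sequential atom placement, with sidechain geometry
frozen from chemical-component reference values and χ₁/χ₂ fully
parameterized (remaining internal degrees of freedom sit at library
defaults).  Because every scored torsion is a direct input, the
generator provides *exact* ground truth: `perturb()` operates in
torsion space — rebuild, not Cartesian noise — so the applied deltas
are recoverable to numerical precision, including engineered ω flips
and sidechain truncations that must surface as Δχ = 180.

What the generator deliberately does **not** emulate: steric
plausibility (no clash avoidance or energy minimization; a proline ring
is left open at arbitrary χ), experimental artifacts (missing density,
altlocs, occupancy disorder), multi-chain complexes, and realistic
error correlation along the chain.  Green round-trip tests therefore
establish the correctness of the measurement and scoring machinery —
not that the scores behave well on pathological experimental input,
which only real structures can exercise.

`synth_metric_table()` plants a linear group-quality latent factor
(default separation 3 SD between best and worst group, the regime where
full-order recovery should be near-certain at 20 targets) and draws
each metric as an oriented noisy readout.  Ranking tests verify planted
recovery under strong effects and top-rank uniformity under zero
effect; they validate the ranking pipeline, not any claim about real
predictor populations.

# Numerical choices

* Angles in degrees throughout, canonical range (−180, 180];
  `dihedral()` follows the standard IUPAC sign convention and is
  cross-checked against an independent two-normal/acos oracle on 1000
  random quadruples (≤1e−6° disagreement).
* Torsion round trips (build → measure) are required to 1e−3°; in
  practice they hold to ~1e−12.
* ω classification boundaries at exactly 30° resolve to the
  non-twisted (planar) class; the MR filter boundaries (GDT_TS = 30,
  median error = 3 Å) resolve to acceptance.  Both follow the strict
  inequalities of the stated rules.
* χ₂ of Asp, Phe and Tyr is compared under its chemical 2-fold symmetry
  by default (`chi_symmetry = FALSE` restores the literal comparison):
  the naming of chemically equivalent terminal atoms is arbitrary in
  experimental models, and penalizing a 180° relabeling would be noise.
  Whether the original assessment applied this correction is unstated;
  both behaviors are supported and tested.
* Chain breaks are detected by peptide C–N distance > 2.5 Å; torsions
  are never computed across a break.
* Degenerate z-score populations (SD = 0 in either pass) define that
  pass's z-scores as 0 rather than propagating NaN.
* All randomness (perturbation draws, metric simulation) flows through
  a single integer seed per call, and generators restore the global RNG
  state on exit.

# Known limitations

* Only χ₁ and χ₂ are computed; the scores use no deeper torsions, so
  long sidechains (Arg, Lys, Met) are compared only near the backbone.
* Aggregation over residues is an unweighted mean over scored residues;
  coverage is reported separately rather than folded into the score.  A
  model that omits its hardest regions is *not* penalized by the means
  — consumers should read `n_residues_scored` alongside.
* The mmCIF reader handles the `_atom_site` loop of standard
  coordinate files, not the full CIF grammar (no multi-line semicolon
  values inside the loop).
* Burial counts neighbor heavy atoms broadly (other residues, ligands,
  other chains; waters excluded).  `burial_include_het = FALSE`
  restricts to polymer neighbors.
* Ranking significance (bootstrap over targets) and the computation of
  the external metrics themselves (GDT, lDDT, CADaa, SG, ASE,
  clashscore, LLG) are out of scope; they arrive as inputs.
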