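---
title: "Methods: propensity analysis and prediction of purine nucleotide binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity analysis and prediction of purine nucleotide binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purinesite)
```

`purinesite` implements a residue-level pipeline for adenine and guanine
phosphate binding sites: dataset curation from PDB complexes, geometric
contact labeling, amino-acid propensity statistics with bootstrap error
bars, PSSM-window feature encoding, support-vector-regression
prediction under a leave-one-protein-out jackknife, and cross-ligand
prediction matrices. This vignette documents the models, the tunable
parameters, the numerical conventions, and the design decisions taken
where more than one defensible convention existed.

## Ligands and dataset curation

Eight nucleotides are supported, identified by their PDB HETATM codes:
cAMP (`CMP`), cGMP (`PCG`), AMP, ADP, ATP, GMP (`5GP`), GDP and GTP —
the mono-, di-, tri- and cyclic mono-phosphates of the two purine
bases. Note that `CMP` here is cyclic AMP, the code used in the
nucleotide-complex context, not the modern chemical-component meaning
of cytidine monophosphate.

Curation applies three filters, each a function argument rather than a
constant:

* **Resolution ≤ 2.5 Å** (`apply_structure_filters()`, `max_resolution`).
  "Resolution lower than 2.5 Å" is read in the crystallographic sense of
  numerically-worse-than, so the boundary value 2.5 Å is retained. NMR
  entries carry no resolution and pass this filter; for multi-model
  (NMR) files only the first model is parsed.
* **Length ≥ 30 residues** (`min_length`).
* **Redundancy removal at 30% identity** (`remove_redundancy()`).
  No clustering algorithm is canonical for this step, so the package
  uses the simplest reproducible convention: chains sorted by
  descending length (ties by identifier), each kept unless its
  global-alignment identity to an already-kept chain exceeds the
  cutoff. Identity is the number of identical aligned positions divided
  by the shorter length, under Needleman–Wunsch scoring match +1,
  mismatch 0, linear gap cost 1. Under this scoring gapped alignments
  are rarely score-optimal, which makes the measure conservative
  (close to a gapless identity); the scoring is stated here because a
  different alignment convention would shift identities by a few
  percent around the cutoff.

Alternate atom locations keep the highest-occupancy altloc, ties broken
by the lowest altloc character. Modified residues with a known parent
(MSE, SEP, TPO, PTR, CSO, MLY, HYP, PCA) map to the parent amino acid;
anything else becomes `X`, stays in the sequence, and is excluded from
propensity counts so that rare chemistry cannot masquerade as
depletion.

## Contact labeling

A residue is a binding-site residue when its minimum heavy-atom
distance to any atom of any copy of the ligand is **≤ 4.5 Å**. The
comparison is inclusive ("within" is read as ≤) and the cutoff is an
argument. Hydrogens are excluded by default (`exclude_hydrogens`):
crystal structures at ≤ 2.5 Å rarely resolve them, and including them
when present would make labels depend on deposition practice rather
than chemistry.

Contacts are decomposed into four channels: protein main chain (`N`,
`CA`, `C`, `O`, `OXT`; `CB` is side chain) × ligand base or phosphate
group. Ligand atoms are tagged by a deterministic name table per HET
code — purine ring and exocyclic substituents are base, phosphorus and
its bonded oxygens are phosphate, sugar atoms are ribose; an unknown
atom name is tagged ribose with a warning, never an error.
Ribose-mediated contacts count toward the overall label but toward no
channel, because the channel decomposition targets the two chemically
interpretable ligand moieties; the channel union is therefore a subset
of the overall label.

## Propensity and bootstrap error bars

For amino acid $i$ within one ligand class, all selected proteins are
pooled and

$$P(i) = \frac{N_b(i)/N(i)}{N_b(\mathrm{all})/N(\mathrm{all})},$$

with $N_b$ counting binding residues. $P(i) > 1$ is enrichment. Two
identities follow directly and are asserted in the test suite on every
fixture: $\sum_i P(i)\,N(i) = N(\mathrm{all})$, and invariance of
$P$ under any common rescaling of the counts. An amino acid absent
from a dataset gets `NaN`, never 0.

Error bars: pseudo-copies of the dataset are built by drawing proteins
with replacement until the original protein count is reached;
propensities are recomputed on each pseudo-copy, and the per-amino-acid
standard deviation across 500 replicates (the default) is the error
bar. The **population** SD is used; at 500 replicates it differs from
the sample SD by a factor $\sqrt{499/500}$, far below the bar widths.
Replicates in which no residue binds leave the propensity undefined and
are excluded from the SD, with their count reported. The generator is
R's default RNG under a caller-supplied seed, and the seed is stored on
the returned table, so error bars are bit-reproducible.

Per-channel propensities use the channel's own binding counts in both
the numerator and the "all" denominator, so each channel's table is
internally normalised (its weighted mean is exactly 1). This makes
within-channel comparisons across amino acids clean; comparing absolute
levels across channels instead requires the overall denominator, which
a caller can obtain by assembling counts directly.

Ligand pairs are compared by the Pearson correlation of their
propensity vectors over amino acids finite in both tables (at least 3
required), reported as $R$ and $R^2$.

## Feature encoding

Each residue is represented by the rows of its chain's PSSM in a
five-residue window (two on each side — the window is centred, the
field convention). Every slot contributes 21 dimensions: the 20
substitution scores in the fixed column order `ARNDCQEGHILKMFPSTWYV`,
plus a terminal flag that is 1 exactly when the slot falls beyond
either terminus (in which case the 20 score dimensions are 0). The
vector is therefore 21 × 5 = 105-dimensional.

Scores are used **raw**. No normalisation is stated for this family of
methods, and the downstream SVR's default hyperparameters act on
unscaled inputs; an optional logistic squashing
$1/(1+e^{-s/10})$ is available (`logistic = TRUE`) for users who want
bounded features, and this choice is surfaced prominently because it
changes the kernel geometry and hence any attempt at numerical
reproduction.

Profiles come from PSI-BLAST ASCII PSSMs (`load_psiblast_pssm()`),
parsed robustly: the column order is taken from the file's own header
and re-ordered to the canonical alphabet, and header/footer noise is
skipped. A thin adapter (`run_psiblast_adapter()`) drives an external
`psiblast` executable with 3 iterations by default and fails with a
structured error when the executable is absent; nothing in the package
or its tests requires it, because the synthetic profile generator can
be substituted.

## Prediction model and evaluation protocol

The model is ε-support-vector regression with RBF kernel as implemented
in `e1071::svm`, at that implementation's default hyperparameters
(`cost = 1`, `gamma = 1/105`, `epsilon = 0.1` — recorded on the fitted
object and reported by `glance()`). Training targets are 1 for binding
residues, 0 otherwise. One deliberate departure from `svm()`'s argument
defaults: `scale = FALSE`. Column-wise rescaling would fail on the
terminal-flag dimensions (constant 0 over interior slots) and the PSSM
scores already share one integer scale; raw features are also the
package's stated encoding. Fits are deterministic given the data, and
data order is fixed by sorting entries on `(structure_id, chain_id,
seq_index)`, so refitting reproduces predictions exactly.

Generalisation is measured by a leave-one-protein-out jackknife: each
protein is scored by a model trained on all other proteins of its
ligand class, so the pooled score set covers every residue exactly
once and no residue is ever scored by a model that saw its protein. A
fold whose training set has only one class cannot be fitted and is
scored at the training base rate, with a warning. Metrics are computed
on the pooled residues by default; a per-protein-average mode exists
(`jackknife_report(aggregate = "per_protein")`) because averaging over
left-out proteins is the other defensible reading of the protocol, and
reports name the mode used.

Cross-ligand prediction scores dataset B with the model trained on
ligand A for all ordered pairs; the diagonal deliberately scores the
self-trained model on its own training data (no jackknife), the
"over-learning" protocol under which separable training data reaches
100% AUC. The matrix is generally asymmetric; no symmetry is assumed.

## Metrics

Predictions are positive when the score is **strictly greater** than
the cutoff; the strictness matters at tied scores and is therefore
fixed by contract. Sensitivity, specificity, accuracy and precision
follow the standard definitions, reported in percent, with `NaN` and a
warning on empty denominators. The F-measure defaults to the harmonic
mean of precision and recall (F1); a geometric-mean variant
$\sqrt{\mathrm{precision}\times\mathrm{recall}}$ is provided as
`f_mode = "geometric"` because both phrasings circulate for this family
of methods, and the package refuses to guess silently — reports carry
the mode. Summary reports evaluate threshold metrics at the cutoff
maximising the F-measure (ties to the lowest cutoff, so the most
sensitive of the tied operating points is reported), alongside the
cutoff-free AUC.

The ROC sweeps every distinct score as a threshold; AUC is the
trapezoidal area, which with tied scores handled as diagonal segments
equals the Mann–Whitney U statistic normalised by
$n_+ n_-$ with tied pairs counting ½. The test suite checks this
equality to $10^{-12}$ against an exhaustive pair-counting oracle, plus
invariance under strictly monotone score transforms and the identity
$\mathrm{AUC}(s) + \mathrm{AUC}(-s) = 1$ for tie-free scores. Raw SVR
outputs (which may leave $[0,1]$ slightly) are used directly for ROC
analysis — threshold sweeps are monotone-invariant — and clipped only
for display via `clip_scores()`.

## The synthetic generator: what it emulates, and what it does not

`fixture_spec()` + `make_ligand_dataset()` build toy complexes whose
ground truth is *geometric*: residues sit on an idealised helical
backbone, one ligand copy (with correct atom names per HET code and
idealised hand-built geometry) sits well off the helix axis, and each
requested binding residue receives a side-chain probe atom placed
3.5 Å from a ligand atom. All non-binding residues stay ≥ 6.0 Å from
every ligand atom, so the 4.0/6.0 Å margins straddle the 4.5 Å cutoff
with buffer and floating-point placement noise cannot flip a label.
The generator never copies its requested positions into the labels —
each complex is serialised to PDB text, re-parsed, and labeled by the
contacts module; a disagreement is an error. Probe targets cycle over
base, phosphate and ribose atoms so channel code paths are exercised.

Profiles are Normal(0, `noise_sd`) backgrounds with `signal_shift`
added on `signal_dims` for binding rows. The reference study conditions
— the generator defaults, fixed once — are 40 proteins × 60 residues,
6 binding residues per protein, shift +6 on 3 dimensions over unit
noise. These sizes keep the full jackknife (40 SVR fits on ~2340 × 105
matrices) around a minute on one CPU while leaving the planted signal
comfortably recoverable: pooled jackknife AUC ≥ 0.85 is asserted, and
permuting labels within proteins collapses it to 0.5 ± 0.1.

What the toys do **not** emulate, and the resulting caveats:

* No physical realism: side-chain probes are placed without regard to
  chemistry, conformers or clashes. The fixtures validate distance
  logic and bookkeeping, not structural biology.
* Profile rows are independent Gaussians, unlike real PSSMs whose rows
  are integer log-odds with strong positional correlation. Passing
  tests show the pipeline recovers a known signal; they say nothing
  about attainable accuracy on real evolutionary profiles.
* Cross-ligand toys share the background distribution but differ in
  their positives. When two toy ligands are given *orthogonal* signal
  dimensions, the tested dataset's binding rows are far from the entire
  training distribution of the model scoring them; an RBF model then
  returns near-constant scores for them (all kernel terms shrink
  together, leaving the fitted offset), and that constant can sit above
  the typical negative score. Orthogonal-signal cross-prediction AUC
  therefore lands well above chance (≈ 0.85 at the reference
  conditions rather than ≈ 0.5), and the same-vs-orthogonal AUC margin
  is ≈ 0.10–0.15. The margin is reliably positive — shared-signal
  transfer always scores higher — but a toy with out-of-distribution
  positives overstates transfer from "unrelated" signals, a caveat
  real cross-ligand comparisons (where all datasets share the PSSM
  feature distribution) do not carry. The corresponding acceptance
  check expects a ≥ 0.2 margin and is allowed to fail rather than
  re-tuning the fixture toward it.

## Problem sizes used by the tests

Unit tests run on 3–12 proteins with chains of 15–40 residues; the
end-to-end checks use the reference 40-protein conditions for
self-prediction, jackknife and permutation, 20-protein sets for
cross-prediction, 200 random atom clouds for the contact oracle, 500
bootstrap replicates (5000 in the convergence check), and ≤ 11
sequences for the redundancy oracle. The whole suite completes in a
few minutes on one CPU.

## Known limitations

* Redundancy removal is greedy and order-dependent by design; it
  guarantees no retained pair above the cutoff, not a maximum retained
  set.
* mmCIF input, biological assemblies and symmetry mates are out of
  scope; one PDB file is one asymmetric-unit complex.
* Propensity differences between ligands are reported descriptively
  ($R$, $R^2$) without significance testing.
* The SVR uses its implementation defaults throughout; no
  hyperparameter search is attempted, matching the method family this
  package implements.
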