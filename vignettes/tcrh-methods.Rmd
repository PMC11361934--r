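---
title: "tcrh: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcrh: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cytotoxic T cells recognize peptide epitopes presented by MHC class I
through the T-cell receptor (TCR); the third complementarity-determining
region of the receptor's beta chain (CDR3beta) is the most diverse and most
epitope-proximal loop and is commonly used as the receptor's proxy
sequence.  `tcrh` predicts, for a (CDR3beta, epitope) pair, whether the
receptor binds the epitope.  The crux of the problem is *generalization to
unseen sequences*: a model scored on a random train/test split is flattered
by epitopes and receptors that occur on both sides, so the package builds
leakage-aware splits in which test epitopes (epitope-hard), test CDR3betas
(TCR-hard) or both (strict) never occur in training.

The model itself is deliberately shallow: each sequence is summarized by 96
whole-sequence physicochemical descriptors, and a support vector machine
with a radial-basis-function kernel is trained on the concatenated
192-dimensional pair representation after standardization and
correlation-based feature pruning.  A model-agnostic KernelSHAP
implementation attributes predictions back to the descriptors.

## The 96-descriptor census

`feature_vector()` returns, in a fixed documented order, 88 *family*
descriptors — per-residue scale-table averages — followed by 8 scalar
indices:

| block | dimensions |
|---|---|
| BLOSUM indices | 10 |
| Cruciani properties (PP1–PP3) | 3 |
| FASGAI vectors (F1–F6) | 6 |
| Kidera factors (KF1–KF10) | 10 |
| MS-WHIM scores | 3 |
| PCP/MDS descriptors (E1–E5) | 5 |
| Physical descriptors (PD1, PD2) | 2 |
| ProtFP descriptors | 8 |
| Sneath vectors (SV1–SV4) | 4 |
| SVGER descriptors | 11 |
| ST-scales | 8 |
| T-scales | 5 |
| VHSE-scales | 8 |
| Z-scales | 5 |
| Boman, charge, hydrophobic moment, hydrophobicity, instability, isoelectric point, molecular weight, m/z | 8 |

Published tabulations of these families are not perfectly consistent about
per-family dimensionality; we fix the census once, following the families'
primary descriptions (three Cruciani principal properties, eleven SVGER
components) and including the instability index among the scalars, which
makes the total exactly 96 per sequence.  The order is frozen and asserted
in the test suite; `featurize_pair()` emits the epitope block (prefix
`epi_`) followed by the CDR3beta block (prefix `cdr_`), 192 named values.

### Scale-table provenance

The per-residue tables live in `inst/extdata/aa_scales.csv` (with an md5
checksum verified at load) and carry a `provenance` column:

* `published` — transcribed from the widely reproduced published tables
  (Kidera factors, Z-scales, VHSE, Cruciani, MS-WHIM, PCP/MDS, T-scales,
  Boman solubility values, average residue masses).
* `aaindex` — extracted verbatim from AAindex distributions (Sneath
  vectors, Eisenberg consensus, Kyte–Doolittle) and the Guruprasad
  dipeptide weights (`inst/extdata/diwv.csv`).
* `synthetic_analogue` — scales we **derived ourselves** because no
  machine-readable source of the published values was available when the
  package was built: the BLOSUM indices are a varimax-rotated principal
  decomposition of BLOSUM62 (the construction the family is defined by,
  recomputed), and the FASGAI, Physical, ProtFP, SVGER and ST analogues
  are principal components of keyword-matched AAindex property panels
  mirroring each family's described inputs.  They preserve the family's
  dimensionality, construction style and correlation structure but are
  *not* the originally published numbers.  Every downstream result in this
  package is computed against these bundled tables; users comparing
  descriptor values with other software should expect the
  `synthetic_analogue` families to differ.  `data-raw/make_scales.R`
  regenerates the CSVs deterministically.

### Scalar-index conventions

Several scalar indices require conventions the descriptor definitions
leave open; the package fixes them once:

* **Charge / isoelectric point.** Henderson–Hasselbalch fractional charges
  with the EMBOSS pKa set (`pka_set("emboss")`, configurable); the scalar
  charge feature is evaluated at pH 7.0.  The isoelectric point is found
  by bisection on [0, 14] to a bracketing width of `1e-4`; the
  precondition (positive charge at pH 0, negative at pH 14) holds for any
  peptide with free termini.
* **Hydrophobicity.** Mean Kyte–Doolittle value by default; the Eisenberg
  consensus scale is bundled as an alternative.
* **Hydrophobic moment.** Eisenberg scale, helical angle 100°, maximum
  over sliding windows of length `min(11, L)`, normalized by the window
  length.
* **Instability index.** `(10/L) * sum` of Guruprasad dipeptide weights;
  a length-1 sequence has no dipeptide and returns 0 with a warning.
* **m/z.** `(M_avg + z * 1.00728)/z` with charge state `z = 1` by default.

## Data curation and splits

`apply_filters()` keeps CDR3beta lengths 9–23 and epitope lengths at most
15, drops exact duplicate (CDR3beta, epitope) pairs keeping the first, and
removes *entirely* any pair observed with both labels — the most
conservative treatment of label conflicts.  Filtering is idempotent, and
class imbalance is preserved as-is (no reweighting or downsampling).

Splits are index partitions tagged with their kind and seed:

* **random** — uniform record-level partition,
  `n_test = max(1, round(f * n))`.
* **epitope-hard / TCR-hard** — distinct key values are shuffled with the
  seed and whole groups assigned to the test side until the test record
  count first reaches `f * n`.  Group sizes are lumpy, so the realized
  fraction is *reported*, never forced; a group holding more than `1 - f`
  of the records triggers a warning rather than an error.
* **strict** — a test epitope set and a test CDR3beta set are drawn
  independently by the same greedy procedure; test records need both keys
  test-side, train records both keys train-side, and crossing records are
  **discarded and counted**.  Discarding is the only construction that
  guarantees both disjointness invariants simultaneously.  With per-key
  fraction `g` the realized record-level test fraction is about `g^2` for
  independent keys — e.g. `g = 1/3` yields roughly a 4:1 train:test ratio
  on the synthetic data — so callers choose `test_fraction` per key with
  that in mind.

## Preprocessing pipeline

The composition is fixed and logged: featurize → drop zero-variance
columns → prune correlated features → standardize.  All three stages are
fitted on the **training matrix only** and applied unchanged to test data.
Whole-dataset scaling would be defensible for a purely descriptive study,
but train-only fitting is the leakage-safe default and is what
`fit_pipeline()` implements.

Pruning computes Pearson correlations on the training matrix, walks the
feature pairs in lexicographic name order and, whenever both members of a
pair with `|r| > 0.8` are still retained, removes one chosen by a seeded
coin flip.  The lexicographic enumeration makes runs reproducible despite
the randomized victim choice; a single pass suffices because removals are
permanent.  The prune report records every (removed, surviving partner)
pair, and `prune_proxy_groups()` reconstructs the transitive clusters —
useful for asking whether a signal planted on a pruned feature resurfaces
through its retained proxy.

## Classifiers and evaluation

The primary model is an SVM with RBF kernel (`e1071`), `cost = 1` and the
"scale" kernel-width heuristic `gamma = 1/(d * var(X))`; after unit
standardization this is essentially `1/d`.  Hyperparameters are pinned to
explicit numbers in the `model_spec` and echoed into the run log, because
library defaults drift across versions; no cross-validation or tuning is
performed anywhere.  Comparators are a random forest (`randomForest`,
500 trees, `mtry = floor(sqrt(d))`) and two boosted-tree configurations
delegated to `xgboost`: a classical gradient-boosting setting
(`eta = 0.1`, depth 3) and the extreme-gradient-boosting setting
(`eta = 0.3`, depth 6).  A dedicated gradient-boosting implementation is
not available in the supported environment, so both boosted comparators
share the xgboost backend and differ only in these pinned settings.

ROC curves and AUC are computed from the SVM's *decision values*, not
Platt-scaled probabilities: decision values are deterministic and need no
extra calibration fit.  The AUC is the Mann–Whitney rank statistic (ties
counted one half), which equals the trapezoidal area under the ROC curve;
the suite cross-checks it against `pROC`.  Threshold metrics are computed
from confusion counts with positives = label 1; any 0/0 denominator is
returned as a flagged `NA`, never a silent 0.  The SVM's decision-value
orientation is pinned at training time so that larger scores always mean
"binds".

## KernelSHAP

`kernel_shap()` re-implements the kernel formulation of Shapley value
estimation from its definition:

1. coalitions `z` in `{0,1}^M` are drawn with sizes weighted by the
   Shapley kernel `pi(z) = (M-1)/(choose(M,|z|) |z| (M-|z|))` (uniform
   within a size); `n_samples = 100` by default;
2. a coalition's value is the mean model score over background rows with
   the coalition's features replaced by the explained instance's values;
3. attributions solve the kernel-weighted least squares under the
   efficiency constraint `sum(phi) = f(x) - base`, enforced exactly by
   eliminating one unknown; the reduced system is solved by an
   SVD-based minimum-norm solver, so under-determined designs (more
   retained features than sampled coalitions) behave like the reference
   KernelSHAP least-squares solver.

Efficiency therefore holds to machine precision for every explanation.
With `method = "exact"` all `2^M - 2` proper coalitions are enumerated
with analytic kernel weights; the suite verifies that this solve equals
classical permutation-averaged Shapley values (tolerance 1e-8), that dummy
features receive zero attribution, and that duplicated features share
attribution symmetrically.  The background set is a seeded subsample of
the training matrix (the reference distribution is a design choice and is
logged); the global summary ranks features by mean |phi| with ties broken
by name.

## The synthetic generator

`simulate_binding_data()` emulates the *structure* of curated binding
data: epitopes drawn from a small pool (8–15 residues) and reused across
many receptors; CDR3betas 9–23 residues with the canonical C...F motif;
balanced classes.  Labels come from a planted latent rule
`s = 2 H(epi) H(cdr) + 1 C(epi) C(cdr) + 0.5 MW(cdr)/1000 + e`,
`e ~ N(0, 0.25)`, thresholded at the sample median, where `H`, `C`, `MW`
are the descriptor module's hydrophobicity, net charge at pH 7 and
molecular weight.  Because the rule depends on physicochemical descriptors
and not on sequence identity, a correct pipeline generalizes across hard
and strict splits — the desk-scale analogue of the scientific claim the
package exists to test.  The three-family structure also gives the SHAP
summary a known ground truth: the planted families must surface in the top
of the importance ranking, directly, through a direct algebraic transform
(m/z for mass; the isoelectric point for charge), or through the retained
feature standing proxy for a pruned family member.

What the generator does **not** emulate: V(D)J recombination statistics,
real repertoire composition, epitope biology, or the label noise structure
of assay data.  Passing the synthetic end-to-end test demonstrates the
machinery is correct, not that real binding data are this learnable.

## Problem sizes and tolerances used in the tests

The suite exercises the full pipeline at desk scale: 9,000 generated
pairs, strict split at per-key fraction 1/3 (about 4,000 train / 1,000
test records), pruning at 0.8, SVM-RBF, and a SHAP summary over 60
explained test instances with a 50-row background and 100 coalitions per
instance — sizes chosen so the whole end-to-end check completes in a few
minutes on one CPU while leaving the conclusions unchanged at larger n.
Descriptor equivalence against brute-force table recomputation is asserted
at 1e-9 on 200 random sequences; split invariants over 50 seeds on 1,000
records; exact-vs-classical Shapley agreement at 1e-8; SHAP efficiency at
1e-6.  `scripts/acceptance.R` re-runs the same computations from scratch
under a caller-supplied seed and writes the headline numbers as JSON.

## Known limitations

* Binary bind/no-bind classification only; no affinity regression.
* The five `synthetic_analogue` scale families are package-derived
  analogues, not the published values (see provenance above).
* Splits are leakage-aware but not similarity-aware: an unseen epitope may
  still be one mutation away from a training epitope.  Clustering-based
  splits are out of scope.
* No CDR3alpha, V/J gene, MHC-allele or structural features.
* KernelSHAP with 100 coalitions on ~100 retained features is an
  under-determined estimate; rankings are stable in aggregate, individual
  phi values carry Monte Carlo noise.
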