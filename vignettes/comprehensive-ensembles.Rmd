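---
title: "Comprehensive stacked ensembles for QSAR classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive stacked ensembles for QSAR classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarstack)
```

## The model

`qsarstack` treats QSAR bioactivity prediction as binary classification
(active = 1, the positive class for AUC) and attacks the central weakness of
single-model QSAR — that the best method and the best molecular
representation change from assay to assay — by combining diversity along
three axes at once:

* **representation diversity**: PubChem substructure keys, ECFP circular
  fingerprints, MACCS keys, and the SMILES string itself;
* **method diversity**: random forest, linear SVM, gradient boosting, and
  feed-forward networks on the fingerprint families, plus an end-to-end
  CNN→GRU sequence model on SMILES;
* **data diversity**: optional bootstrap bagging of any first-level
  learner (an `n`-sized bootstrap holds ≈ 1 − 1/e ≈ 63.2% unique compounds,
  which is what makes bagged members disagree).

The second level is stacked generalization. Every first-level learner
emits out-of-fold probabilities through k-fold cross-validation on the
training set (k = 5 by default): the model that predicts compound *i* never
saw compound *i* during training, a structural property the package records
per row and audits with `audit_oof()`. A meta-learner is then fitted on the
concatenated probability matrix. The default meta-learner is a linear SVM
run through the same Platt-calibration path as the first level, so ensemble
outputs remain probabilities; logistic regression and ordinary least
squares are the other linear choices, RF/GBM/NN the nonlinear ones, and
uniform averaging the non-learning baseline. For linear combiners the
normalized absolute weights |wᵢ|/Σ|wⱼ| are reported as model importances —
invariant to positive rescaling of the weight vector, and exercised in the
test suite by planting an informative "oracle" probability column among
pure-noise columns and checking that it receives the maximum importance.

At test time each first-level learner is refit on the full training set
(the standard stacking arrangement); averaging the five fold models instead
is available behind `refit = FALSE`. The package assumes the two choices
are close but does not assume they are identical.

## Tunable parameters

First-level defaults (all overridable per `learner_spec`):

| parameter | default | notes |
|---|---|---|
| RF trees / GBM rounds | 100 | GBM additionally depth 3, learning rate 0.1 |
| SVM kernel, penalty C | linear, 0.05 | calibrated on internal 3-fold CV decision scores |
| NN geometry | 512/64/1, ReLU/tanh/sigmoid | Adam, lr 0.001, 30 epochs, minibatch 256 |
| CNN filters × width | 384 × 17 | valid convolution, no pooling: 100 − 17 + 1 = 84 positions |
| GRU units | 9 | many-to-many; flattened output 84 × 9 = 756 |
| dropout (fractions dropped) | conv 0.9, GRU 0.6, first dense 0.6 | aggressive by design; config-exposed |
| sequence training | Adam, lr 0.001, 120 epochs, minibatch 256 | no early stopping by default |
| SMILES grid | 100 × 10 | 9 most frequent characters + OTHERS |
| ECFP | radius 2, 2048 bits | the community-default ECFP4 |
| split | 75% train, k = 5 folds | unstratified uniform draw; `stratify` flag available |

The evaluation layer fixes the classification threshold for
accuracy/MCC/F1 at 0.5, scores AUC as pairwise concordance with ties
credited ½ (which makes the exhaustive pairwise oracle exact), and runs the
paired t-test two-sided with the sample standard deviation and n − 1
degrees of freedom.

## Design choices where the design was open

* **Label polarity.** Active = 1 is fixed as the positive class; screening
  AUCs read naturally with actives ranked on top.
* **Deduplication.** Duplicate compound ids keep their first occurrence;
  ids observed with both outcomes are removed entirely. First-occurrence
  order makes the operation deterministic and idempotent.
* **Stratification.** The 75/25 draw is uniform by default — matching a
  protocol that says only "randomly divided" — with a `stratify` switch for
  heavily imbalanced assays.
* **Vocabulary scope.** The character vocabulary is built per training set
  by default (no test-set leakage); nothing stops a caller from building it
  globally and passing it in. Frequency ties break lexicographically.
* **Tokenization and truncation.** Tokens are single characters, so Cl and
  Br occupy two positions; strings longer than 100 keep their head, which
  preserves the canonical SMILES root.
* **SVM calibration.** Platt's sigmoid 1/(1 + exp(a·s + b)) fitted by
  logistic regression on decision scores from an internal 3-fold
  cross-validation, then the SVM is refit on all data. The calibrator is
  constrained monotone non-decreasing; degenerate score vectors (zero
  variance, or a slope pointing the wrong way) collapse to the constant
  class prevalence.
* **GRU convention.** Classic single-bias-per-gate GRU
  (h_t = z⊙h_{t−1} + (1−z)⊙h̃) with the gate's own tanh as the output
  nonlinearity — no extra activation layer. Parameter counts in the test
  suite are frozen under this convention: 3·(384·9 + 9² + 9) = 10,638 for
  the GRU, 10·17·384 + 384 = 65,664 for the convolution.
* **Dropout convention.** Rates are fractions *dropped* (inverted dropout),
  applied to the convolution output, to the GRU output copy that feeds the
  flatten (the recurrent path is untouched), and to the first dense layer.
* **Scaffold split.** Bemis–Murcko frameworks are computed by pruning
  degree-1 atoms from the connection table until only rings and linkers
  remain, re-attaching atoms that are double- or triple-bonded to that core
  (ring and linker carbonyls survive; side chains do not), and
  canonicalizing through OpenBabel. Acyclic molecules share the empty
  scaffold. Groups are assigned largest-first: to train while train is
  below its 80% target, then to validation, then to test; an oversized
  group may overflow its subset because groups are indivisible. The test
  suite checks the resulting partition against an independent toolkit's
  scaffold grouping.
* **Ordinary-regression combiner.** Implemented as least squares on the
  probability columns with predictions clamped to [0, 1].
* **Meta-feature scaling.** None — the inputs are already probabilities.
* **Seed discipline.** One master seed fans out to every stage through a
  polynomial rolling hash (`derive_seed`), so different assays, repeats,
  folds, bags and learners draw from independent reproducible streams, and
  a manifest records enough to re-run bit-identically for the
  deterministic learners.

## The neural backend

No deep-learning framework is assumed: the dense, 1D-convolution and GRU
layers, Adam, and binary cross-entropy are implemented directly on BLAS
matrix products inside the package. Gradients are exact — the test suite
verifies every parameter block of the CNN→GRU model against central finite
differences at 10⁻⁴ relative tolerance — and training is bit-reproducible
given the model seed (initialization, minibatch order and dropout masks all
derive from it). Probabilities are clamped to [10⁻⁷, 1 − 10⁻⁷] inside the
loss; Glorot-uniform initialization throughout; Adam with β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁸.

## Fingerprint backends

MACCS and ECFP are computed from SMILES via OpenBabel (ChemmineOB): MACCS
as the first 166 bits of OpenBabel's key block, ECFP as the diameter-4
(radius-2) hashed environments folded from 4,096 to 2,048 bits by OR-ing
halves. OpenBabel's ECFP implementation costs tens of milliseconds per
molecule, so the featurizer also exposes an `"rdkit"` backend that shells
out to the RDKit python toolkit for large simulated screens. Both backends
emit valid members of the same fingerprint family, but their bit
assignments differ (different hash functions), so a model must be trained
and applied under one backend. The 881-bit PubChem fingerprint is generated
by the PubChem service, not re-implemented; the package consumes it from a
registered per-compound bit-string source and raises a configuration error
otherwise.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_assay()` assembles each compound by concatenating 3–8
building-block fragments from a small alphabet chosen so that any
concatenation is a valence-correct SMILES under both backends. Activity is
planted by motif fragments (default the amide fragment `C(=O)N`): the
active minority class contains at least one motif, inactives contain none,
labels are then flipped independently at the `label_noise` rate, and class
sizes are fixed up front to hit the requested imbalance ratio (the
benchmark panel ranges from 1:1.1 to 1:4.2 with an average near 1:2, which
is the default). This reproduces the *statistical* structure the method
assumes — a substructure-driven signal visible to every representation,
class imbalance, label noise — and makes every pipeline stage testable
offline and in minutes.

It does not emulate real chemistry: no pharmacological realism, a narrow
fragment vocabulary, molecules far smaller than screening libraries, and a
single planted mechanism where real assays mix many. One known subtlety is
embraced rather than removed: fragment junctions can create incidental
amide-like environments in inactive compounds (e.g. an `N` fragment
followed by a ketone fragment), so fingerprint learners face a slightly
noisy version of the motif signal — a feature, since perfect separability
would make the ensemble comparison vacuous. Consequently, passing tests
demonstrate that the machinery is correct and that stacking does not lose
accuracy at desk scale; they do not certify performance on real screening
data.

## Problem sizes used by the tests and the acceptance script

Simulation scale is chosen to make the checks sharp but cheap: the
ensemble-versus-best-single comparison runs ten synthetic assays of 1,000
compounds (imbalance 2:1, 10% label noise) with five diverse base learners
(RF, SVM, GBM, NN across MACCS and ECFP) and compares median held-out AUCs;
importance recovery uses 100 seeds of a 500-row, 5-column planted-oracle
design; the bootstrap-uniqueness simulation uses n = 10,000 with 200
replicates; the sequence-model learning test uses 400 compounds with a
reduced desk-scale geometry (96 filters, milder dropout, 30 epochs). The
leakage audit sweeps 50 random (n, k, seed) designs.

## Known limitations

* The PubChem fingerprint family is input-only; synthetic screens therefore
  exercise ECFP/MACCS/SMILES but not PubChem-based learners.
* Scaffold canonicalization ignores formal charges when rebuilding the
  pruned framework; scaffolds differing only by charge may merge.
* The linear-SVM importance is a global, per-model weight; it does not
  decompose importance per compound or per feature.
* The published per-assay AUC cells of the 19-assay benchmark require the
  original screening data and full-scale training; the packaged tables
  support recomputing their summary statistics, not regenerating the cells.
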