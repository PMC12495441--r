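---
title: "Building affinity models from noisy bioassay databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building affinity models from noisy bioassay databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public affinity databases (BindingDB and its relatives) hold millions of
measured binding constants — Ki, Kd, IC50 — for protein–ligand pairs, but the
raw tables are not a training set. Measurements are replicated with spreads
that routinely exceed an order of magnitude; many values are censored
("`Ki > 10000`") because a serial dilution series ended; records cover
bacterial proteins, peptides, ribosome-scale complexes and broken SMILES; and
nearly half of the unique pairs carry more than one, mutually inconsistent,
measurement. `dtaforge` implements the full path from such a table to a
drug–target affinity (DTA) regression model: curation into a weighted
per-pair training set, leakage-free train/test splitting, a transformer
encoder–decoder network over frozen per-token embeddings with a masked
multitask loss and K-fold ensembling, evaluation metrics, and a consensus
score for classical molecular-modeling outputs.

## Curation model

All constants are mapped to the p-scale, `p = 9 - log10(value in nM)`, so
1 nM is 9 and 10 µM is 5. Kd and Ki records feed one pKi channel (Ki is
treated as a special case of Kd); IC50 stays a separate pIC50 target, since
the two constants have different natures even when numerically close.

**Threshold resolution.** A censored value is replaced by its best estimate
under a 10× dilution hypothesis: half a dilution step beyond the reported
bound, i.e. the concentration is multiplied or divided by √10 ≈ 3.16
(a ±0.5 shift on the p-scale toward the allowed side). This removes the
artificial spikes that integer-valued bounds otherwise create in the target
distribution, at the price of added uncertainty — which is why the record's
weight is simultaneously divided by √10.

**Filters.** Rules run in a fixed order so each removal is attributed to
exactly one rule, and a reduction ledger chains `in = removed + out` across
every stage: missing affinity → organism (bacteria and bacteriophages out)
→ temperature/pH → SMILES validity → protein length (50–2500 residues)
→ protein mass (1–500 kDa). The paper trail this produces is a first-class
output: `tidy()` on a curation result returns the ledger.

Two choices here were genuinely open. Physiological temperature and pH
windows are not standardized anywhere; the defaults are 20–45 °C and pH 5–8,
configurable, and records with *missing* metadata pass the rule — absence of
an annotation is not evidence of a non-physiological assay. Second,
"clipping values outside the 99th percentile" could mean winsorization or
removal, one- or two-sided; because the pipeline accounts for how much each
operation reduces the dataset, clipping is implemented as removal outside
the central 99% window of each target channel, and is a warning no-op below
100 pairs where tail percentiles are meaningless.

**Weights.** Every record starts at weight 1. Criteria multiply the weight
when they make a record more valuable and divide when they cast doubt:
√10 ≈ 3.16 for significant criteria, ⁴√10 ≈ 1.8 for insignificant ones.
Threshold-resolved records are divided by √10; mutant proteins are
multiplied by (2 + n_mut) — mutated targets are scarce and informative.
Only those two factors are fixed by the method; the remaining criteria (an
approximate "~" relation, unreviewed sources) live in a configurable
registry and use the insignificant factor. The raw product is clamped to
[0.1, 10] and then lightened by a square root, so final weights span about
0.3–3.2.

**Replicate aggregation.** Per (protein sequence, canonical SMILES) pair and
per channel the curated value is the *weighted 80th percentile* of the
replicate p-values. The 80th percentile acts as a soft maximum: experimental
error is more likely to depress an affinity than to inflate it, so the upper
part of the replicate distribution is the better estimate — but unlike the
strict maximum it ignores isolated high outlier clusters. The weighted
percentile is defined by letting each value occupy `weight` ranks of the
sorted replicate list and interpolating linearly at rank `1 + (W−1)q/100`;
for integer weights it equals the plain percentile of the weight-replicated
list (the property the test suite checks against a brute-force oracle), and
for unit weights it reduces to the standard type-7 quantile. The pair's
weight is the weighted mean of its member weights, which stays inside the
member range and hence inside [0.3, 3.2]. A per-pair 95% CI of the
replicate spread (Student's t; a seeded percentile bootstrap is also
provided) is attached as `ci_exp`; for pairs with both channels the mean of
the per-channel CIs is reported.

## Splitting

Random splits flatter DTA models: the same protein and the same scaffold
appear on both sides. The test set here is built half *cold-target* (whole
proteins held out, grouped by exact sequence identity) and half
*drug-scaffold* (whole Bemis–Murcko frameworks held out). Groups are atomic,
sampled in seeded random order until each half first reaches its share, so
the test size can overshoot by at most one group. Scaffold-half pairs whose
protein was already held out cold are reassigned to the cold half rather
than dropped. The scaffold of a molecule is computed by iteratively pruning
degree-≤1 heavy atoms from the molecular graph and re-canonicalizing the
remaining framework; acyclic molecules share one empty-scaffold group. This
pruning also removes exocyclic double-bonded atoms (a ring carbonyl oxygen,
for example), a slightly coarser grouping than some toolkits' Murcko
variant — coarser grouping can only make the split stricter. Classical
K-fold cross-validation (default k = 4) then partitions the training pairs
into disjoint validation subsets.

## Encoders and caching

The network consumes per-token embeddings from frozen encoders: ligands as
tokens × 512, proteins as residues × 640 in the reference configuration.
Because the encoders are frozen, embeddings are a pure function of the input
string and are cached: training K submodels invokes each provider at most
once per unique string, so the ensemble costs far less than K times one
model. Cache entries store the exact input and a checksum; a corrupted entry
raises an error and a key collision degrades to a miss, never to a wrong
matrix. The package ships a deterministic synthetic provider — per-token
vectors are a seeded pseudo-random function of (token, position bucket,
seed) — so every downstream component is testable offline; adapters to real
pretrained encoders plug in behind the same interface.

## Network

The model is a vanilla transformer encoder–decoder. The protein embedding
passes through a kernel-size-1 1D convolution projecting width 640 → 512 and
one encoder layer (the protein encoder has already done the feature
extraction); the ligand embedding feeds six decoder layers that condition on
the encoder output through encoder–decoder attention; decoder output is
max-pooled over tokens and a dense layer emits pKi and pIC50. Keeping the
two sequences in separate stacks costs `len_p² + len_m² + len_p·len_m`
attention entries per layer instead of `(len_p + len_m)²` for a concatenated
single-stack design. Heads (8), feed-forward width (2048), dropout (0.1) and
sinusoidal positional encoding follow the original transformer convention;
the method does not pin them, so they live in the
configuration. Examples are processed individually (no padding), which makes
per-example isolation exact by construction.

Targets are sparse — most pairs have only one of pKi/pIC50 — so the loss is
a masked weighted squared error: `Σ w·(ŷ − y)² / Σ w` over present cells
only. Missing cells contribute zero loss *and* zero gradient; a batch with
one task entirely absent leaves that task's head untouched (asserted in the
tests). Normalizing by the total present weight keeps the effective learning
rate independent of missingness; whether sample weights enter the loss at
all is a flag (`use_sample_weights`), on by default. Because the two targets
correlate strongly, labels for one task improve the other — the multitask
transfer property is exercised in the test suite on generated data with
r = 0.8 and half the pIC50 labels removed.

Optimization is RAdam (lr 1e-4, batch 64, up to 60 epochs in the reference
recipe) with early stopping on validation loss and best-epoch parameter
retention; patience is a free choice and defaults to 5. The forward and backward
passes are implemented directly in R matrix code; correctness rests on a
finite-difference gradient check across every parameter tensor in the test
suite. One analytic subtlety the check surfaces: the gradient of attention
key biases is exactly zero, because row-wise softmax is invariant to a
constant shift of all key scores.

K submodels are trained on classical K-fold splits with identical
architecture and training parameters (fold-derived seeds); inference
averages the per-task outputs arithmetically.

## Evaluation

MSE/RMSE over present targets (RMSE shares the target scale), the
concordance index with the DTA-community tie convention (pairs with tied
targets excluded, tied predictions score 0.5 — kept for comparability even
though rank metrics are a debatable fit for regression), Spearman's rank
correlation with mid-ranks, and the large-N prediction interval
`CI = 1.96 · RMSE`, which treats the RMSE as the standard error of a single
prediction. All three rank statistics are verified against brute-force
oracles on random instances.

## Consensus modeling score

Structure-based baselines (Glide docking scores, MM-GBSA binding free
energies, PM7+COSMO binding enthalpies — all produced by external software
and consumed here as scalars) are rank-binned per method into
high/medium/low by half-open intervals read literally (`[−20;−7)` means −7
is *not* high), mapped to 1/0.5/0, and averaged. Anything outside every
interval — positive energies, values below the most negative bound, missing
outputs — is "failed" and maps to −1; the literal reading of the binning
treats an implausibly negative score as a modeling failure rather than a
success, and that choice is flagged here because the alternative is
defensible. The selective-test harness reports Spearman correlations of the
modeling score (`C_Mod`) and of the DTA predictions (`C_DTA`) against
experiment side by side.

## What the synthetic data does and does not emulate

The generator reproduces the *statistical* structure the pipeline must
survive: replicate multiplicity with skewed measurement error — a mixture of
small symmetric noise, a dominant downward error mode and rare high outlier
clusters, scaled by `noise_sd` (default 0.5 orders), since assay errors are
far more likely to depress an affinity than to inflate it, which is exactly
the error structure the 80th-percentile soft maximum is designed for —
threshold censoring concentrated at integer p-values,
correlated sparse two-task targets (r = 0.8), consistent mutation
annotations, and per-rule contamination with recorded ground truth. Ligands
come from a small fragment grammar that is valid by construction; proteins
are uniform random sequences. The latent affinity surface is a smooth
function of hashed token composition of both strings — learnable in
principle by any encoder that sees token identities, with known ground truth
for recovery tests. It does **not** emulate real chemistry: no realistic
scaffold frequencies, no homology structure between proteins, no
assay-specific biases. Passing the recovery tests therefore demonstrates
that the machinery is correct and consistent, not that full-scale real-data accuracy transfers.

Desk-scale sizes are used throughout the tests and the acceptance script:
30 proteins of 60–180 residues, 150 ligands, 500 pairs, embedding widths
32/40, a 2-layer decoder and k = 2 folds for the toy ensemble. These sizes
were chosen so the whole pipeline — generation, curation, splitting,
training, evaluation — demonstrates its properties in minutes on one CPU;
the reference configuration (512/640 widths, 6 decoder layers, k = 4,
millions of records) is reached purely through configuration.

## Numerical choices and degenerate inputs

* Weighted percentile: ties in replicate values are harmless (interpolation
  between equal values); a single replicate returns itself; fractional
  weights can push the bracketing rank past the total weight, which clamps
  to the top value, and a sub-unit total weight degrades to the
  cumulative-fraction step estimator.
* CI of fewer than two replicates is undefined (`NA`), not zero; identical
  replicates give exactly zero.
* `clip_extremes` is a warning no-op under 100 pairs.
* Splits refuse degenerate inputs (single group, or a fraction that would
  consume every group).
* Softmax is stabilized by row-max subtraction; layer norm uses ε = 1e-5.
* Dropout, shuffling and initialization all derive from the training seed;
  one seed reproduces a bit-identical loss trajectory on one machine.
* Training aborts with diagnostics on a non-finite loss rather than
  continuing.

## Known limitations

* The OpenBabel canonicalization used for SMILES standardization differs in
  detail from other toolkits' canonical forms; canonical strings are stable
  within a run manifest but not interchangeable across toolkits.
* The full criterion list behind "confidence in the value" weighting is
  open-ended; beyond the two fixed factors the registry is configuration, and
  different registries yield different weight distributions.
* The pure-R network is for method development and desk-scale validation;
  it is not a GPU training framework.
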