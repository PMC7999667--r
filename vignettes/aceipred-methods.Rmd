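---
title: "Methods: PseAAC encoding, classifier benchmarking and k-mer screening of ACE-inhibitory peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PseAAC encoding, classifier benchmarking and k-mer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aceipred)
```

## The screening problem

Food proteins are reservoirs of short bioactive peptides.  Some of these
inhibit the angiotensin-converting enzyme (ACE) and thereby lower blood
pressure.  Because in-vitro assays are slow, the standard computational
strategy is: (i) learn a classifier from curated databases of known
ACE-inhibitory peptides, (ii) digest a target protein exhaustively into
short fragments in silico, and (iii) promote only fragments that the
classifier scores as near-certain positives.  `aceipred` implements this
pipeline end to end, with a synthetic benchmark generator so every stage
is testable without external database access.

## Type-II pseudo amino acid composition

Plain amino-acid composition discards residue order, which matters for
receptor binding.  The pseudo amino acid composition (PseAAC) family of
encodings appends *sequence-order correlation factors* to the 20
composition frequencies.  We use the type-II (amphiphilic) form: for a
standardized property scale $H$ and lag $g$,

$$\tau_{g,p} = \frac{1}{L-g}\sum_{j=1}^{L-g} H_p(R_j)\,H_p(R_{j+g}),$$

the mean *product* of property values of residues $g$ apart (type I would
use squared differences).  With frequencies $f_u$ and weight $\omega$,

$$x_u = \frac{f_u}{1+\omega\sum_j \tau_j},\qquad
  x_{20+j} = \frac{\omega\,\tau_j}{1+\omega\sum_j \tau_j},$$

so the full vector always sums to 1 — a useful algebraic invariant that
the test suite checks to $10^{-9}$ on randomly generated peptides, and
against an independent brute-force oracle to $10^{-12}$.

### Parameters

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 1 | correlation depth (lags considered); 1 = adjacent residues only |
| $\omega$  | 0.05 | weight of the order block relative to composition |
| scales    | 6 | hydrophobicity, hydrophilicity, side-chain mass (Da), pK1, pK2, pI |

At the defaults the vector has $20 + 6\lambda = 26$ dimensions.  Because
$\lambda = 1$, any peptide of length $\ge 2$ is encodable; this is why the
screening k-range starts at $k = 2$.  Peptides shorter than $\lambda + 1$
are excluded with a logged count wherever they appear.

### The property table

The six scales are shipped as a plain TSV asset
(`inst/extdata/aa_properties.tsv`) with one literature citation per row:
Eisenberg consensus hydrophobicity, Hopp–Woods hydrophilicity, rounded
side-chain masses as conventional in PseAAC work, and pK1/pK2/pI from
standard reference tables.  Pinning the numbers in a documented,
swappable asset (rather than anonymous constants in code) is a
reproducibility decision: users can substitute scales by pointing
`load_property_table()` at a file of the same layout.

Standardization divides by the *population* (divide-by-20) SD across
residues, the classical PseAAC convention; using the sample SD would
rescale every correlation factor, so the choice is pinned and tested
(`|mean| < 10^{-10}$, $|SD-1| < 10^{-10}`).  The correlation block is
ordered lag-major, property-minor — irrelevant at $\lambda = 1$ but fixed
so that $\lambda > 1$ encodings are well-defined.

## Dataset construction

A benchmark dataset is the disjoint union $I = I^+ \uplus I^-$ of known
inhibitors and presumed negatives, with $I^+ \cap I^- = \emptyset$ and
balanced counts.  Since validated *non*-inhibitors are scarce, negatives
are sampled from background proteins.  Whole database proteins are far
longer than inhibitory peptides (typically 2–12 residues), so negatives
are taken as *contiguous fragments* whose lengths are drawn from the
positives' empirical length distribution — the only construction that
yields a matched average length.  Fragments colliding with a positive or
an earlier negative are rejected and redrawn (budget: 1,000 attempts per
negative, then a hard error naming the attempt count).  The 10%
mean-length agreement is asserted post hoc and logged rather than forced
by further resampling.

## The synthetic benchmark generator

`generate_synthetic()` emulates the compositional signature that real
ACE-inhibitory collections show: positives enriched in Pro and Leu,
depleted in Cys, Met and Trp.  Defaults:

* positive residue law: P = L = 0.12, C = M = W = 0.01, remaining mass
  uniform over the other 15 residues;
* negative (background) law: uniform 0.05;
* shared length law: lengths 2–15 with mode at 4–5 residues and mean
  ≈ 5.8, chosen to mirror the short di-/tri-peptide-heavy length profile
  of known inhibitors.

What the generator does *not* emulate: positional motifs (real inhibitors
favour Pro/aromatic residues at the C-terminus), correlated residues,
database redundancy and labelling noise.  Residues are i.i.d. given
length, so *all* learnable signal is compositional; the correlation
features contribute little on this benchmark by construction.  A green
pipeline on synthetic data therefore demonstrates correct plumbing,
calibration and contracts — not field performance on curated databases.
The default effect size makes the benchmark learnable but deliberately
far from separable: because the positive and negative residue laws
overlap heavily and peptides are short, even the exact likelihood-ratio
classifier cannot approach AUC 1, and fitted models on 800 peptides
typically land in the high 0.7s to low 0.8s.  The test suite asserts that
every family beats AUC 0.7 on the fixed benchmark seed.

## Classifier families

All four families sit behind `model_config()` / `fit_model()` /
`predict_proba()` and emit positive-class probabilities, so a single
decision threshold applies uniformly.

* **Gradient boosted trees** (xgboost): learning rate 0.01, 1,000 trees,
  depth 4, min child weight 1, gamma 0, subsample 0.8; the only family
  permitted to accept missing feature values (its splits learn a default
  direction).
* **RBF SVM** (e1071/libsvm): C = 1, $\gamma$ = 0.001.  Margins are not
  probabilities, so the fit is followed by Platt-style calibration: a
  logistic regression of the training labels on the training decision
  values.  This in-package calibration is deterministic, which libsvm's
  internal cross-validated estimator is not (it draws from a C-level RNG
  outside `set.seed()`'s control).
* **Random forest** (ranger): 80 trees, max depth 13, minimum node size
  to split 150, minimum terminal node size 15, 7 candidate features per
  split, OOB error kept, default seed 10.
* **k-NN**: K = 5, Euclidean distance; the predicted probability is the
  fraction of positive labels among the K nearest training rows.  Ties
  in distance are broken by training input order (stable sort), which
  pins determinism.

Determinism under a fixed seed is property-tested for every family.  Note
that with only tens of training points the forest's min-split of 150
prevents any split; tests that need a tree on toy data override those
hyperparameters explicitly.

## Evaluation protocol

* Strict threshold: predicted positive iff $p > 0.5$; exactly 0.5 is
  negative.
* Metrics: accuracy, sensitivity, specificity, precision; any metric with
  a zero denominator is flagged `NA`, never silently zeroed, and excluded
  from fold averaging with a warning (a silent 0 would bias CIs).
* AUC: Mann–Whitney concordance with midrank tie handling; verified
  against an $O(n^2)$ pair-counting oracle.
* Cross-validation: stratified folds (the datasets are balanced by
  design; stratification reduces fold variance).  Features are encoded
  once before folding — PseAAC depends only on the sequence, so
  pre-encoding cannot leak labels.
* Intervals: fold mean ± $1.96\,\mathrm{SD}/\sqrt{n}$; the raw fold
  values are retained in the report so any other interval construction
  can be applied.
* Cross-dataset protocol: train on one full dataset, test on another,
  repeated with fresh seeds; sequence overlap between the two sets is
  computed and reported because shared sequences trivialize the task.

## Screening rule

Target proteins are cut by exhaustive sliding windows for every
$k \in [2, 9]$ (linear, non-circular — proteins are not circular
molecules), with 1-based inclusive coordinates in UniProt convention.  A
protein of length $L \ge 9$ yields exactly $8L - 36$ windows, a closed
form the tests check for $L$ up to 300.  Duplicate sequences are
deduplicated by default (identical sequences receive identical scores)
with counts retained.

The candidate rule: train the model three times with independent seeds
and score every k-mer each time; flag a k-mer only when all three
probabilities strictly exceed 0.99.  The repetition guards against
single-fit artefacts of the stochastic training procedures.  Control bins
collect k-mers whose probabilities all round to 0.00 or 0.50 at two
decimals (tolerance ±0.005, matching two-decimal probability reporting).
Candidate flagging is monotone in the threshold, and with one repeat of a
deterministic family the screen is idempotent — both are tested.

## Numerical and degenerate-input choices

* Encoding denominator guarded at $|1+\omega\Sigma\tau| > 10^{-8}$
  (unreachable at $\omega = 0.05, \lambda = 1$, but the error is explicit
  rather than a silent Inf).
* Zero-variance property rows are rejected by name at standardization.
* Non-canonical residues (B/J/O/U/X/Z, gaps) are rejected by default with
  the record and position named; a drop-with-warning policy is available.
  Lowercase input is uppercased, not an error.
* Empty FASTA files parse to empty record tables; a protein shorter than
  `k_min` yields an empty k-mer set with a warning, not an error.
* Peptide-list dialect (plain vs id TAB sequence) is detected from the
  first data line and applied to the whole file.

## Problem sizes

The shipped tests and the acceptance script use a 400+400-peptide
synthetic benchmark for cross-validation, 200-peptide training sets for
screening demonstrations, and six synthetic stand-in proteins generated
at the canonical bovine-milk-protein lengths (224, 190, 214, 222, 178,
142 residues) for k-mer counting, coordinate round-trips and full
screens.  These sizes exercise every code path while keeping a complete
run in well under a minute per stage; users reproducing database-scale
studies simply substitute their own inputs.

## Known limitations

* Negative sets are presumed, not validated, non-inhibitors; some true
  inhibitors will contaminate them, biasing sensitivity estimates
  downward.
* The synthetic benchmark carries compositional signal only; performance
  numbers on it say nothing quantitative about curated databases.
* k-mer digestion is theoretical: it ignores whether any protease could
  actually liberate a given fragment.
* The shipped property scales are standard literature values; studies
  using other scales will produce numerically different (if typically
  similar-ranking) features.
* No docking, structure, or activity-regression support: classification
  of primary sequence only.
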