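---
title: "Methods: stacked ensemble and convolutional RBP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble and convolutional RBP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpstack)
```

## The problem

RNA-binding proteins (RBPs) regulate RNA stability, splicing, transport and
translation; in plants they are central to development and stress response.
Experimentally cataloguing them is slow, so sequence-based classifiers are
used to triage candidate proteins. Evolutionary-profile features (PSSMs) are
accurate but expensive to compute at proteome scale. `rbpstack` implements a
lightweight alternative: composition-only features enriched with the
predictions of a small committee of classical learners, classified by a
compact convolutional network.

## The model

### k-peptide composition (KPC)

A protein of length $L$ contains $L - k + 1$ overlapping windows of length
$k$. The KPC vector assigns to each of the $20^k$ possible $k$-peptides $i$
its windowed frequency

$$ f_i = \frac{N_i}{L - k + 1}, $$

where $N_i$ counts occurrences of peptide $i$. Each block is a probability
vector (non-negative, summing to 1 within $10^{-9}$). $k = 1$ is amino-acid
composition (AAC, 20 dimensions), $k = 2$ dipeptide composition (DPC, 400),
$k = 3$ tripeptide composition (TPC, 8000). The default encoding
concatenates $k = 1, 2$ into 420 columns; $k = 3$ is supported for
ablations (8420 columns) but adds sparsity and noise faster than signal at
typical dataset sizes. Feature names are the peptides themselves in
lexicographic order over the fixed alphabet `ACDEFGHIKLMNPQRSTVWY`, so
column identity is stable across runs and files. KPC frequencies already lie
in $[0,1]$ and are not rescaled before model input.

### Stacked meta-features

Four base learners are trained on the KPC matrix: an RBF-kernel SVM,
ridge-regularised logistic regression, linear discriminant analysis, and a
leaf-wise histogram gradient-boosted tree model (the LightGBM algorithm
family, fitted through xgboost's `lossguide` growth policy). Their
positive-class probabilities are appended to the KPC block as columns named
`<learner>_Pred_Result`, giving the default 424-dimensional fused input.

Each column is produced **out-of-fold**: the training rows are split into
five stratified folds and row $i$ is scored by a model trained on the folds
that exclude $i$. In-sample stacking (scoring every row with a model trained
on all rows) optimistically biases the meta-features — the classifier
partially reads the training labels through them — so it is available only
as an explicit `oof = FALSE` toggle for comparison, never the default.
Unseen sequences are scored by full-data models, standard stacking practice
at deployment. Probabilities rather than hard labels are used because the
downstream correlation analysis needs continuous columns; SVM scores are
obtained by Platt calibration of the decision values (a one-dimensional
logistic fit on a training subsample), and inputs of the SVM/LR/LDA/KNN
learners are standardised with statistics of the training rows only.

Eleven candidate learners are registered (SVM, LR, LDA, LightGBM, XGB, RF,
GBDT, KNN, DT, NB, BG) so the committee itself can be re-derived: each
candidate's out-of-fold column carries a single-feature AUC, and
`tune_learner()` reproduces the random-search-under-CV protocol for
hyperparameters (library defaults are used when no search is run).

### Correlation pruning

Meta-features inherit information from the same underlying matrix and can be
nearly collinear. All pairwise Pearson coefficients among the candidate
columns are computed; any pair with $|r| > 0.80$ is resolved by dropping the
member with the lower out-of-fold AUC. Pairs are processed in deterministic
order ($|r|$ descending, ties by name), and a feature already dropped is
skipped later — with three or more mutually correlated columns an ad hoc
order would make the outcome path-dependent. One pair is exempt by default:
the SVM and LDA columns, whose correlation typically exceeds the threshold
but whose decision mechanisms (margin maximisation vs. class-variance
discrimination) are complementary enough that both are kept. The allow-list
is user-overridable. Zero-variance columns are excluded from the
correlation table and reported, never silently dropped.

### The convolutional classifier

The fused vector of width $n$ (424 by default) is treated as a length-$n$,
single-channel 1D feature map — there is no embedding layer. Three parallel
branches apply valid 1D convolutions with kernel sizes 3, 4 and 5 (64
filters each, ReLU), followed by global max pooling, which reduces each
branch to a 64-vector regardless of $n$. The three pooled vectors are fused
by scaled dot-product self-attention: treating them as a length-3 sequence
of 64-dim tokens with query = key = value,

$$ A = \mathrm{softmax}\!\left(\frac{VV^\top}{\sqrt{d}}\right), \qquad
   O = AV, $$

and the attended tokens are concatenated (192 units). With attention
disabled the branches are concatenated directly — both fusion variants are
implemented because the architecture admits either reading; attention is the
default. A 64-unit ReLU dense layer with dropout 0.5 and a sigmoid output
complete the network.

Training minimises binary cross-entropy with Adam (learning rate $10^{-3}$,
batch size 32), for at most 50 epochs with early stopping: if the validation
loss fails to *strictly* decrease for 5 consecutive epochs, training stops
and the best-epoch weights are restored. The dense width, optimizer, batch
size and dropout rate are surfaced in `textcnn_config()` rather than
hard-coded, since reasonable alternatives exist; the listed values are the
package defaults. Convolutions use valid padding (branch length
$n - s + 1$); global max pooling makes this invisible in shapes but it is
the numerically defined choice. One integer seed controls weight
initialisation, shuffling and dropout masks; bit-identical reruns are
promised within one software environment. The forward convolution is an
im2col matrix product (BLAS) with a small C++ kernel for bias/ReLU/pooling
and the backward pass exploits the sparsity of max-pooling gradients.

An embedding **baseline** of the original architecture is included for
comparison: residues integer-encoded over a 21-token vocabulary (20 amino
acids + padding), a trainable embedding layer, then the identical
convolution/pooling/dense stack, with sequences padded or truncated to a
fixed length.

### Evaluation

From the confusion cells (TP, TN, FP, FN):
ACC $= (TP+TN)/(TP+TN+FP+FN)$, SN $= TP/(TP+FN)$, SP $= TN/(TN+FP)$,
Precision $= TP/(TP+FP)$, F1 $= 2TP/(2TP+FP+FN)$, and

$$ \mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, $$

all reported as percentages. AUC is the rank-based Mann–Whitney statistic
(exact tie handling, equal to trapezoidal ROC integration). Zero-denominator
ratios are returned as `NA` carrying a reason attribute — a
perfect-specificity fold can zero $TP+FP$, and silently reporting 0 would
corrupt fold averages. A support-weighted F1/Precision mode is provided for
independent-set reporting conventions.

Cross-validation refits the **entire** pipeline per fold — stacking,
selection and network training all see only the fold's training portion.
Fold summaries are mean ± population standard deviation (ddof = 0); the
population convention is the one consistent with the per-fold summaries this
pipeline family reports, and sample sd is available via a flag. Ablation
ladders (D0 = bare KPC, D1..D4 adding the SVM, LR, LDA and boosted-tree
columns in that order; widths 420..424) are evaluated under identical fold
partitions, and adjacent sets are compared with one-tailed paired t-tests
(alternative: the larger set is better) on per-fold ACC and MCC, with
Shapiro–Wilk normality checks on the paired differences. The paired
differences are the quantity entering the t statistic, so they are what the
normality check must support; per-sample Shapiro p-values are also returned
for reporting.

## The synthetic benchmark

Real RBP benchmarks are distributed externally; the generator provides a
self-contained stand-in with the statistical structure the method assumes —
class-differential k-peptide composition:

* negatives are i.i.d. draws from a background composition (uniform by
  default; a SwissProt-like preset exists) with log-normal lengths
  (mean 350, sd 150 residues, truncated to [50, 2000] — typical of protein
  databases);
* positives are generated identically, then motif peptides are substituted
  in at non-overlapping, uniformly chosen positions, each eligible position
  selected with probability `effect_size × p`. Substitution rather than
  insertion keeps the length distribution of the two classes *identical*,
  so composition is the only signal;
* the default motifs are three arginine/glycine-rich 3-peptides
  (`RGG`, `GRG`, `RGR` at $p = 0.002$), an echo of the RGG-box repeats of
  real RBPs. At the default `effect_size = 1` a typical 350-residue positive
  carries only a couple of motif copies — a deliberately weak, realistic
  signal. The "strong enrichment" condition used in the shipped end-to-end
  checks is `effect_size = 5` (roughly ten motif copies per sequence, well
  over 2× dipeptide enrichment, while most of each sequence remains
  background); `effect_size = 0` makes the class laws identical and
  provides the null calibration.

What passing tests on this generator do **not** show: real RBPs differ from
non-RBPs through structured binding domains, disorder, and evolutionary
signal, none of which the generator simulates. Synthetic results validate
the machinery (leakage-freedom, calibration, signal recovery, monotonicity
in effect size), not biological accuracy; accuracy claims require the
external benchmark (see `inst/scripts/rbplight_integration.R`).

## Numerical and design choices

* **Alphabet order** for feature naming is fixed (`ACDEFGHIKLMNPQRSTVWY`);
  any fixed order is consistent with the composition definition.
* **Nonstandard residues** (B, J, O, U, X, Z, `*`, gaps) are removed
  per-residue by default (`drop_residue`), preserving as many sequences as
  possible — KPC is frequency-based, so removal only shortens $L$. A
  `drop_record` policy is available. Sequences emptied by sanitisation are
  rejected with an explicit reason.
* **Sequences shorter than the largest k** are rejected at encoding time
  (training) or routed to a rejects table (prediction), never silently
  padded.
* **Dense storage** is used for all KPC blocks; at $k \le 3$ (8420 columns)
  this remains desk-scale.
* **Strict early stopping**: an epoch counts against patience unless the
  validation loss is strictly below the best seen.
* **Undefined statistics** (zero-variance correlation inputs, degenerate
  t-tests, zero-denominator metrics) raise errors or tagged `NA`s; nothing
  degrades to a silent 0.
* **Problem sizes in the shipped checks**: the test-suite's end-to-end runs
  use 1000 + 1000 synthetic sequences for signal recovery and the ablation
  ladder, and 500 + 500 for the null calibration (its binomial acceptance
  band is computed from the n actually used); `scripts/acceptance.R`
  re-runs the strong-signal pipeline at 1000 + 1000 and the null at
  500 + 500. These sizes were chosen once as representative desk-scale
  experiments.

## Known limitations

* Composition features ignore residue order beyond k-mers; motifs longer
  than the largest k are invisible except through their sub-peptides.
* The committee's value depends on diversity; on very easy or very hard
  problems the meta-features correlate strongly and pruning may remove all
  but one (the reported selection behaviour, not a failure).
* CPU-only training is the contract; the network is small by design, and no
  GPU path or pretrained protein language model is provided.
* Hyperparameters of the base learners default to library conventions; the
  random-search tuner reproduces the protocol for deriving better ones, not
  any specific published setting.
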