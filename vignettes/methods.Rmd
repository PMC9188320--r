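---
title: "Extracting AHI and SaO2 from scanned sleep-study reports: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting AHI and SaO2 from scanned sleep-study reports: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polysomnography (overnight sleep study) reports reach the EHR as scanned
page images. Two findings matter for most secondary-use research: the
apnea–hypopnea index (AHI, events per hour of sleep) and the minimum
oxygen saturation (SaO₂, percent). A page carries dozens of other
numbers — hypopnea counts, sleep-stage durations, mean saturations — so
extraction is not "find a number" but "find *the* number". `sleepscan`
casts this as a 3-way classification of *numeric candidates*: every OCR
word fully matching `[0-9.,%]+` that parses to a finite value is a
candidate, labelled AHI, SaO₂, or Other. At the document level, the
candidate with the highest class probability represents the document,
and document accuracy is the fraction of documents whose chosen value
equals the gold value.

## Pipeline stages and their parameters

**Image preprocessing.** Three primitives compose into six methods:
gray-scaling (luma weights 0.299/0.587/0.114, rounded), one iteration of
dilation followed by erosion, and a multiplicative contrast gain
`clip(round((1 + pct/100) * pixel), 0, 255)` at 20% or 60%. The kernel
geometry is a 3×3 square with edge-replicated borders: the minimal
neighbourhood that removes 1–2 px speckle while restoring any stroke at
least 3 px wide exactly (opening with a rectangular element is exact on
rectangles at least as large as the element). We use standard
bright-region-growing dilation, so dilate-then-erode is an opening with
respect to *dark* strokes — the polarity that removes dark noise dots on
a light page. The contrast model is a pure gain about zero; applying the
gain about a midpoint instead would darken the background, which
contradicts its purpose of saturating near-white scanner noise to white,
so the zero-anchored form is used. Default method: gray + dilate/erode +
20% contrast.

**OCR.** The package defines a word-level TSV dialect (`page_num, left,
top, width, height, conf, text`; top-left pixel origin) and treats the
engine as pluggable. Since character recognition itself is not the
subject here, tests run on synthetic backends: *perfect* (returns the
page's planted word plan), *perfect-noise* (seeded character confusions
such as I→!, l→1, O→0, S→5), and *degraded*, whose confusion rate is
`min(0.5, 200 × residual dark fraction outside word boxes)` — a simple
monotone link between image cleanliness and text quality that makes the
preprocessing matrix produce non-trivial differences. Word confidence is
carried but unused by default (floor −1 keeps all words); no spelling
correction is attempted.

**Deidentification.** Name tokens and MRNs are matched per-token,
case-insensitively and exactly against a lookup table, and replaced by
`[PATNAME]`/`[MRN]`; any word shaped like `d{1,2}/d{1,2}/d{2,4}`
becomes `[DATE]`. Exact matching is conservative (no fuzzy matches that
could silently miss), the broad date pattern fails safe for privacy, and
the operation is idempotent and geometry-preserving. Placeholders
contain brackets and letters, so they can never re-enter the candidate
stream.

**Segmentation.** Windows take up to 10 words on each side of the
candidate (21 total), crossing page boundaries in reading order and
truncating only at report boundaries; the page number rides along as a
structured feature, so the model can still learn page effects. Numeric
parsing strips `%`, trailing `.`/`,` (sentence punctuation attached to
the OCR word), and thousands separators. Label matching is exact
(tolerance 0) by default because the generator's planted tokens parse
back to the gold values exactly; a tolerance flag exists for
rounded-gold scenarios. When one value matches both golds, AHI takes
precedence — pinned in a test; the synthetic generator avoids ever
producing that tie so labelling on clean corpora is exact. Candidates
are not deduplicated within a report: repeated mentions of the gold
value are separate (all correctly labelled) instances.

**Splits.** 70% development / 30% test at report level, never segment
level; development further split 6:1 into training and validation for
the sequence models. Rounding is half-up for the development share and
floor for the validation seventh — the only pair of rules that
reproduces the canonical 669/286 and 574/95 sizes from 955 reports.

## Bag-of-words models

Features are six structured values (left, top, width, height, page,
parsed value) plus tf–idf over the 400 most frequent (lowercased,
stopword-filtered) training-window terms, L2-normalised per window. The
stopword list is vendored into the package so the vocabulary cannot
drift with library versions. The idf is smoothed,
`ln((1+n)/(1+df)) + 1`, so a term never seen in a cross-validation fold
still has finite weight. Frequency ties at the cap break
lexicographically, making the vocabulary deterministic.

The seven classifiers and their canonical settings: unpenalised
multinomial logistic regression; L1- and L2-penalised multinomial
logistic models at λ = 0.01 (fit along a decreasing λ path for
convergence, predicted at the target λ); a polynomial-kernel SVM with
probability calibration; kNN with k = 3 (per-class probabilities are
neighbour fractions); multinomial Naive Bayes with additive smoothing
α = 0.5 (implemented in-package; it requires non-negative features, which
holds for counts and layout magnitudes); and a 500-tree random forest
with √d features per split. The six structured columns are standardised
(training mean/SD) for the linear, kernel and distance-based models and
fed raw to the trees and NB. Hyperparameter selection, when used, is
5-fold cross-validation with folds drawn at report level; grid ties
resolve to the first entry, and the winner is refit on the full
development set.

## Sequence models

The dual-branch network: a structured branch (6 inputs → two 100-unit
dense layers, 20% dropout each) and a sequence branch (the encoded
21-word window, capped at 32 tokens, right-padded and masked). The
BiLSTM path embeds whitespace tokens with 100-dimensional CBOW word2vec
vectors trained on the training windows (negative sampling;
out-of-vocabulary tokens map to the zero vector) and runs two
bidirectional LSTM layers; the second layer's final hidden state
(forward‖backward) feeds a dense projection. The transformer path trains
its own token and position embeddings and encoder layers from random
initialisation — the encoder is pluggable and deliberately small by
default, since no pretrained clinical weights ship with the package —
and the per-token outputs are flattened as stated (32 × d), not pooled.
Branches concatenate into a 200-unit classifier layer with 20% dropout
and three sigmoid outputs. The loss is per-class binary cross-entropy
against one-hot targets, matching the sigmoid output design; the
outputs then need not sum to one, which is immaterial for argmax
extraction. A softmax/categorical option exists behind a flag.

Training uses Adam, batch size 64, a fixed epoch budget with no early
stopping, and per-epoch checkpointing; the returned model is the
checkpoint with minimum validation cross-entropy (ties → earliest
epoch). Canonical learning rates are 2e-4 (BiLSTM) and 2e-6 (appropriate
for fine-tuning a large pretrained encoder); desk-scale experiments with
the small from-scratch encoders use 1e-3–5e-3, set in the experiment
helpers. The networks run on a small reverse-mode tape autodiff written
for this package (there is no R deep-learning runtime in its dependency
set); gradients are verified against central differences to ~1e-6 in the
test suite, and identical seeds reproduce identical weights. The
"batch normalisation" of the structured inputs is realised as fixed
standardisation by training-set statistics — a constant affine map,
which at these widths serves the same conditioning purpose while keeping
training exactly reproducible.

Width choices the architecture description leaves open: the
sequence-branch projection after flattening is 100 units (mirroring the
structured branch), and the BiLSTM hidden width is 100 per direction.
Tests and experiment matrices shrink all widths (e.g. hidden 8, d = 16)
purely for speed; the defaults remain the canonical sizes.

## Evaluation and statistics

Segment metrics are one-vs-rest recall, precision (0 with a warning when
nothing is predicted positive) and F1. AUROC is the Mann–Whitney
concordance with ties counted ½, computed by the rank formula and
cross-checked against brute-force pair counting. DeLong's method
provides the AUROC variance (placement-value covariance), 95% CIs
(auc ± z₀.₉₇₅·SE), and the paired two-sided z-test; with degenerate
variance the CI collapses and p is reported as 1 with a warning.
Document accuracy CIs are Wald by default (Wilson by flag). Model
accuracies are compared with Pearson's chi-squared without continuity
correction on the 2×2 correct/incorrect table; this treats the two
models' document sets as independent even though they are paired, so a
McNemar variant is provided for paired flags. Bonferroni adjustment
takes an *explicit* family size m (adjusted p = min(1, m·p)); m is never
inferred from the vector length. Documents whose gold value never
survived OCR count as extraction failures with the denominator
unchanged.

## The synthetic corpus

The generator emulates the published corpus statistics as its defaults:
pages per report drawn from {1..6} with probabilities (.20, .35, .15,
.15, .10, .05) — median 2, quartiles [2, 4]; numeric values per page
from a rounded normal (mean 44, SD 9, clamped to [5, 90]) — median 44
(the real corpus has a heavier right tail from table-dense pages, which
we do not model); AHI and SaO₂ from truncated normals whose *truncated*
moments equal the published mean/SD (34.9/31.3 on [0, ∞); 76.5/15.6 on
(0, 100]). Naively truncating a normal with those parameters at zero
would inflate the AHI mean to ≈42.7, so the generator solves for the
parent parameters by moment matching at spec-construction time; the
resulting AHI law is strongly right-skewed, which is also clinically
realistic. AHI values are formatted to one decimal and SaO₂ to integers,
matching how the values appear in report text. 52.8% / 45.9% of reports
carry multiple AHI / SaO₂ mentions (2, occasionally 3).

Sentences come from a template pool paraphrasing the narrative style of
real reports ("The total APNEA/HYPOPNEA INDEX (AHI) was 19.5.", "The
lowest desaturation was 87, with a mean value of 95."), plus distractor
sentences carrying other indices and numeric-free prose. Distractor
values resample until they differ from both gold values
(`suppress_collisions = TRUE`, the default), and the two gold values are
kept distinct, so value-match labelling agrees with the planted roles
exactly. Page-1 carries a PHI header (name, MRN, dates) so
deidentification is exercised end to end; the joint distribution of
numerics across pages is i.i.d. per page.

Rendered pages draw each word as rows of filled blocks at least 3 px
wide inside its recorded bounding box — synthetic glyphs, since
recognition is performed by the plan-reading perfect backend, not from
pixels. What passing tests on this corpus demonstrate is that the
*pipeline machinery* — preprocessing, candidate segmentation, window
construction, labelling, training, extraction, statistics — is correct
and end-to-end coherent; they do not certify performance on real scans,
whose OCR noise, layouts, tables and handwriting are far richer than the
generator's narrative pages.

## The structured-input ablation

To test the claim that layout features add signal beyond text, the
generator has a text-ambiguous mode: gold sentences and all numeric
distractors use the *identical* sentence template, a prose buffer
separates the page-1 header from the gold sentence (so header
placeholders cannot leak position into the text window), and the gold
value is always planted at the top of page 1. Text then carries no class
signal and layout carries all of it. On such corpora
`ablate_structured()` trains the dual-branch network with and without
the structured branch over several seeds and compares validation AUROC.

Two design points matter at desk scale. First, a from-scratch sequence
encoder on a few dozen reports *memorises* the training windows, so with
a high-capacity encoder both arms converge to early, noisy checkpoints
and the comparison washes out; the ablation therefore fixes a
deliberately low-capacity encoder (d = 8, one layer). Second, the
canonical 6:1 validation split leaves too few validation reports for a
stable AUROC at n = 64, so the ablation uses a 60/40 report split. Under
these documented conditions (`ablation_corpus_spec()`, 15 epochs,
lr 3e-3) the with-structured arm exceeds the without-structured arm by
roughly 0.25 AUROC averaged over seeds and classes.

## Numerical and degenerate-input choices

Seeds flow from a single integer through labelled child seeds; every
stochastic stage (generation, splits, initialisation, shuffling,
dropout, noise injection) is reproducible bit-for-bit. Degenerate inputs
are contracts, not crashes: empty OCR pages yield empty word tables;
unparseable candidate tokens are excluded rather than erroring;
precision with no predicted positives is 0 with a warning; zero-margin
chi-squared tables and zero-variance DeLong comparisons report p = 1
with warnings; single-class training data and report-overlapping
train/validation sets are errors. Problem sizes in the tests (30–300
synthetic reports, encoder widths 8–16, 2000 bootstrap replicates, 200
null simulations) were chosen once as the smallest sizes at which the
statistical checks have adequate resolution.

## Known limitations

Extraction uses only the linear reading-order window: values in table
cells whose meaning comes from a column header above them are out of
reach by construction. The generator does not model skew, bleed-through,
handwriting, logos, or table structure. The chi-squared model comparison
ignores pairing (McNemar is offered). The transformer path ships no
pretrained weights, so its desk-scale results reflect training from
scratch, not fine-tuning a clinical language model; the encoder
interface accepts one if available. Finally, all shipped benchmarks are
synthetic: real-corpus performance must be established on real data.
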