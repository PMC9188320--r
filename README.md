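# sleepscan

Clinical findings often live only in scanned documents: a sleep laboratory
faxes a polysomnography report, the PDF lands in the EHR as page images,
and the two numbers a researcher needs — the apnea–hypopnea index (AHI)
and the minimum oxygen saturation (SaO₂) — are locked in pixels.
`sleepscan` implements a complete, tested pipeline for pulling those
values back out:

1. **Image preprocessing** — gray-scaling, one iteration of 3×3
   dilate/erode (a morphological opening with respect to dark strokes,
   removing scanner speckle), and a multiplicative contrast gain of 20% or
   60%; six method combinations selectable as an experiment matrix.
2. **OCR adapters** — a word+position TSV dialect, a QA overlay renderer,
   and engine-free synthetic backends (perfect, seeded
   character-confusion noise, and a "degraded" backend whose error rate
   tracks residual speckle) so the NLP stages are testable without an OCR
   engine.
3. **Deidentification** — masking of patient names, medical record
   numbers and date-shaped words with `[PATNAME]`/`[MRN]`/`[DATE]`
   placeholders.
4. **Segmentation** — numeric candidates are words fully matching
   `[0-9.,%]+`; each candidate gets a 21-word context window (10 words a
   side), six structured layout features (left, top, width, height, page,
   parsed value), and a label assigned by matching the document's gold
   values.
5. **Classification** — the task is 3-way (AHI / SaO₂ / Other) per
   candidate. Seven bag-of-words classifiers (tf–idf over the top-400
   training terms + structured features) and a dual-branch neural network:
   a structured-input branch and a sequence branch (2-layer BiLSTM over
   corpus-trained CBOW embeddings, or a pluggable transformer encoder),
   concatenated into shared classifier layers with three sigmoid outputs.
6. **Document-level extraction and evaluation** — the candidate with the
   highest class probability represents the document
   (`document accuracy = # documents correctly extracted / # documents`),
   with segment-level recall/precision/F1, one-vs-rest AUROC with DeLong
   variance/CI/test, chi-squared accuracy comparison, and explicit-family
   Bonferroni adjustment.

Because real sleep-study corpora are protected health information, the
package ships a seeded synthetic report generator that emulates the
published corpus statistics (median 2 pages/report, ~44 numeric values
per page, AHI ~ mean 34.9/SD 31.3, SaO₂ ~ mean 76.5/SD 15.6, 52.8%/45.9%
multi-mention rates) with exact ground truth, so every stage runs and is
verified at desk scale.

## A worked example

```r
library(sleepscan)
library(dplyr)

corpus <- corpus_spec(n_reports = 300, seed = 42) %>% generate_corpus()
words  <- deid_corpus(corpus$words, corpus$phi)
cands  <- segment_corpus(words, corpus$gold)
split  <- split_documents(corpus$gold$report_id, seed = 42)

dev  <- cands %>% filter(report_id %in% split$dev_ids)
test <- cands %>% filter(report_id %in% split$test_ids)

vocab  <- build_vocab(dev$segment)
rf     <- train_bow(featurize(dev, vocab), dev$label, "rf", seed = 42)
scores <- predict_scores(rf, featurize(test, vocab))

eval_report(test, scores, corpus$gold, report_ids = split$test_ids) %>%
  select(class, recall, precision, f1, auroc, doc_accuracy)
#> # A tibble: 2 × 6
#>   class recall precision    f1 auroc doc_accuracy
#>   <chr>  <dbl>     <dbl> <dbl> <dbl>        <dbl>
#> 1 AHI    0.912     0.948 0.930 1.000        0.989
#> 2 SaO2   0.662     0.966 0.785 0.999        0.933
```

Reading the output: on the 90 held-out synthetic reports, the random
forest ranks AHI candidates essentially perfectly (AUROC ≈ 1.0) and the
document-level argmax recovers the correct AHI in 98.9% of documents and
the correct SaO₂ in 93.3%. Segment-level recall is lower than document
accuracy by design — a document is extracted correctly as long as *one*
of its gold-value mentions outranks every distractor.

The sequence models follow the same pattern:

```r
train <- cands %>% filter(report_id %in% split$train_ids)
val   <- cands %>% filter(report_id %in% split$val_ids)
net <- fit_sequence_model(
  train, val,
  spec = network_spec("bilstm", emb_dim = 16, hidden = 8),
  cfg  = train_config(lr = 5e-3, epochs = 8, seed = 1))
autoplot(net)                 # training curves with the chosen checkpoint
predict_scores(net, test)     # per-candidate 3-class probabilities
```

`run_experiment()` reproduces the three experiment designs (classifier
matrix, preprocessing matrix, training-size curve), and
`run_pipeline()` / the `inst/cli/sleepscan` script orchestrate all stages
from a single config with per-stage artifacts and provenance.

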