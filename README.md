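# dilitext

Controlled-vocabulary text classification of drug-induced liver injury
(DILI) risk from regulatory free text.

## The problem

Drug labels and safety abstracts describe adverse events in stereotyped
clinical prose. Classifying whether a document signals DILI risk is
usually done by expert reading. `dilitext` implements an automated
bag-of-words alternative built around a controlled vocabulary of
preferred terms (a MedDRA-PT-style list, supplied by the user — licensed
dictionaries are not shipped):

1. **Extraction** — every token is discarded *unless* it participates in a
   longest-match, non-overlapping phrase match against the dictionary (plus
   an explicit synonym/stem recoding table, e.g. "autoimmune hepatitis" →
   "hepatitis"). This replaces generic stop-word removal.
2. **TF-IDF** — the document-term matrix holds
   `w(d,t) = tf(d,t) · log10(N / df(t))`.
3. **Gradient-boosted trees** — a second-order boosted tree ensemble
   (binary logistic objective; implemented in-package with Rcpp) predicts
   the 0/1 DILI indicator, evaluated by repeated stratified
   cross-validation (k = 5 folds × R = 10 sets) with ACC, AUC, MCC, RMSE,
   precision, sensitivity, specificity; term importance is reported as
   splits / gain / cover.
4. **Decision support** — cost-sensitive threshold (profit-matrix)
   analysis, probability-decile consistency with expert labels,
   Latin-hypercube hyperparameter autotuning, multi-learner screening
   under nested CV, and frozen-IDF scoring of new or cross-corpus
   documents from a saved JSON model sidecar.

A planted-signal synthetic corpus generator makes every stage testable
without external or licensed data.

## Worked example

```r
library(dilitext)

spec   <- generator_spec(n_docs = 300, vocabulary_size = 200,
                         n_signal_terms = 10, rate_ratio = 4, seed = 11)
toy    <- make_toy_dictionary(spec)        # dictionary + recoding map
corpus <- simulate_corpus(spec, toy)       # labeled documents

built <- corpus_to_dtm(corpus, toy$dict, toy$recoding, min_freq = 1)
built$dtm
#> <dili_dtm> 300 documents x 200 terms; 16044 non-zero TF-IDF weights

plan <- make_fold_plan(corpus$label, k = 5, R = 10, seed = 11)
cv   <- cross_validate(built$dtm, corpus$label, booster_config(seed = 11), plan)
cv$report
#> training:
#>   ACC           0.995 (sd 0.003)
#>   AUC           1.000 (sd 0.000)
#>   ...
#> validation:
#>   ACC           0.924 (sd 0.033)
#>   AUC           0.978 (sd 0.018)
#>   MCC           0.831 (sd 0.075)
#>   RMSE          0.253 (sd 0.032)
#>   precision     0.927 (sd 0.048)
#>   sensitivity   0.848 (sd 0.084)
#>   specificity   0.964 (sd 0.025)
```

The validation block is the honest estimate: on this synthetic corpus the
ten planted signal terms separate the classes well (AUC 0.978), with the
usual training-side optimism above it. Term importance recovers the
planted signal:

```r
model <- train_booster(built$dtm, corpus$label, booster_config(seed = 11))
imp   <- importance(model)
head(imp[, c("term", "splits", "gain", "gain_rank")], 5)
#>            term splits     gain gain_rank
#> 1        hesuze     21 9.129299         1
#> 2 jubeza nesevo     23 5.201828         2
#> 3        pugatu     16 5.142577         3
#> 4 sijare pupero     11 5.125826         4
#> 5        kekuhe     10 4.566728         5
sum(toy$signal_terms %in% imp$term[1:20])
#> [1] 10    # all 10 planted terms in the top 20 by gain
```

Raising the classification threshold trades false positives for false
negatives (the profit-matrix view; FN = DILI called non-DILI):

```r
oof <- rowMeans(cv$scores)                 # out-of-fold probabilities
profit_analysis(oof, corpus$label)
#>   threshold predicted_positive fn fp
#> 1      0.25                125  4 26
#> 2      0.50                 95 13  5
#> 3      0.75                 57 46  0

consistency_report(oof, corpus$label)
#> overall consistency: 94.0%
#>   [0.0, 0.1)  n= 115  100.0%
#>   ...                        # middle deciles drop toward ~55-80%
#>   [0.9, 1.0]  n=  14  100.0%
```

Real corpora are read with `read_corpus()` (CSV/TSV: `doc_id`, `text`,
`label`, `source`), dictionaries with `load_dictionary()` and recoding
tables with `load_recoding()`. Models are saved/reloaded with
`save_model()` / `load_model()` and applied to new documents with
`predict_new()` (training IDF frozen in the sidecar) or across corpora
with `cross_corpus_predict()`.

## Command line

```sh
Rscript -e 'dilitext::dili_cli()' simulate --n-docs 300 --seed 11 --out sim
Rscript -e 'dilitext::dili_cli()' evaluate \
    --corpus sim/corpus.csv --dictionary sim/dictionary.txt \
    --recoding sim/recoding.tsv --folds 5 --repeats 10 --seed 11 --out run
```

(or use the installed `exec/dilitext` script). Subcommands: `simulate`,
`build-dtm`, `train`, `evaluate`, `importance`, `predict`, `screen`; every
output directory contains a `manifest.json` sufficient to re-run the
command bit-identically.

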