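# shared fixtures, built in code at test time

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# small liver-flavoured dictionary + recoding used across vocab/dtm tests
liver_dict <- function() {
  term_dictionary(c("hepatotoxicity", "hepatic failure", "hepatitis",
                    "jaundice", "liver injury", "failure",
                    "aminotransferase", "liver function test"),
                  name = "fixture")
}

liver_recoding <- function() {
  recoding_map(c("autoimmune hepatitis" = "hepatitis",
                 "chronic hepatitis b" = "hepatitis",
                 "aminotransferases" = "aminotransferase",
                 "acute hepatic failure" = "hepatic failure"))
}

# small strong-signal synthetic world for fast model tests
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generator_spec(n_docs = 200L, vocabulary_size = 120L,
                             n_signal_terms = 8L, rate_ratio = 4,
                             mean_doc_length = 120, n_phrases = 20L,
                             seed = 42L)
      toy <- make_toy_dictionary(spec)
      corpus <- simulate_corpus(spec, toy)
      built <- corpus_to_dtm(corpus, toy$dict, toy$recoding, min_freq = 1)
      cache <<- list(spec = spec, toy = toy, corpus = corpus,
                     dtm = built$dtm, counts = built$counts,
                     labels = corpus$label)
    }
    cache
  }
})

# the acceptance stated world: generator defaults, fixed seed, full 10x5 CV
acceptance_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generator_spec(seed = 20240603L)
      toy <- make_toy_dictionary(spec)
      corpus <- simulate_corpus(spec, toy)
      built <- corpus_to_dtm(corpus, toy$dict, toy$recoding, min_freq = 1)
      plan <- make_fold_plan(corpus$label, k = 5L, R = 10L,
                             seed = 20240603L)
      cv <- cross_validate(built$dtm, corpus$label,
                           booster_config(seed = 20240603L), plan)
      cache <<- list(spec = spec, toy = toy, corpus = corpus,
                     dtm = built$dtm, counts = built$counts, plan = plan,
                     cv = cv, labels = corpus$label)
    }
    cache
  }
})

# O(n^2) pair-counting AUC oracle (ties count 1/2)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independently coded confusion-metric oracle
metrics_oracle <- function(TP, FP, TN, FN) {
  den <- function(x) if (x == 0) NA_real_ else x
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(ACC = (TP + TN) / (TP + FP + TN + FN),
       MCC = if (mcc_den == 0) NA_real_ else
         (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den,
       sensitivity = TP / den(TP + FN),
       specificity = TN / den(TN + FP),
       precision = TP / den(TP + FP))
}
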