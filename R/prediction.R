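#' Save a trained model as a JSON sidecar
#'
#' Serializes the tree ensemble (node arrays), vocabulary, configuration,
#' threshold and the frozen training IDF (corpus size and per-term document
#' frequencies) to a single plain-text JSON file, sufficient to reload and
#' score new documents.
#'
#' @param model a `dili_booster`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dili_booster"))
  payload <- list(
    format = "dilitext_booster",
    version = 1L,
    vocabulary = model$vocabulary,
    config = unclass(model$config),
    threshold = model$threshold,
    base_margin = model$base_margin,
    n_train = model$n_train,
    idf = model$idf,
    importance = model$importance_raw,
    trees = lapply(model$trees, function(tr)
      lapply(tr, as.vector))
  )
  # digits = I(17): full IEEE double precision, so reloaded models predict
  # bit-identically
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path the JSON sidecar path.
#' @return a `dili_booster`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model sidecar missing: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "dilitext_booster"))
    stop("not a dilitext model sidecar: ", path)
  trees <- lapply(payload$trees, function(tr)
    list(feature = as.integer(tr$feature),
         threshold = as.numeric(tr$threshold),
         value = as.numeric(tr$value),
         left = as.integer(tr$left),
         right = as.integer(tr$right)))
  cfg <- payload$config
  config <- booster_config(cfg$max_depth, cfg$subsample,
                           cfg$colsample_bytree, cfg$min_child_weight,
                           cfg$alpha, cfg$lambda, cfg$learning_rate,
                           cfg$iterations, cfg$seed)
  idf <- payload$idf
  if (!is.null(idf))
    idf$doc_freq <- stats::setNames(as.numeric(idf$doc_freq),
                                    payload$vocabulary)
  structure(list(trees = trees,
                 vocabulary = payload$vocabulary,
                 config = config,
                 threshold = payload$threshold,
                 base_margin = payload$base_margin,
                 importance_raw = lapply(payload$importance, as.vector),
                 idf = idf,
                 n_train = payload$n_train),
            class = "dili_booster")
}


#' Score new documents with a saved model
#'
#' Runs new documents through the training text-mining process: extract
#' controlled-vocabulary counts, weight by TF-IDF, align the columns to the
#' model vocabulary (unseen terms are dropped and logged; vocabulary terms
#' absent from a document are zero), then apply the saved ensemble. By
#' default the IDF uses the *training* corpus size and document frequencies
#' frozen in the model, so a saved model is a fixed prediction formula;
#' `idf_mode = "concat"` instead recomputes document frequencies over the
#' training corpus plus the new documents (the literal concatenate-then-score
#' reading).
#'
#' @param model a `dili_booster` carrying frozen IDF metadata.
#' @param new_docs corpus data.frame with `doc_id` and `text`.
#' @param dict the [term_dictionary()] used at training time.
#' @param recoding the [recoding_map()] used at training time (or NULL).
#' @param idf_mode "frozen" (default) or "concat".
#' @return data.frame `doc_id, probability, class, matched_terms` (total
#'   in-vocabulary term occurrences per document), empty for an empty
#'   corpus.
#' @export
predict_new <- function(model, new_docs, dict, recoding = NULL,
                        idf_mode = c("frozen", "concat")) {
  idf_mode <- match.arg(idf_mode)
  stopifnot(inherits(model, "dili_booster"))
  if (is.null(model$idf))
    stop("model has no frozen IDF metadata; train from a dili_dtm")
  if (nrow(new_docs) == 0L)
    return(data.frame(doc_id = character(0), probability = numeric(0),
                      class = integer(0), matched_terms = integer(0)))
  counts_list <- extract_corpus(new_docs, dict, recoding)
  vocab <- model$vocabulary
  n_new <- length(counts_list)
  tf <- matrix(0, n_new, length(vocab),
               dimnames = list(new_docs$doc_id, vocab))
  dropped <- 0L
  matched <- integer(n_new)
  for (d in seq_len(n_new)) {
    cts <- counts_list[[d]]
    keep <- names(cts) %in% vocab
    dropped <- dropped + sum(cts[!keep])
    matched[d] <- sum(cts[keep])
    if (any(keep)) tf[d, names(cts)[keep]] <- cts[keep]
  }
  if (dropped > 0L)
    message(dropped, " out-of-vocabulary term occurrences dropped")
  df <- model$idf$doc_freq[vocab]
  N <- model$idf$n_docs
  if (idf_mode == "concat") {
    df <- df + Matrix::colSums(tf > 0)
    N <- N + n_new
  }
  idf <- ifelse(df > 0, log10(N / df), 0)
  X <- sweep(tf, 2, idf, "*")
  prob <- predict(model, X)
  data.frame(doc_id = new_docs$doc_id, probability = prob,
             class = as.integer(prob >= model$threshold),
             matched_terms = matched, stringsAsFactors = FALSE)
}

#' Cross-corpus prediction with consistency analysis
#'
#' Scores corpus B with a model trained on corpus A (columns aligned to A's
#' vocabulary) and, when B is labeled, evaluates agreement by the
#' subtraction rule: the rounded-up prediction (probability >= threshold)
#' minus the expert label is 0 for a consistent document and +/-1 for an
#' inconsistent one.
#'
#' @param model corpus-A `dili_booster`.
#' @param corpus_b data.frame with `doc_id`, `text` and (optionally)
#'   `label`.
#' @param dict,recoding the vocabulary resources.
#' @param idf_mode see [predict_new()].
#' @return list with `predictions` (see [predict_new()]) and, when labels
#'   are present, `consistency` (a [consistency_report()]) and
#'   `inconsistency_fraction`; unlabeled corpora get scores only.
#' @export
cross_corpus_predict <- function(model, corpus_b, dict, recoding = NULL,
                                 idf_mode = "frozen") {
  preds <- predict_new(model, corpus_b, dict, recoding, idf_mode)
  labels <- corpus_b$label
  if (is.null(labels) || anyNA(labels))
    return(list(predictions = preds))
  rep <- consistency_report(preds$probability, labels)
  list(predictions = preds, consistency = rep,
       inconsistency_fraction = 1 - rep$overall)
}
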