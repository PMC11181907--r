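#' Assemble per-document term counts into a sparse count matrix
#'
#' Columns are the union of observed canonical terms, sorted
#' lexicographically (C collation) for determinism; rows follow `doc_ids`.
#'
#' @param counts_list list of named integer count vectors (one per document,
#'   as produced by [extract_corpus()]).
#' @param doc_ids unique document ids, same length as `counts_list`; defaults
#'   to `names(counts_list)`.
#' @return a `dgCMatrix` of counts with dimnames (doc_ids x terms). A corpus
#'   in which no document matched any term yields a 0-column matrix with a
#'   warning.
#' @export
build_count_matrix <- function(counts_list, doc_ids = names(counts_list)) {
  stopifnot(is.list(counts_list))
  if (is.null(doc_ids)) stop("doc_ids required")
  doc_ids <- as.character(doc_ids)
  if (length(doc_ids) != length(counts_list))
    stop("doc_ids and counts_list lengths differ")
  if (anyDuplicated(doc_ids)) stop("duplicate doc_id")
  terms <- sort_terms(unique(unlist(lapply(counts_list, names))))
  if (length(terms) == 0L) {
    warning("no terms observed in any document; 0-column matrix")
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(doc_ids), 0L),
                                dimnames = list(doc_ids, character(0))))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(counts_list)) {
    cts <- counts_list[[d]]
    if (length(cts) == 0L) next
    ii <- c(ii, rep.int(d, length(cts)))
    jj <- c(jj, match(names(cts), terms))
    xx <- c(xx, as.numeric(cts))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(doc_ids), length(terms)),
                            dimnames = list(doc_ids, terms))
  methods::as(m, "CsparseMatrix")
}

# locale-independent lexicographic term order
sort_terms <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[order(x, method = "radix")]
}

#' Drop rare term columns from a count matrix
#'
#' Removes term columns below a minimum frequency. The paper-style default
#' counts total corpus occurrences; `mode = "documents"` counts the number of
#' documents containing the term instead.
#'
#' @param m counts `dgCMatrix` from [build_count_matrix()].
#' @param min_freq positive integer threshold; `1` is the identity.
#' @param mode "occurrences" (corpus-total counts) or "documents"
#'   (document frequency).
#' @return the filtered count matrix (rows preserved).
#' @export
filter_min_frequency <- function(m, min_freq,
                                 mode = c("occurrences", "documents")) {
  mode <- match.arg(mode)
  if (!is.numeric(min_freq) || length(min_freq) != 1L || min_freq < 1)
    stop("min_freq must be a positive integer")
  tot <- if (mode == "occurrences") Matrix::colSums(m)
         else Matrix::colSums(m > 0)
  m[, tot >= min_freq, drop = FALSE]
}

#' Weight a count matrix by TF-IDF
#'
#' Computes `weight(d, t) = tf(d, t) * log10(N / df(t))` where `tf` is the
#' raw in-document count, `N` the number of documents and `df(t)` the number
#' of documents containing term `t`. Terms present in every document get
#' weight 0 everywhere; rarer terms are up-weighted relative to common ones.
#'
#' @param m counts `dgCMatrix`.
#' @return a `dili_dtm`: list with `weights` (sparse docs x terms), `doc_ids`,
#'   `terms`, `n_docs` and per-term `doc_freq`.
#' @export
tfidf_weight <- function(m) {
  stopifnot(nrow(m) > 0L)
  n <- nrow(m)
  df <- Matrix::colSums(m > 0)
  idf <- ifelse(df > 0, log10(n / df), 0)
  w <- m %*% Matrix::Diagonal(x = idf)
  w <- Matrix::drop0(w)
  dimnames(w) <- dimnames(m)
  new_dtm(methods::as(w, "CsparseMatrix"), n_docs = n, doc_freq = df)
}

new_dtm <- function(weights, n_docs, doc_freq) {
  terms <- colnames(weights) %||% character(0)
  structure(list(weights = weights,
                 doc_ids = rownames(weights) %||% character(0),
                 terms = terms,
                 n_docs = n_docs,
                 doc_freq = stats::setNames(as.numeric(doc_freq), terms)),
            class = "dili_dtm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dili_dtm <- function(x, ...) {
  cat("<dili_dtm>", length(x$doc_ids), "documents x", length(x$terms),
      "terms;", Matrix::nnzero(x$weights), "non-zero TF-IDF weights\n")
  invisible(x)
}

#' @export
dim.dili_dtm <- function(x) dim(x$weights)

#' Restrict/reorder a DTM to a reference vocabulary
#'
#' Used to score corpus B with a model trained on corpus A: columns are
#' restricted and reordered to `reference_terms`; reference terms absent from
#' the DTM become all-zero columns (document frequency 0).
#'
#' @param dtm a `dili_dtm`.
#' @param reference_terms non-empty ordered character vector.
#' @return a `dili_dtm` over exactly `reference_terms`.
#' @export
align_vocabulary <- function(dtm, reference_terms) {
  stopifnot(inherits(dtm, "dili_dtm"))
  reference_terms <- as.character(reference_terms)
  if (length(reference_terms) == 0L) stop("empty reference vocabulary")
  if (anyDuplicated(reference_terms)) stop("duplicate reference terms")
  idx <- match(reference_terms, dtm$terms)
  n <- nrow(dtm$weights)
  w <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, length(reference_terms)),
                            dimnames = list(dtm$doc_ids, reference_terms))
  present <- which(!is.na(idx))
  if (length(present))
    w[, present] <- dtm$weights[, idx[present], drop = FALSE]
  df <- ifelse(is.na(idx), 0, dtm$doc_freq[idx])
  new_dtm(methods::as(w, "CsparseMatrix"), n_docs = dtm$n_docs, doc_freq = df)
}

#' Export a DTM as MatrixMarket plus plain-text sidecars
#'
#' Writes `weights.mtx` (coordinate MatrixMarket), `terms.txt`, `docs.txt`
#' and `meta.json` (n_docs and per-term document frequencies) under `dir`.
#' The round trip through [import_dtm()] is lossless to 1e-15.
#'
#' @param dtm a `dili_dtm`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_dtm <- function(dtm, dir) {
  stopifnot(inherits(dtm, "dili_dtm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dtm$weights, file.path(dir, "weights.mtx"))
  writeLines(dtm$terms, file.path(dir, "terms.txt"))
  writeLines(dtm$doc_ids, file.path(dir, "docs.txt"))
  jsonlite::write_json(list(n_docs = dtm$n_docs,
                            doc_freq = as.numeric(dtm$doc_freq)),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Import a DTM written by [export_dtm()]
#'
#' @param dir directory holding `weights.mtx`, `terms.txt`, `docs.txt`,
#'   `meta.json`.
#' @return a `dili_dtm`; dimension/sidecar mismatches are an error.
#' @export
import_dtm <- function(dir) {
  paths <- file.path(dir, c("weights.mtx", "terms.txt", "docs.txt",
                            "meta.json"))
  if (!all(file.exists(paths)))
    stop("missing DTM files under ", dir)
  w <- methods::as(Matrix::readMM(paths[1L]), "CsparseMatrix")
  terms <- readLines(paths[2L])
  docs <- readLines(paths[3L])
  meta <- jsonlite::read_json(paths[4L], simplifyVector = TRUE)
  if (ncol(w) != length(terms))
    stop("sidecar mismatch: matrix has ", ncol(w), " columns but terms.txt ",
         "lists ", length(terms))
  if (nrow(w) != length(docs))
    stop("sidecar mismatch: matrix has ", nrow(w), " rows but docs.txt ",
         "lists ", length(docs))
  if (length(meta$doc_freq) != length(terms))
    stop("sidecar mismatch: meta.json doc_freq length != number of terms")
  dimnames(w) <- list(docs, terms)
  new_dtm(w, n_docs = meta$n_docs, doc_freq = meta$doc_freq)
}

#' One-call corpus-to-DTM pipeline
#'
#' [extract_corpus()] then [build_count_matrix()], [filter_min_frequency()]
#' and [tfidf_weight()].
#'
#' @param corpus data.frame with doc_id, text.
#' @param dict a [term_dictionary()].
#' @param recoding a [recoding_map()] or NULL.
#' @param min_freq minimum term frequency (paper: 1 for drug labels, 10 for
#'   the large abstract corpus).
#' @param min_freq_mode "occurrences" or "documents".
#' @return list with `dtm` (a `dili_dtm`) and `counts` (the filtered count
#'   matrix).
#' @export
corpus_to_dtm <- function(corpus, dict, recoding = NULL, min_freq = 1,
                          min_freq_mode = "occurrences") {
  counts <- build_count_matrix(extract_corpus(corpus, dict, recoding),
                               doc_ids = corpus$doc_id)
  counts <- filter_min_frequency(counts, min_freq, min_freq_mode)
  list(dtm = tfidf_weight(counts), counts = counts)
}
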