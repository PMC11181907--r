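#' Specification for the synthetic corpus generator
#'
#' Defaults emulate the published drug-label corpora at desk scale: 600
#' documents, 35% positive, a 500-term controlled vocabulary with 10
#' planted signal terms whose occurrence rate is 4x higher in positive
#' documents, mean document length 150 tokens with half the tokens drawn
#' from a common-word filler list, and 50 multi-word dictionary phrases.
#'
#' @param n_docs number of documents.
#' @param positive_fraction Bernoulli rate of label 1 (paper corpora: 0.35,
#'   0.48, 0.42).
#' @param vocabulary_size number of dictionary terms.
#' @param n_signal_terms how many terms carry label signal.
#' @param rate_ratio signal-term Poisson rate in positives / negatives
#'   (>= 1).
#' @param mean_doc_length mean tokens per document.
#' @param filler_fraction share of tokens drawn from the filler word list.
#' @param n_phrases how many dictionary entries are two-word phrases.
#' @param seed integer seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_docs = 600L, positive_fraction = 0.35,
                           vocabulary_size = 500L, n_signal_terms = 10L,
                           rate_ratio = 4, mean_doc_length = 150,
                           filler_fraction = 0.5, n_phrases = 50L,
                           seed = 1L) {
  spec <- list(n_docs = as.integer(n_docs),
               positive_fraction = positive_fraction,
               vocabulary_size = as.integer(vocabulary_size),
               n_signal_terms = as.integer(n_signal_terms),
               rate_ratio = rate_ratio,
               mean_doc_length = mean_doc_length,
               filler_fraction = filler_fraction,
               n_phrases = as.integer(n_phrases),
               seed = as.integer(seed))
  stopifnot(spec$n_docs > 0, spec$vocabulary_size > 0,
            spec$n_signal_terms >= 0,
            spec$vocabulary_size >= spec$n_signal_terms,
            spec$rate_ratio >= 1,
            spec$positive_fraction >= 0, spec$positive_fraction <= 1,
            spec$filler_fraction >= 0, spec$filler_fraction <= 1,
            spec$mean_doc_length > 0,
            spec$n_phrases <= spec$vocabulary_size)
  structure(spec, class = "generator_spec")
}

# deterministic pseudo-medical word stock: cvcvcv syllable words
pseudo_words <- function(n, seed) {
  cons <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  words <- character(0)
  while (length(words) < n) {
    batch <- vapply(seq_len(2L * (n - length(words)) + 8L), function(i)
      paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE), collapse = ""),
      character(1))
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

filler_word_list <- function() {
  path <- system.file("extdata", "filler_words.txt", package = "dilitext")
  readLines(path)
}

#' Generate a toy dictionary and recoding map
#'
#' Builds `vocabulary_size` pseudo-terms (single words plus `n_phrases`
#' two-word phrases; the planted signal set includes phrases when
#' available) and a recoding map with the rule shapes seen in real
#' synonym/stem curation: plural variants ("...s" -> base term) for a third
#' of the single-word terms and qualified variants ("chronic <phrase>" ->
#' phrase) for a third of the phrases. The map is idempotent by
#' construction.
#'
#' @param spec a [generator_spec()].
#' @return list with `dict` (a [term_dictionary()]), `recoding` (a
#'   [recoding_map()]), and `signal_terms` (canonical signal term names).
#' @export
make_toy_dictionary <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n_single <- spec$vocabulary_size - spec$n_phrases
  stock <- pseudo_words(n_single + 2L * spec$n_phrases, spec$seed + 101L)
  singles <- stock[seq_len(n_single)]
  phrases <- character(0)
  if (spec$n_phrases > 0L) {
    rest <- matrix(stock[n_single + seq_len(2L * spec$n_phrases)], ncol = 2L)
    phrases <- paste(rest[, 1L], rest[, 2L])
  }
  entries <- c(singles, phrases)
  old <- withr_seed(spec$seed + 202L)
  # recoding variants: plural singles, "chronic"-qualified phrases
  n_ps <- floor(length(singles) / 3)
  plural_src <- if (n_ps > 0) sample(singles, n_ps) else character(0)
  n_pp <- floor(length(phrases) / 3)
  qual_src <- if (n_pp > 0) sample(phrases, n_pp) else character(0)
  # signal terms: a couple of phrases when available, the rest single words
  n_sig_ph <- min(max(2L, spec$n_signal_terms - length(singles)),
                  spec$n_phrases, spec$n_signal_terms)
  n_sig_s <- spec$n_signal_terms - n_sig_ph
  signal <- c(if (n_sig_ph > 0) sample(phrases, n_sig_ph),
              if (n_sig_s > 0) sample(singles, n_sig_s))
  restore_seed(old)
  rules <- c(if (n_ps > 0) stats::setNames(plural_src,
                                           paste0(plural_src, "s")),
             if (n_pp > 0) stats::setNames(qual_src,
                                           paste("chronic", qual_src)))
  if (is.null(rules)) rules <- character(0)
  list(dict = term_dictionary(entries, name = "synthetic"),
       recoding = recoding_map(rules),
       signal_terms = sort(signal))
}

#' Simulate a labeled corpus with planted signal terms
#'
#' Each document gets a Bernoulli(`positive_fraction`) label; every
#' dictionary term count is Poisson with a common base rate calibrated so
#' dictionary tokens fill `(1 - filler_fraction)` of the mean document
#' length, except that signal terms use `rate_ratio` times the base rate in
#' positive documents. A third of the mentions of a term that has a
#' recoding variant are emitted as the variant spelling, so extraction must
#' canonicalize to recover the signal. Filler words pad the document to its
#' Poisson length, word order is randomized (phrases kept intact), and
#' light capitalization/punctuation noise exercises normalization.
#'
#' @param spec a [generator_spec()].
#' @param toy result of [make_toy_dictionary()] (regenerated from `spec`
#'   when omitted).
#' @return corpus data.frame `doc_id, text, label, source` with attribute
#'   `"signal_terms"`.
#' @export
simulate_corpus <- function(spec, toy = make_toy_dictionary(spec)) {
  stopifnot(inherits(spec, "generator_spec"))
  dict <- toy$dict
  recoding <- toy$recoding
  terms <- dict$entries
  tok_per_term <- mean(lengths(strsplit(terms, " ", fixed = TRUE)))
  dict_tokens <- spec$mean_doc_length * (1 - spec$filler_fraction)
  if (dict_tokens > spec$mean_doc_length)
    stop("infeasible length: dictionary tokens exceed mean_doc_length")
  base_rate <- dict_tokens / (length(terms) * tok_per_term)
  is_signal <- terms %in% toy$signal_terms
  # variant spellings, inverse of the recoding map
  variant_of <- stats::setNames(names(recoding), unname(unclass(recoding)))
  filler <- filler_word_list()
  n_filler_mean <- spec$mean_doc_length * spec$filler_fraction
  old <- withr_seed(spec$seed + 303L)
  on.exit(restore_seed(old))
  labels <- stats::rbinom(spec$n_docs, 1L, spec$positive_fraction)
  texts <- character(spec$n_docs)
  for (d in seq_len(spec$n_docs)) {
    mu <- base_rate * ifelse(is_signal & labels[d] == 1L,
                             spec$rate_ratio, 1)
    cts <- stats::rpois(length(terms), mu)
    hit <- which(cts > 0L)
    units <- character(0)
    for (t in hit) {
      k <- cts[t]
      term <- terms[t]
      var <- variant_of[term]
      n_var <- if (!is.na(var)) stats::rbinom(1L, k, 1 / 3) else 0L
      units <- c(units, rep.int(term, k - n_var),
                 rep.int(unname(var), n_var))
    }
    units <- c(units, sample(filler, stats::rpois(1L, n_filler_mean), TRUE))
    if (length(units) == 0L) units <- sample(filler, 1L)
    units <- units[sample.int(length(units))]
    # punctuation / capitalization noise
    caps <- stats::runif(length(units)) < 0.1
    units[caps] <- paste0(toupper(substr(units[caps], 1L, 1L)),
                          substr(units[caps], 2L, nchar(units[caps])))
    sep <- ifelse(stats::runif(length(units)) < 0.1, ", ", " ")
    texts[d] <- paste0(units, c(sep[-length(sep)], "."), collapse = "")
  }
  out <- data.frame(doc_id = sprintf("doc%04d", seq_len(spec$n_docs)),
                    text = texts, label = labels, source = "synthetic",
                    stringsAsFactors = FALSE)
  attr(out, "signal_terms") <- toy$signal_terms
  out
}
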