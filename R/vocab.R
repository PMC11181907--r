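#' Tokenize raw text into normalized word tokens
#'
#' Lowercases, treats every non-alphanumeric character (including hyphens and
#' slashes) as a separator, and keeps digits inside alphanumeric tokens, so
#' "hepatitis B surface antigen" becomes `c("hepatitis","b","surface",
#' "antigen")` and "drug-induced" splits into two tokens. Deterministic;
#' empty or all-punctuation input yields `character(0)`.
#'
#' @param text a character scalar (raw document text).
#' @return character vector of tokens.
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

# normalize a term/phrase to its canonical single-spaced lowercase form
normalize_term <- function(term) {
  vapply(term, function(t) paste(normalize_text(t), collapse = " "),
         character(1), USE.NAMES = FALSE)
}

#' Load a preferred-term dictionary
#'
#' Reads a controlled vocabulary (e.g., a MedDRA-PT-style list, one term per
#' line, or a TSV with a named column). Entries are normalized (case-folded,
#' whitespace collapsed, surrounding punctuation stripped) and de-duplicated.
#'
#' @param path file with one term per line, or a TSV when `column` is given.
#' @param column optional column name holding the terms in a TSV file.
#' @param name provenance tag carried on the dictionary (e.g. "MedDRA 26.0").
#' @return a `term_dictionary`: list with `entries` (sorted character vector)
#'   and `name`.
#' @export
load_dictionary <- function(path, column = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read dictionary file: ", path)
  if (is.null(column)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!column %in% names(tab))
      stop("dictionary TSV has no column '", column, "'")
    lines <- as.character(tab[[column]])
  }
  entries <- unique(normalize_term(lines))
  entries <- sort(entries[nzchar(entries)])
  if (length(entries) == 0L) stop("empty dictionary: ", path)
  message("loaded dictionary '", name, "': ", length(entries), " entries")
  new_term_dictionary(entries, name)
}

#' Construct a term dictionary from a character vector
#'
#' @param entries character vector of terms (normalized internally).
#' @param name provenance tag.
#' @return a `term_dictionary`.
#' @export
term_dictionary <- function(entries, name = "custom") {
  entries <- sort(unique(normalize_term(entries)))
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L) stop("empty dictionary")
  new_term_dictionary(entries, name)
}

new_term_dictionary <- function(entries, name) {
  structure(list(entries = entries, name = name), class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>", x$name, "-", length(x$entries), "entries\n")
  invisible(x)
}

#' Load a synonym/stem recoding table
#'
#' Two-column TSV mapping a source term to its canonical term (e.g.
#' "autoimmune hepatitis" -> "hepatitis", "aminotransferases" ->
#' "aminotransferase"). Rules are normalized, chains are resolved
#' (a->b, b->c becomes a->c, b->c) so the resulting map is idempotent,
#' self-maps are dropped, and cycles are an error.
#'
#' @param path 2-column TSV; a header row `source<TAB>target` is skipped.
#' @return a `recoding_map`: named character vector (names = source terms).
#' @export
load_recoding <- function(path) {
  if (!file.exists(path)) stop("cannot read recoding file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("source", "target"),
                           colClasses = "character")
  if (nrow(tab) > 0L &&
      identical(tolower(trimws(unlist(tab[1L, ]))), c("source", "target")))
    tab <- tab[-1L, , drop = FALSE]
  recoding_map(stats::setNames(tab$target, tab$source))
}

#' Construct a recoding map from a named character vector
#'
#' @param rules named character vector, `names(rules)` are source terms and
#'   values are their canonical targets.
#' @return a `recoding_map` (idempotent: chains resolved, self-maps dropped).
#' @export
recoding_map <- function(rules) {
  if (length(rules) == 0L)
    return(structure(stats::setNames(character(0), character(0)),
                     class = "recoding_map"))
  src <- normalize_term(names(rules))
  dst <- normalize_term(unname(rules))
  keep <- nzchar(src) & nzchar(dst)
  src <- src[keep]; dst <- dst[keep]
  if (anyDuplicated(src))
    stop("duplicate source terms in recoding: ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  # resolve chains a->b->c to a->c; detect cycles
  map <- stats::setNames(dst, src)
  for (s in src) {
    cur <- s
    seen <- character(0)
    while (cur %in% names(map)) {
      if (cur %in% seen)
        stop("recoding cycle detected: ",
             paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- unname(map[[cur]])
    }
    map[[s]] <- cur
  }
  map <- map[map != names(map)]
  structure(map, class = "recoding_map")
}

#' @export
print.recoding_map <- function(x, ...) {
  cat("<recoding_map>", length(x), "rules\n")
  invisible(x)
}

# canonical vocabulary implied by a dictionary + recoding map
canonical_vocabulary <- function(dict, recoding = NULL) {
  v <- dict$entries
  if (!is.null(recoding) && length(recoding))
    v <- union(v, unname(unclass(recoding)))
  sort(v)
}

# match automaton: hashed environment of phrase -> canonical term, plus the
# distinct phrase token-lengths in decreasing order (for longest-match-first)
build_matcher <- function(dict, recoding = NULL) {
  phrases <- dict$entries
  canon <- phrases
  if (!is.null(recoding) && length(recoding)) {
    src <- names(recoding)
    dst <- unname(unclass(recoding))
    # dictionary entries that are themselves recoded map to their target
    hit <- match(phrases, src)
    canon[!is.na(hit)] <- dst[hit[!is.na(hit)]]
    # recoding sources absent from the dictionary are still matchable
    extra <- !(src %in% phrases)
    phrases <- c(phrases, src[extra])
    canon <- c(canon, dst[extra])
  }
  env <- new.env(parent = emptyenv(), size = length(phrases))
  for (i in seq_along(phrases)) assign(phrases[i], canon[i], envir = env)
  lens <- sort(unique(lengths(strsplit(phrases, " ", fixed = TRUE))),
               decreasing = TRUE)
  list(env = env, lens = lens)
}

#' Extract controlled-vocabulary term counts from a document
#'
#' Scans the token stream left to right with non-overlapping,
#' longest-match-first phrase matching against the dictionary entries plus
#' the recoding-map source phrases; every match is canonicalized through the
#' recoding map and counted, and every non-matching token (the universal
#' stop words) is discarded.
#'
#' @param text raw document text (a character scalar).
#' @param dict a [term_dictionary()].
#' @param recoding a [recoding_map()] or `NULL`.
#' @param matcher optional prebuilt matcher (internal; reuse across a corpus).
#' @return named integer vector of counts over canonical terms (possibly
#'   empty).
#' @export
extract_terms <- function(text, dict, recoding = NULL, matcher = NULL) {
  if (is.null(matcher)) matcher <- build_matcher(dict, recoding)
  toks <- normalize_text(text)
  n <- length(toks)
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- new.env(parent = emptyenv())
  i <- 1L
  lens <- matcher$lens
  env <- matcher$env
  while (i <= n) {
    matched <- FALSE
    for (L in lens) {
      if (i + L - 1L > n) next
      phrase <- paste(toks[i:(i + L - 1L)], collapse = " ")
      canon <- get0(phrase, envir = env, inherits = FALSE)
      if (!is.null(canon)) {
        prev <- get0(canon, envir = counts, inherits = FALSE)
        assign(canon, if (is.null(prev)) 1L else prev + 1L, envir = counts)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  terms <- sort(ls(counts))
  stats::setNames(vapply(terms, get, integer(1), envir = counts,
                         USE.NAMES = FALSE), terms)
}

#' Extract term counts for every document in a corpus
#'
#' @param corpus data.frame with columns `doc_id` and `text` (see
#'   [read_corpus()]).
#' @param dict a [term_dictionary()].
#' @param recoding a [recoding_map()] or `NULL`.
#' @return named list of per-document count vectors, in corpus order.
#' @export
extract_corpus <- function(corpus, dict, recoding = NULL) {
  stopifnot(is.data.frame(corpus), all(c("doc_id", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$doc_id))
    stop("duplicate doc_id in corpus")
  matcher <- build_matcher(dict, recoding)
  out <- lapply(corpus$text, extract_terms, dict = dict, recoding = recoding,
                matcher = matcher)
  names(out) <- corpus$doc_id
  out
}

#' Read a document corpus from delimited text
#'
#' Expects columns `doc_id`, `text`, and optionally `label` (binary 0/1 DILI
#' indicator) and `source`. The delimiter is inferred from the file
#' extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path CSV/TSV file, UTF-8.
#' @return data.frame with columns doc_id, text, label (may be NA), source.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", encoding = "UTF-8")
  if (!all(c("doc_id", "text") %in% names(tab)))
    stop("corpus must have columns doc_id and text")
  tab$doc_id <- as.character(tab$doc_id)
  if (anyDuplicated(tab$doc_id)) stop("duplicate doc_id in corpus")
  if (!"label" %in% names(tab)) tab$label <- NA_integer_
  if (!all(is.na(tab$label) | tab$label %in% c(0L, 1L)))
    stop("label must be 0/1 when present")
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  tab[, c("doc_id", "text", "label", "source")]
}

#' Write a document corpus as CSV
#'
#' @param corpus data.frame as returned by [read_corpus()] or
#'   [simulate_corpus()].
#' @param path output CSV path.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Positive-class percentage of a labeled corpus
#'
#' @param labels binary 0/1 vector.
#' @return percentage of documents labeled 1, on the 0-100 scale.
#' @export
class_balance <- function(labels) {
  labels <- labels[!is.na(labels)]
  stopifnot(length(labels) > 0L, all(labels %in% c(0, 1)))
  100 * mean(labels == 1)
}
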