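#' Gradient-boosting configuration
#'
#' Defaults and tuning ranges follow the published add-in defaults:
#' max_depth 3 (1-7), subsample 1 (0.5-1), colsample_bytree 1 (0.5-1),
#' min_child_weight 1 (1-3), alpha 0 (0-0.5), lambda 1 (0-2),
#' learning_rate 0.1 (0.05-0.2), iterations 30 (20-50). Objective is binary
#' logistic.
#'
#' @param max_depth maximum tree depth.
#' @param subsample row-sampling fraction per tree (without replacement).
#' @param colsample_bytree feature-sampling fraction per tree.
#' @param min_child_weight minimum hessian sum in a child.
#' @param alpha L1 regularization on leaf weights.
#' @param lambda L2 regularization on leaf weights.
#' @param learning_rate shrinkage applied to each tree's leaf weights.
#' @param iterations number of boosting rounds.
#' @param seed integer RNG seed for row/column subsampling.
#' @return a `booster_config` list.
#' @export
booster_config <- function(max_depth = 3L, subsample = 1, colsample_bytree = 1,
                           min_child_weight = 1, alpha = 0, lambda = 1,
                           learning_rate = 0.1, iterations = 30L, seed = 1L) {
  cfg <- list(max_depth = as.integer(max_depth), subsample = subsample,
              colsample_bytree = colsample_bytree,
              min_child_weight = min_child_weight, alpha = alpha,
              lambda = lambda, learning_rate = learning_rate,
              iterations = as.integer(iterations),
              objective = "binary:logistic", seed = as.integer(seed))
  with(cfg, {
    stopifnot(max_depth >= 1L, iterations >= 1L,
              subsample > 0, subsample <= 1,
              colsample_bytree > 0, colsample_bytree <= 1,
              min_child_weight >= 0, alpha >= 0, lambda >= 0,
              learning_rate > 0)
  })
  structure(cfg, class = "booster_config")
}

#' Default hyperparameter tuning ranges
#'
#' @return named list of `c(lo, hi)` ranges for [autotune()].
#' @export
default_tuning_ranges <- function() {
  list(max_depth = c(1, 7), subsample = c(0.5, 1),
       colsample_bytree = c(0.5, 1), min_child_weight = c(1, 3),
       alpha = c(0, 0.5), lambda = c(0, 2), learning_rate = c(0.05, 0.2),
       iterations = c(20, 50))
}

# resolve a dili_dtm or plain matrix into a dense feature matrix + term names
as_feature_matrix <- function(x) {
  if (inherits(x, "dili_dtm")) {
    list(X = as.matrix(x$weights), terms = x$terms)
  } else {
    X <- as.matrix(x)
    list(X = X, terms = colnames(X))
  }
}

check_labels <- function(labels, n) {
  labels <- as.numeric(labels)
  if (length(labels) != n) stop("labels length does not match documents")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) stop("degenerate labels: only one class")
  labels
}

#' Train the gradient-boosted tree classifier
#'
#' Fits a binary-logistic boosted tree ensemble on a TF-IDF document-term
#' matrix with exactly `config$iterations` rounds. Deterministic for fixed
#' seed and inputs. The trained model freezes the training corpus size and
#' per-term document frequencies so saved models score new documents with
#' the training IDF (see [predict_new()]).
#'
#' @param dtm a `dili_dtm` (or plain numeric matrix with column names).
#' @param labels binary 0/1 response, one per document/row.
#' @param config a [booster_config()].
#' @param threshold classification cutoff stored with the model.
#' @return a `dili_booster` model.
#' @export
train_booster <- function(dtm, labels, config = booster_config(),
                          threshold = 0.5) {
  fm <- as_feature_matrix(dtm)
  y <- check_labels(labels, nrow(fm$X))
  params <- c(unclass(config)[c("max_depth", "subsample", "colsample_bytree",
                                "min_child_weight", "alpha", "lambda",
                                "learning_rate", "iterations")],
              list(seed = config$seed, base_margin = 0, bootstrap = FALSE))
  fit <- .gbt_train(fm$X, y, params)
  idf <- if (inherits(dtm, "dili_dtm"))
    list(n_docs = dtm$n_docs, doc_freq = dtm$doc_freq) else NULL
  structure(list(trees = fit$trees,
                 vocabulary = fm$terms,
                 config = config,
                 threshold = threshold,
                 base_margin = 0,
                 importance_raw = list(splits = fit$importance_splits,
                                       gain = fit$importance_gain,
                                       cover = fit$importance_cover),
                 idf = idf,
                 n_train = nrow(fm$X)),
            class = "dili_booster")
}

#' @export
print.dili_booster <- function(x, ...) {
  cat("<dili_booster>", length(x$trees), "trees over",
      length(x$vocabulary), "terms; threshold", x$threshold, "\n")
  invisible(x)
}

#' Predict with a trained booster
#'
#' @param object a `dili_booster`.
#' @param newdata a `dili_dtm` or numeric matrix whose columns match the
#'   model vocabulary (aligned by name when column names are present).
#' @param type "prob" (default), "margin", or "class" (round-up at the
#'   model threshold: probability >= threshold is class 1).
#' @param iterations use only the first so many trees (default: all).
#' @param per_iteration return an n x iterations matrix of cumulative
#'   predictions instead of a vector.
#' @param ... unused.
#' @return numeric vector (or matrix when `per_iteration`).
#' @export
predict.dili_booster <- function(object, newdata, type = c("prob", "margin",
                                                           "class"),
                                 iterations = NULL, per_iteration = FALSE,
                                 ...) {
  type <- match.arg(type)
  fm <- as_feature_matrix(newdata)
  X <- fm$X
  if (!is.null(fm$terms) && !identical(fm$terms, object$vocabulary)) {
    if (!all(object$vocabulary %in% fm$terms))
      stop("newdata lacks model vocabulary columns; use align_vocabulary()")
    X <- X[, object$vocabulary, drop = FALSE]
  }
  if (ncol(X) != length(object$vocabulary))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$vocabulary))
  trees <- object$trees
  if (!is.null(iterations)) {
    stopifnot(iterations >= 1L, iterations <= length(trees))
    trees <- trees[seq_len(iterations)]
  }
  marg <- .gbt_margins(trees, X, object$base_margin)
  out <- if (per_iteration) marg else marg[, ncol(marg)]
  switch(type,
         margin = out,
         prob = 1 / (1 + exp(-out)),
         class = as.integer(1 / (1 + exp(-out)) >= object$threshold))
}

binary_logloss <- function(p, y) {
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated iteration history
#'
#' For every (set, fold) pair of the plan, trains on the remaining folds and
#' records per-iteration training and held-out log-loss, mirroring the
#' iteration-history curves used to pick the boosting round count.
#'
#' @param dtm a `dili_dtm` or matrix.
#' @param labels binary response.
#' @param config a [booster_config()]; `config$iterations` caps the probe
#'   unless `max_iterations` is larger.
#' @param fold_plan a [make_fold_plan()] plan.
#' @param max_iterations number of rounds to probe (default
#'   `config$iterations`).
#' @return an `iteration_history`: matrices `train` and `valid` (iterations x
#'   folds) of log-loss, their mean curves, and `best_iteration`.
#' @export
iteration_history <- function(dtm, labels, config = booster_config(),
                              fold_plan, max_iterations = config$iterations) {
  fm <- as_feature_matrix(dtm)
  y <- check_labels(labels, nrow(fm$X))
  cfg <- config
  cfg$iterations <- as.integer(max_iterations)
  n_folds <- fold_plan$k * fold_plan$R
  tr_loss <- matrix(NA_real_, max_iterations, n_folds)
  va_loss <- matrix(NA_real_, max_iterations, n_folds)
  col <- 0L
  for (r in seq_len(fold_plan$R)) {
    for (f in seq_len(fold_plan$k)) {
      col <- col + 1L
      hold <- fold_plan$assignment[, r] == f
      fit <- train_booster(fm$X[!hold, , drop = FALSE], y[!hold], cfg)
      ptr <- predict(fit, fm$X[!hold, , drop = FALSE], per_iteration = TRUE)
      pva <- predict(fit, fm$X[hold, , drop = FALSE], per_iteration = TRUE)
      for (it in seq_len(max_iterations)) {
        tr_loss[it, col] <- binary_logloss(ptr[, it], y[!hold])
        va_loss[it, col] <- binary_logloss(pva[, it], y[hold])
      }
    }
  }
  mean_valid <- rowMeans(va_loss)
  structure(list(train = tr_loss, valid = va_loss,
                 mean_train = rowMeans(tr_loss), mean_valid = mean_valid,
                 best_iteration = which.min(mean_valid)),
            class = "iteration_history")
}

#' Pick the boosting round count from an iteration history
#'
#' Returns the iteration minimizing mean held-out log-loss; ties go to the
#' smallest iteration.
#'
#' @param history an `iteration_history`, or a numeric vector of mean
#'   validation losses.
#' @return 1-based iteration index.
#' @export
select_iterations <- function(history) {
  losses <- if (inherits(history, "iteration_history")) history$mean_valid
            else as.numeric(history)
  if (length(losses) == 0L) stop("empty iteration history")
  which.min(losses)
}

#' Latin-hypercube hyperparameter autotuning
#'
#' Samples `n_design_points` configurations by a seeded Latin-hypercube
#' design over the tuning ranges, scores each by `inner_folds`-fold
#' stratified CV mean validation log-loss, and returns the best
#' configuration (score table attached as attribute `"scores"`).
#'
#' @param dtm a `dili_dtm` or matrix.
#' @param labels binary response.
#' @param ranges named list of `c(lo, hi)` (see [default_tuning_ranges()]).
#' @param n_design_points number of candidate settings (default 10).
#' @param inner_folds folds for the inner CV (default 2).
#' @param seed RNG seed.
#' @return the winning [booster_config()].
#' @export
autotune <- function(dtm, labels, ranges = default_tuning_ranges(),
                     n_design_points = 10L, inner_folds = 2L, seed = 1L) {
  if (n_design_points < 1L) stop("n_design_points must be >= 1")
  bad <- vapply(ranges, function(r) r[2] < r[1], logical(1))
  if (any(bad)) stop("invalid range (hi < lo): ",
                     paste(names(ranges)[bad], collapse = ", "))
  fm <- as_feature_matrix(dtm)
  y <- check_labels(labels, nrow(fm$X))
  design <- lhs_design(ranges, n_design_points, seed)
  plan <- make_fold_plan(y, k = inner_folds, R = 1L, seed = seed + 7L)
  scores <- numeric(n_design_points)
  configs <- vector("list", n_design_points)
  for (i in seq_len(n_design_points)) {
    cfg <- do.call(booster_config, c(design[i, , drop = FALSE],
                                     list(seed = seed + i)))
    configs[[i]] <- cfg
    loss <- 0
    for (f in seq_len(inner_folds)) {
      hold <- plan$assignment[, 1L] == f
      fit <- train_booster(fm$X[!hold, , drop = FALSE], y[!hold], cfg)
      loss <- loss + binary_logloss(predict(fit, fm$X[hold, , drop = FALSE]),
                                    y[hold])
    }
    scores[i] <- loss / inner_folds
  }
  best <- which.min(scores)
  out <- configs[[best]]
  attr(out, "scores") <- data.frame(design, valid_logloss = scores,
                                    row.names = NULL)
  attr(out, "candidates") <- configs
  out
}

# seeded Latin-hypercube sample over named ranges; integer parameters rounded
lhs_design <- function(ranges, n, seed) {
  integer_params <- c("max_depth", "iterations")
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  cols <- lapply(names(ranges), function(nm) {
    lo <- ranges[[nm]][1]; hi <- ranges[[nm]][2]
    u <- (sample.int(n) - stats::runif(n)) / n
    v <- lo + u * (hi - lo)
    if (nm %in% integer_params) round(v) else v
  })
  names(cols) <- names(ranges)
  as.data.frame(cols)
}

# save/seed/restore helpers (deterministic without clobbering the caller's RNG)
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Term importance: splits, gain, cover
#'
#' @param model a fitted `dili_booster`.
#' @param ... unused.
#' @return data.frame with one row per term actually used for splitting:
#'   `term`, `splits` (times used), `gain` (average objective improvement
#'   per split), `total_gain`, `cover` (average hessian-weighted data
#'   covered), `total_cover`, and `gain_rank` (1 = most important, ranked by
#'   average gain, ties broken by term name). Terms never used are absent;
#'   an ensemble with no splits yields an empty table.
#' @export
importance <- function(model, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.dili_booster <- function(model, ...) {
  splits <- model$importance_raw$splits
  used <- which(splits > 0L)
  if (length(used) == 0L)
    return(data.frame(term = character(0), splits = integer(0),
                      gain = numeric(0), total_gain = numeric(0),
                      cover = numeric(0), total_cover = numeric(0),
                      gain_rank = integer(0)))
  tab <- data.frame(term = model$vocabulary[used],
                    splits = splits[used],
                    total_gain = model$importance_raw$gain[used],
                    total_cover = model$importance_raw$cover[used],
                    stringsAsFactors = FALSE)
  tab$gain <- tab$total_gain / tab$splits
  tab$cover <- tab$total_cover / tab$splits
  ord <- order(-tab$gain, tab$term, method = "radix")
  tab <- tab[ord, c("term", "splits", "gain", "total_gain", "cover",
                    "total_cover")]
  tab$gain_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Compare term importance with raw corpus counts
#'
#' Contrasts each term's total corpus occurrence count with its boosting
#' gain and gain rank, flags supplied keywords, and reports the Spearman
#' rank correlation between count and gain (importance is typically *not*
#' driven by count).
#'
#' @param imp an [importance()] table.
#' @param m the counts matrix the model's DTM was built from.
#' @param keywords optional character vector of terms to flag (e.g. the
#'   expert DILI keywords).
#' @return data.frame `term, count, gain, gain_rank, keyword`, sorted by
#'   gain rank, with attribute `"rank_correlation"` (NA with a message when
#'   fewer than 2 terms).
#' @export
gain_vs_count <- function(imp, m, keywords = character(0)) {
  if (!all(imp$term %in% colnames(m)))
    stop("importance terms missing from the count matrix")
  counts <- Matrix::colSums(m)[imp$term]
  out <- data.frame(term = imp$term, count = as.numeric(counts),
                    gain = imp$gain, gain_rank = imp$gain_rank,
                    keyword = imp$term %in% keywords,
                    stringsAsFactors = FALSE)
  rho <- if (nrow(out) >= 2L)
    stats::cor(out$count, out$gain, method = "spearman") else NA_real_
  if (is.na(rho) && nrow(out) < 2L)
    message("rank correlation undefined with fewer than 2 terms")
  attr(out, "rank_correlation") <- rho
  out
}
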