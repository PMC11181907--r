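# Screening learner families. Each fit_* returns a closure scoring new rows
# (higher = more positive); screen_models only needs AUC, so monotone scores
# are enough. All learners are deterministic given their seed.

fit_family <- function(family, X, y, knob, seed) {
  switch(family,
    xgboost = {
      cfg <- booster_config(iterations = knob, seed = seed)
      fit <- train_booster(X, y, cfg)
      function(newX) predict(fit, newX)
    },
    random_forest = {
      # bagged unshrunken trees: bootstrap rows + feature subsample per tree
      p <- ncol(X)
      cfg <- list(max_depth = as.integer(knob), subsample = 1,
                  colsample_bytree = max(1 / p, floor(sqrt(p)) / p),
                  min_child_weight = 1, alpha = 0, lambda = 1e-6,
                  learning_rate = 1, iterations = 60L, seed = seed,
                  base_margin = 0, bootstrap = TRUE)
      # average single-tree scores rather than boosting: refit each tree to
      # the constant-margin gradients by keeping the margin at 0 per tree
      trees <- lapply(seq_len(cfg$iterations), function(b) {
        one <- cfg
        one$iterations <- 1L
        one$seed <- seed + 17L * b
        .gbt_train(X, y, one)$trees[[1L]]
      })
      function(newX) {
        s <- rowMeans(vapply(trees, function(tr)
          .gbt_margins(list(tr), newX, 0)[, 1L], numeric(nrow(newX))))
        1 / (1 + exp(-s))
      }
    },
    decision_tree = {
      one <- list(max_depth = as.integer(knob), subsample = 1,
                  colsample_bytree = 1, min_child_weight = 1, alpha = 0,
                  lambda = 1e-6, learning_rate = 1, iterations = 1L,
                  seed = seed, base_margin = 0, bootstrap = FALSE)
      tr <- .gbt_train(X, y, one)$trees[[1L]]
      function(newX) 1 / (1 + exp(-.gbt_margins(list(tr), newX, 0)[, 1L]))
    },
    neural_net = fit_mlp(X, y, decay = knob, hidden = 8L, seed = seed),
    svm_linear = fit_linear_svm(X, y, cost = knob, seed = seed),
    stop("unknown learner family: ", family)
  )
}

# per-family inner-CV grids (one knob each)
family_grids <- list(
  xgboost = c(20L, 30L, 50L),          # iterations
  random_forest = c(4L, 8L),           # tree depth
  decision_tree = c(2L, 3L, 5L),       # tree depth
  neural_net = c(0.01, 0.1),           # weight decay
  svm_linear = c(0.1, 1)               # cost (inverse regularization)
)

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(scale = function(M) sweep(sweep(M, 2, mu), 2, sdv, "/"))
}

# single-hidden-layer logistic MLP, tanh units, L2 decay, BFGS
fit_mlp <- function(X, y, decay, hidden = 8L, seed = 1L, maxit = 200L) {
  st <- standardize_cols(X)
  Xs <- st$scale(X)
  p <- ncol(Xs)
  n_w <- hidden * (p + 1L) + hidden + 1L
  old <- withr_seed(seed)
  w0 <- stats::runif(n_w, -0.5, 0.5)
  restore_seed(old)
  unpack <- function(w) {
    W1 <- matrix(w[seq_len(hidden * p)], p, hidden)
    b1 <- w[hidden * p + seq_len(hidden)]
    W2 <- w[hidden * p + hidden + seq_len(hidden)]
    b2 <- w[n_w]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(M, pr) {
    H <- tanh(sweep(M %*% pr$W1, 2, pr$b1, "+"))
    drop(H %*% pr$W2) + pr$b2
  }
  n <- length(y)
  obj <- function(w) {
    pr <- unpack(w)
    z <- fwd(Xs, pr)
    pp <- 1 / (1 + exp(-z))
    binary_logloss(pp, y) + decay * sum(w^2) / n
  }
  grad <- function(w) {
    pr <- unpack(w)
    A <- sweep(Xs %*% pr$W1, 2, pr$b1, "+")
    H <- tanh(A)
    z <- drop(H %*% pr$W2) + pr$b2
    pp <- 1 / (1 + exp(-z))
    dz <- (pp - y) / n
    dW2 <- drop(crossprod(H, dz))
    db2 <- sum(dz)
    dH <- outer(dz, pr$W2) * (1 - H^2)
    dW1 <- crossprod(Xs, dH)
    db1 <- colSums(dH)
    c(as.vector(dW1), db1, dW2, db2) + 2 * decay * w / n
  }
  fit <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  pr <- unpack(fit$par)
  function(newX) 1 / (1 + exp(-fwd(st$scale(newX), pr)))
}

# linear SVM via L2-regularized squared hinge loss
fit_linear_svm <- function(X, y, cost = 1, seed = 1L, maxit = 300L) {
  st <- standardize_cols(X)
  Xs <- st$scale(X)
  yy <- ifelse(y == 1, 1, -1)
  p <- ncol(Xs)
  obj <- function(w) {
    z <- drop(Xs %*% w[seq_len(p)]) + w[p + 1L]
    slack <- pmax(0, 1 - yy * z)
    sum(w[seq_len(p)]^2) / 2 + cost * sum(slack^2)
  }
  grad <- function(w) {
    z <- drop(Xs %*% w[seq_len(p)]) + w[p + 1L]
    slack <- pmax(0, 1 - yy * z)
    coef <- -2 * cost * slack * yy
    c(w[seq_len(p)] + drop(crossprod(Xs, coef)), sum(coef))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  w <- fit$par
  function(newX) drop(st$scale(newX) %*% w[seq_len(p)]) + w[p + 1L]
}

#' Multi-learner screening under nested cross-validation
#'
#' Compares learner families under a shared nested CV plan: the outer `k`
#' folds estimate validation AUC; within each outer training set an inner
#' `L`-fold CV picks one small per-family tuning knob (boosting iterations,
#' tree depth, weight decay, or SVM cost). Families: gradient-boosted trees
#' (`"xgboost"`), a bagged-tree forest (`"random_forest"`), a single
#' decision tree (`"decision_tree"`), a small single-hidden-layer neural
#' network (`"neural_net"`), and a linear support-vector classifier
#' (`"svm_linear"`).
#'
#' @param dtm a `dili_dtm` or numeric matrix.
#' @param labels binary response.
#' @param k outer folds (default 10).
#' @param L inner folds (default 5).
#' @param seed integer seed (shared plan across families).
#' @param families subset of the five family names.
#' @return data.frame `family, auc` (mean outer-fold validation AUC),
#'   sorted by AUC descending.
#' @export
screen_models <- function(dtm, labels, k = 10L, L = 5L, seed = 1L,
                          families = names(family_grids)) {
  unknown <- setdiff(families, names(family_grids))
  if (length(unknown))
    stop("unknown learner family: ", paste(unknown, collapse = ", "))
  fm <- as_feature_matrix(dtm)
  y <- check_labels(labels, nrow(fm$X))
  outer <- make_fold_plan(y, k = k, R = 1L, seed = seed)
  auc <- stats::setNames(numeric(length(families)), families)
  for (family in families) {
    grid <- family_grids[[family]]
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      hold <- outer$assignment[, 1L] == f
      Xtr <- fm$X[!hold, , drop = FALSE]; ytr <- y[!hold]
      knob <- grid[1L]
      if (length(grid) > 1L) {
        inner <- make_fold_plan(ytr, k = L, R = 1L, seed = seed + 31L * f)
        inner_auc <- vapply(grid, function(g) {
          a <- numeric(L)
          for (j in seq_len(L)) {
            ih <- inner$assignment[, 1L] == j
            sc <- fit_family(family, Xtr[!ih, , drop = FALSE], ytr[!ih],
                             g, seed + f)(Xtr[ih, , drop = FALSE])
            a[j] <- roc_auc(sc, ytr[ih])
          }
          mean(a)
        }, numeric(1))
        knob <- grid[which.max(inner_auc)]
      }
      scorer <- fit_family(family, Xtr, ytr, knob, seed + f)
      fold_auc[f] <- roc_auc(scorer(fm$X[hold, , drop = FALSE]), y[hold])
    }
    auc[family] <- mean(fold_auc)
  }
  out <- data.frame(family = names(auc), auc = unname(auc),
                    stringsAsFactors = FALSE)
  out[order(-out$auc), , drop = FALSE]
}
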