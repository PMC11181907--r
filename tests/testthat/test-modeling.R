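test_that("train_booster fits strong signal, is deterministic and seedable", {
  w <- small_world()
  cfg <- booster_config(seed = 7)
  fit1 <- train_booster(w$dtm, w$labels, cfg)
  fit2 <- train_booster(w$dtm, w$labels, cfg)
  p1 <- predict(fit1, w$dtm)
  expect_identical(p1, predict(fit2, w$dtm))          # bit-identical
  expect_gt(roc_auc(p1, w$labels), 0.95)

  expect_error(train_booster(w$dtm, rep(1, nrow(w$dtm$weights)), cfg),
               "degenerate labels")
  expect_error(train_booster(w$dtm, w$labels[-1], cfg), "length")
})

test_that("constant-zero features predict the base rate for every document", {
  n <- 120
  y <- rep(c(1, 0), c(40, 80))
  X <- matrix(0, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- train_booster(X, y, booster_config(iterations = 60))
  p <- predict(fit, X)
  expect_equal(length(unique(p)), 1L)
  expect_equal(unname(p[1]), mean(y), tolerance = 0.01)
  expect_equal(nrow(importance(fit)), 0L)
})

test_that("predictions are invariant to per-feature positive rescaling", {
  w <- small_world()
  X <- as.matrix(w$dtm$weights)
  cfg <- booster_config(seed = 3)
  base <- predict(train_booster(X, w$labels, cfg), X)
  X2 <- X
  X2[, 5] <- X2[, 5] * 7
  scaled <- predict(train_booster(X2, w$labels, cfg), X2)
  expect_equal(unname(base), unname(scaled), tolerance = 1e-12)
})

test_that("training log-loss never increases with more iterations", {
  w <- small_world()
  fit <- train_booster(w$dtm, w$labels, booster_config(seed = 1))
  pm <- predict(fit, w$dtm, per_iteration = TRUE)
  losses <- apply(pm, 2, dilitext:::binary_logloss, y = w$labels)
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("iteration history has the probed length and exposes the argmin", {
  w <- small_world()
  plan <- make_fold_plan(w$labels, k = 3, R = 1, seed = 5)
  h <- iteration_history(w$dtm, w$labels, booster_config(seed = 1), plan,
                         max_iterations = 25)
  expect_equal(length(h$mean_valid), 25L)
  expect_equal(dim(h$valid), c(25L, 3L))
  expect_equal(h$best_iteration, which.min(h$mean_valid))
  # validation curve declines from its start to its minimum
  expect_lt(min(h$mean_valid), h$mean_valid[1])

  # pure-noise labels: held-out loss never materially below ln 2
  set.seed(8)
  ynull <- sample(w$labels)
  plan0 <- make_fold_plan(ynull, k = 3, R = 1, seed = 6)
  h0 <- iteration_history(w$dtm, ynull, booster_config(seed = 1), plan0,
                          max_iterations = 20)
  expect_gt(min(h0$mean_valid), log(2) - 0.05)
})

test_that("select_iterations is the earliest argmin", {
  expect_equal(select_iterations(c(0.6, 0.5, 0.5, 0.55)), 2L)
  expect_equal(select_iterations(c(0.9, 0.8, 0.7)), 3L)
  expect_error(select_iterations(numeric(0)), "empty")
  w <- small_world()
  plan <- make_fold_plan(w$labels, k = 3, R = 1, seed = 5)
  h <- iteration_history(w$dtm, w$labels, booster_config(seed = 2), plan,
                         max_iterations = 15)
  oracle <- which(h$mean_valid == min(h$mean_valid))[1]  # brute-force argmin
  expect_equal(select_iterations(h), oracle)
})

test_that("autotune returns the argmin candidate over its design points", {
  w <- small_world()
  X <- as.matrix(w$dtm$weights)[, 1:40]
  deg <- lapply(default_tuning_ranges(), function(r) c(r[1], r[1]))
  cfg <- autotune(X, w$labels, ranges = deg, n_design_points = 2, seed = 9)
  expect_equal(cfg$max_depth, 1L)
  expect_equal(cfg$iterations, 20L)
  expect_equal(cfg$lambda, 0)

  tuned <- autotune(X, w$labels, n_design_points = 3, inner_folds = 2,
                    seed = 11)
  sc <- attr(tuned, "scores")
  expect_equal(nrow(sc), 3L)
  best <- which.min(sc$valid_logloss)
  expect_equal(tuned$max_depth, as.integer(sc$max_depth[best]))
  expect_equal(tuned$iterations, as.integer(sc$iterations[best]))
  # sampled points respect the stated ranges
  rng <- default_tuning_ranges()
  for (nm in names(rng)) {
    expect_true(all(sc[[nm]] >= rng[[nm]][1] - 1e-9))
    expect_true(all(sc[[nm]] <= rng[[nm]][2] + 1e-9))
  }
  expect_error(autotune(X, w$labels, n_design_points = 0), "n_design_points")
})

test_that("autotuned model is not materially worse than the default", {
  w <- small_world()
  plan <- make_fold_plan(w$labels, k = 3, R = 1, seed = 21)
  hold <- plan$assignment[, 1] == 1
  X <- as.matrix(w$dtm$weights)
  tuned <- autotune(X[!hold, ], w$labels[!hold], n_design_points = 5,
                    seed = 13)
  auc_tuned <- roc_auc(predict(train_booster(X[!hold, ], w$labels[!hold],
                                             tuned), X[hold, ]),
                       w$labels[hold])
  auc_def <- roc_auc(predict(train_booster(X[!hold, ], w$labels[!hold],
                                           booster_config(seed = 13)),
                             X[hold, ]),
                     w$labels[hold])
  expect_gte(auc_tuned, auc_def - 0.02)
})

test_that("importance recovers planted terms and accounts consistently", {
  w <- small_world()
  fit <- train_booster(w$dtm, w$labels, booster_config(seed = 7))
  imp <- importance(fit)
  expect_true(all(imp$gain >= 0))
  expect_true(all(imp$splits >= 1))
  expect_equal(imp$gain_rank, seq_len(nrow(imp)))
  expect_gte(sum(w$toy$signal_terms %in% imp$term[1:20]), 7)
  # table totals agree with the booster's internal accounting
  expect_equal(sum(imp$total_gain), sum(fit$importance_raw$gain))
  expect_equal(sum(imp$splits), sum(fit$importance_raw$splits))

  # single informative feature gets rank 1
  sig <- w$toy$signal_terms[!grepl(" ", w$toy$signal_terms)][1]
  X1 <- as.matrix(w$dtm$weights)[, sig, drop = FALSE]
  imp1 <- importance(train_booster(X1, w$labels, booster_config(seed = 1)))
  expect_equal(imp1$term[imp1$gain_rank == 1], sig)
})

test_that("gain_vs_count separates importance from raw frequency", {
  # planted construction: a filler column with 5x the count of any signal
  # column but no label association must rank below every signal term
  set.seed(31)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  sig <- sapply(1:4, function(i) rpois(n, 0.3 + 0.9 * y))
  filler <- rpois(n, 5 * max(colSums(sig)) / n)
  X <- cbind(sig, filler)
  colnames(X) <- c(paste0("sig", 1:4), "filler")
  counts <- Matrix::Matrix(X, sparse = TRUE)
  fit <- train_booster(as.matrix(tfidf_weight(counts)$weights), y,
                       booster_config(seed = 2))
  imp <- importance(fit)
  tab <- gain_vs_count(imp, counts, keywords = paste0("sig", 1:4))
  expect_true(all(tab$keyword[tab$term != "filler"]))
  if ("filler" %in% tab$term) {
    filler_rank <- tab$gain_rank[tab$term == "filler"]
    expect_true(all(tab$gain_rank[tab$term != "filler"] < filler_rank))
  }
  expect_true(is.numeric(attr(tab, "rank_correlation")))

  one <- imp[1, ]
  expect_message(t1 <- gain_vs_count(one, counts), "undefined")
  expect_true(is.na(attr(t1, "rank_correlation")))
})
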