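test_that("fold plans stratify exactly and reproduce by seed", {
  y <- rep(c(1, 0), c(35, 65))
  plan <- make_fold_plan(y, k = 5, R = 10, seed = 4)
  for (r in 1:10) {
    f <- plan$assignment[, r]
    expect_setequal(unique(f), 1:5)
    for (k in 1:5) {
      expect_equal(sum(f == k & y == 1), 7)   # exact stratification
      expect_equal(sum(f == k & y == 0), 13)
    }
  }
  expect_identical(make_fold_plan(y, k = 5, R = 10, seed = 4)$assignment,
                   plan$assignment)
  expect_false(identical(make_fold_plan(y, k = 5, R = 10, seed = 5)$assignment,
                         plan$assignment))
  expect_true(plan$max_jaccard < 1)
  expect_error(make_fold_plan(rep(c(1, 0), c(3, 60)), k = 5), "fewer than")
})

test_that("uneven strata stay within one document of balance", {
  set.seed(2)
  y <- rbinom(103, 1, 0.42)
  plan <- make_fold_plan(y, k = 5, R = 3, seed = 9)
  for (r in 1:3) for (cl in 0:1) {
    sizes <- table(factor(plan$assignment[y == cl, r], levels = 1:5))
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("confusion honors the round-up rule and matches brute force", {
  c1 <- confusion(c(0.9, 0.2), c(1, 0))
  expect_equal(c1, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(confusion(0.5, 0)$FP, 1L)     # tie goes to class 1
  expect_error(confusion(c(0.1, 0.2), 1), "mismatch")

  set.seed(12)
  s <- runif(200); y <- rbinom(200, 1, 0.5)
  for (t in c(0.25, 0.5, 0.75)) {
    cc <- confusion(s, y, t)
    tp <- fp <- tn <- fn <- 0L                 # brute-force loop oracle
    for (i in 1:200) {
      pred <- if (s[i] >= t) 1L else 0L
      if (pred == 1L && y[i] == 1) tp <- tp + 1L
      if (pred == 1L && y[i] == 0) fp <- fp + 1L
      if (pred == 0L && y[i] == 0) tn <- tn + 1L
      if (pred == 0L && y[i] == 1) fn <- fn + 1L
    }
    expect_equal(cc, list(TP = tp, FP = fp, TN = tn, FN = fn))
  }
})

test_that("metrics_from_confusion handles perfect, chance and undefined", {
  perfect <- metrics_from_confusion(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(perfect), c(ACC = 1, MCC = 1, sensitivity = 1,
                                  specificity = 1, precision = 1))
  chance <- metrics_from_confusion(list(TP = 5, FP = 5, TN = 5, FN = 5))
  expect_equal(chance$ACC, 0.5)
  expect_equal(chance$MCC, 0)
  # zero denominators are undefined, never silently zero
  none_pos <- metrics_from_confusion(list(TP = 0, FP = 0, TN = 9, FN = 0))
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$precision))
  expect_true(is.na(none_pos$MCC))
  expect_error(metrics_from_confusion(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("roc_auc hits the analytic endpoints and the pair oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(21)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)  # force ties
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), auc_pairs_oracle(s, y), tolerance = 1e-12)
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(plogis(5 * s - 1), y), roc_auc(s, y),
                 tolerance = 1e-12)
  }

  out <- roc_auc(c(0.9, 0.1, 0.5), c(1, 0, 1), curve = TRUE)
  expect_equal(out$roc$sensitivity[1], 0)
  expect_equal(out$roc$specificity[1], 1)
})

test_that("rmse matches the direct formula", {
  expect_equal(rmse(c(1, 0), c(1, 0)), 0)
  expect_equal(rmse(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.5)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  set.seed(3)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(rmse(s, y), sqrt(mean((s - y)^2)), tolerance = 1e-14)
})

test_that("profit analysis is monotone in the threshold", {
  set.seed(5)
  s <- runif(300); y <- rbinom(300, 1, 0.35)
  tab <- profit_analysis(s, y)
  expect_equal(tab$threshold, c(0.25, 0.5, 0.75))
  expect_true(all(diff(tab$fn) >= 0))
  expect_true(all(diff(tab$fp) <= 0))
  expect_true(all(diff(tab$predicted_positive) <= 0))
  expect_equal(profit_analysis(s, y, 0)$fn, 0)
  expect_error(profit_analysis(s, y, c(0.5, 1.2)), "0, 1")
  # equals repeated confusion calls
  for (t in c(0.1, 0.3, 0.6, 0.8, 0.95)) {
    cc <- confusion(s, y, t)
    row <- profit_analysis(s, y, t)
    expect_equal(row$fn, cc$FN)
    expect_equal(row$fp, cc$FP)
    expect_equal(row$predicted_positive, cc$TP + cc$FP)
  }
})

test_that("consistency report bins deciles and matches the confusion rate", {
  rep1 <- consistency_report(c(0.95, 0.05), c(1, 0))
  expect_equal(rep1$overall, 1)
  expect_equal(rep1$bins$consistency[c(1, 10)], c(1, 1))
  rep2 <- consistency_report(0.55, 0)
  expect_equal(rep2$overall, 0)
  expect_equal(rep2$bins$n[6], 1)          # 0.55 lands in [0.5, 0.6)

  set.seed(6)
  s <- runif(400); y <- rbinom(400, 1, 0.4)
  rep3 <- consistency_report(s, y)
  cc <- confusion(s, y, 0.5)
  expect_equal(rep3$overall, 1 - (cc$FN + cc$FP) / 400)
  expect_equal(sum(rep3$bins$n), 400)
  # overall equals the count-weighted mean of bin consistencies
  b <- rep3$bins[rep3$bins$n > 0, ]
  expect_equal(rep3$overall, sum(b$consistency * b$n) / sum(b$n))

  # calibrated scores: extreme deciles are at least as consistent as middle
  set.seed(7)
  p <- runif(4000)
  yy <- rbinom(4000, 1, p)
  rc <- consistency_report(p, yy)$bins$consistency
  expect_gte(min(rc[c(1, 10)]), max(rc[5:6]))
})

test_that("cross_validate separates signal, overfits in the right direction", {
  sep <- generator_spec(n_docs = 150, vocabulary_size = 60,
                        n_signal_terms = 8, rate_ratio = 30,
                        mean_doc_length = 80, n_phrases = 10, seed = 77)
  toy <- make_toy_dictionary(sep)
  corpus <- simulate_corpus(sep, toy)
  built <- corpus_to_dtm(corpus, toy$dict, toy$recoding)
  plan <- make_fold_plan(corpus$label, k = 5, R = 2, seed = 1)
  cv <- cross_validate(built$dtm, corpus$label, booster_config(seed = 1),
                       plan)
  val <- cv$report$validation
  expect_gte(val$mean[val$metric == "AUC"], 0.99)
  # out-of-fold scores cover every document in every set
  expect_false(anyNA(cv$scores))

  # training metrics at least match validation on average
  tr <- cv$report$training
  expect_gte(tr$mean[tr$metric == "AUC"], val$mean[val$metric == "AUC"])
  expect_gte(val$mean[val$metric == "ACC"], 0.8)
})

test_that("training beats validation in expectation across seeds", {
  diffs <- vapply(1:10, function(s) {
    spec <- generator_spec(n_docs = 80, vocabulary_size = 30,
                           n_signal_terms = 4, rate_ratio = 2.5,
                           mean_doc_length = 40, n_phrases = 5, seed = s)
    toy <- make_toy_dictionary(spec)
    corpus <- simulate_corpus(spec, toy)
    built <- corpus_to_dtm(corpus, toy$dict, toy$recoding)
    plan <- make_fold_plan(corpus$label, k = 3, R = 1, seed = s)
    cv <- cross_validate(built$dtm, corpus$label,
                         booster_config(iterations = 15, seed = s), plan)
    cv$report$training$mean[1] - cv$report$validation$mean[1]   # ACC gap
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("screen_models ranks families sensibly and is deterministic", {
  w <- small_world()
  sig <- intersect(w$toy$signal_terms, w$dtm$terms)
  keep <- c(sig, setdiff(w$dtm$terms, sig)[seq_len(60 - length(sig))])
  X <- as.matrix(w$dtm$weights)[, keep]
  y <- w$labels
  tab <- screen_models(X, y, k = 5, L = 3, seed = 10)
  expect_setequal(tab$family, c("xgboost", "random_forest", "decision_tree",
                                "neural_net", "svm_linear"))
  expect_true(all(tab$auc > 0.8))
  expect_gte(tab$auc[tab$family == "xgboost"],
             tab$auc[tab$family == "decision_tree"])
  expect_gte(tab$auc[tab$family == "random_forest"],
             tab$auc[tab$family == "decision_tree"])

  again <- screen_models(X, y, k = 5, L = 3, seed = 10)
  expect_identical(tab, again)
  expect_error(screen_models(X, y, families = "bert"), "unknown")
})

test_that("screen_models is null-calibrated under permuted labels", {
  w <- small_world()
  X <- as.matrix(w$dtm$weights)[, 1:40]
  set.seed(14)
  ynull <- sample(w$labels)
  tab <- screen_models(X, ynull, k = 5, L = 2, seed = 10,
                       families = c("xgboost", "decision_tree",
                                    "svm_linear"))
  expect_true(all(tab$auc > 0.4 & tab$auc < 0.6))
})
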