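test_that("metric formulas evaluate correctly on worked confusion tables", {
  cc <- confusion_counts(c(rep("active", 50), rep("inactive", 50)),
                         c(rep("active", 45), rep("inactive", 5),
                           rep("active", 10), rep("inactive", 40)))
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 45L, fn = 5L, fp = 10L, tn = 40L))
  expect_equal(mcc(cc), (45 * 40 - 10 * 5) / sqrt(55 * 50 * 50 * 45),
               tolerance = 1e-12)
  expect_equal(f1(cc), 90 / 105, tolerance = 1e-12)
  expect_equal(balanced_accuracy(cc), 0.85, tolerance = 1e-12)
  pr <- precision_recall(list(tp = 8, fp = 2, fn = 2, tn = 0))
  expect_equal(unname(pr), c(0.8, 0.8))

  # perfect and chance-level extremes
  expect_equal(mcc(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1.0)
  expect_equal(mcc(list(tp = 25, tn = 25, fp = 25, fn = 25)), 0.0)
  expect_equal(f1(list(tp = 10, tn = 0, fp = 0, fn = 0)), 1.0)
  expect_equal(f1(list(tp = 0, tn = 0, fp = 3, fn = 2)), 0.0)
  expect_equal(balanced_accuracy(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1.0)
})

test_that("zero-denominator metrics are undefined, never zero", {
  one_class <- list(tp = 10, fn = 2, fp = 0, tn = 0)
  expect_true(is.na(mcc(one_class)))
  expect_true(is.na(balanced_accuracy(one_class)))
  expect_true(is.na(f1(list(tp = 0, tn = 5, fp = 0, fn = 0))))
  pr <- precision_recall(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(all(is.na(pr)))
  expect_true(is.na(roc_auc(c(0.2, 0.8), c(1, 1))))
})

test_that("metrics agree with independent formulations on random tables", {
  set.seed(123)
  for (i in 1:200) {
    cc <- as.list(setNames(rpois(4, 12), c("tp", "tn", "fp", "fn")))
    truth <- c(rep(1, cc$tp), rep(0, cc$tn), rep(0, cc$fp), rep(1, cc$fn))
    call <- c(rep(1, cc$tp), rep(0, cc$tn), rep(1, cc$fp), rep(0, cc$fn))
    if (length(unique(truth)) < 2 || length(unique(call)) < 2) next
    expect_equal(mcc(cc), suppressWarnings(cor(truth, call)), tolerance = 1e-12)
    prec <- sum(truth & call) / sum(call)
    rec <- sum(truth & call) / sum(truth)
    if (prec + rec > 0) {
      expect_equal(f1(cc), 2 * prec * rec / (prec + rec), tolerance = 1e-12)
    }
    spec <- sum(!truth & !call) / sum(!truth)
    expect_equal(balanced_accuracy(cc), (rec + spec) / 2, tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the brute-force pairwise probability", {
  brute <- function(s, y) {
    a <- s[y == 1]; b <- s[y == 0]
    mean(outer(a, b, function(x, z) (x > z) + 0.5 * (x == z)))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    s <- round(runif(n), 2)   # rounded scores force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), brute(s, y), tolerance = 1e-12)
  }
})

test_that("fold plans are stratified, reproducible, and validated", {
  y <- rep(c("active", "inactive"), c(60, 40))
  f1_ <- fold_plan(y, 5, seed = 3)
  f2_ <- fold_plan(y, 5, seed = 3)
  expect_identical(f1_, f2_)
  for (k in 1:5) {
    frac <- mean(y[f1_ == k] == "active")
    expect_lt(abs(frac - 0.6), 0.10)
  }
  expect_error(fold_plan(rep(c("active", "inactive"), c(3, 50)), 5), "each class")
})

test_that("a minimal stratified 2-fold plan runs end to end", {
  d <- tibble::tibble(
    smiles = c("CCO", "CCN", "CCC", "CCCl"),
    label = c("active", "active", "inactive", "inactive")
  )
  cv <- crossvalidate(d, booster = booster_config(n_trees = 5), n_folds = 2,
                      seed = 1, featurizer = "morgan")
  expect_equal(nrow(cv$folds), 2)
  expect_true(all(c("mcc", "f1", "ba", "precision", "recall", "auc")
                  %in% names(cv$folds)))
})

test_that("cross-validation never leaks held-out molecules into training", {
  d <- small_target_data()
  gs <- small_graphs()
  cv <- crossvalidate(d, tiny_encoder("gcn"), booster_config(n_trees = 20),
                      n_folds = 3, seed = 2, graphs = gs)
  fold <- fold_plan(d$label, 3, seed = 2)
  for (k in 1:3) {
    expect_identical(cv$folds$train_hash[k], rlang::hash(sort(d$smiles[fold != k])))
  }
  # fold training sets differ, so per-fold encoders differ
  expect_equal(length(unique(cv$folds$train_hash)), 3)
})

test_that("cross-validated summary reports mean and sd in table style", {
  d <- small_target_data()
  cv <- crossvalidate(d, booster = booster_config(n_trees = 30), n_folds = 3,
                      seed = 7, featurizer = "morgan")
  expect_equal(cv$summary$metric,
               c("mcc", "f1", "ba", "precision", "recall", "auc"))
  td <- tidy(cv)
  expect_equal(nrow(td), 3 * 6)
  gl <- glance(cv)
  expect_equal(gl$featurizer[1], "morgan")
})

test_that("pooled multi-target protocol counts only known labels of eligible compounds", {
  # constructed 3-compound fixture; compound c3 has a single known active
  # target and must be excluded from the eligible set
  records <- tibble::tibble(
    compound_id = rep(c("c1", "c2", "c3"), each = 3),
    smiles = rep(c("CCO", "CCN", "CCC"), each = 3),
    target_id = rep(c("T1", "T2", "T3"), 3),
    label = c("active", "active", "inactive",
              "active", "active", "unknown",
              "active", "inactive", "inactive")
  )
  all_active <- tibble::tibble(
    compound_id = rep(c("c1", "c2", "c3"), each = 3),
    target_id = rep(c("T1", "T2", "T3"), 3),
    probability = 0.9, call = "active"
  )
  out <- multitarget_validation(NULL, records, calls = all_active)
  # eligible: c1 (2 known actives), c2 (2 known actives); c3 excluded.
  # known pairs: c1 x3, c2 x2 (unknown excluded) = 5; actives 4, inactives 1
  expect_equal(out$n_compounds, 2)
  expect_equal(out$n_pairs, 5)
  expect_equal(out$tpr, 1.0)
  expect_equal(out$fdr, 1 / 5)
  expect_true(is.na(out$npv))  # no negative calls at all
  # a perfect predictor has TPR = NPV = 1, FDR = 0
  perfect <- dplyr::mutate(records, probability = ifelse(label == "active", .9, .1),
                           call = ifelse(label == "active", "active", "inactive"))
  out2 <- multitarget_validation(NULL, records,
                                 calls = dplyr::select(perfect, -smiles, -label))
  expect_equal(c(out2$tpr, out2$npv, out2$fdr), c(1, 1, 0))
  # empty eligible set errors
  single <- dplyr::filter(records, compound_id == "c3")
  expect_error(multitarget_validation(NULL, single, calls = all_active),
               "at least 2")
})

test_that("stratified train/test split preserves both classes", {
  d <- small_target_data()
  sp <- train_test_split(d, 0.2, seed = 4)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d))
  expect_setequal(unique(sp$test$label), c("active", "inactive"))
  frac_all <- mean(d$label == "active")
  frac_test <- mean(sp$test$label == "active")
  expect_lt(abs(frac_all - frac_test), 0.1)
})
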