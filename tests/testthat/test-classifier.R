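test_that("cohort_features validates shape and missingness", {
  m <- matrix(1, 4, 3)
  expect_error(cohort_features(list(m), rep("ASD", 4)), "named")
  expect_error(cohort_features(list("1" = m, "2" = m[1:3, ]),
                               rep(c("ASD", "NT"), 2)), "disagree")
  m2 <- m; m2[1] <- NA
  expect_error(cohort_features(list("1" = m2), rep(c("ASD", "NT"), 2)),
               "missing")
  expect_error(cohort_features(list("1" = m), rep("ASD", 3)), "one entry")
})

test_that("nested CV is perfect on separable features and deterministic", {
  cf <- separable_features(n_per_class = 10)
  cfg <- cv_config(outer_folds = 5, repeats = 3, inner_folds = 3,
                   tw_grid = c(1, 2), seed = 99)
  res <- nested_cv_predict(cf, cfg)
  expect_equal(res$accuracy, 1)
  expect_false(anyNA(res$predictions))  # each participant predicted per repeat
  expect_true(all(res$selected_tw %in% c(1, 2)))

  res2 <- nested_cv_predict(cf, cfg)
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$scores, res2$scores)
  expect_identical(res$weights, res2$weights)
})

test_that("permuted labels score at chance level", {
  # average over 20 distinct permutations: a single permutation can align
  # with the real class structure by chance and inherit its signal
  cf <- separable_features(n_per_class = 12, seed = 55)
  labs <- cf$labels
  accs <- vapply(1:20, function(p) {
    set.seed(560 + p)
    cf$labels <- sample(labs)
    cfg <- cv_config(outer_folds = 6, repeats = 1, inner_folds = 3,
                     tw_grid = c(1, 2), seed = 57 + p, store_weights = FALSE)
    nested_cv_predict(cf, cfg)$accuracy
  }, 0)
  total <- 20L * length(labs)
  band <- stats::qbinom(c(0.025, 0.975), total, 0.5) / total
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("training folds lacking a class raise a named error", {
  set.seed(58)
  m <- matrix(rnorm(24), 6, 4)
  colnames(m) <- sprintf("f%d", 1:4)
  # both ASD cases sit in outer fold 1: its training set lacks the class
  cf <- cohort_features(list("1" = m), c("ASD", "ASD", rep("NT", 4)))
  cfg <- cv_config(outer_folds = 3, repeats = 1, inner_folds = 2,
                   tw_grid = 1, seed = 3)
  expect_error(facesync:::.run_cv(cf, cfg, shuffle = FALSE), "lacks a class")
})

test_that("standardization is fit on training folds only (canary check)", {
  # canary feature equal to the label signs -> perfect accuracy
  set.seed(61)
  n <- 20
  labs <- rep(c("ASD", "NT"), each = n / 2)
  canary <- ifelse(labs == "ASD", 1, -1) + rnorm(n, 0, 0.01)
  m <- cbind(canary, matrix(rnorm(n * 5), n, 5))
  colnames(m) <- sprintf("f%d", 1:6)
  cf <- cohort_features(list("1" = m), labs)
  cfg <- cv_config(outer_folds = 5, repeats = 2, inner_folds = 2,
                   tw_grid = 1, seed = 62, store_weights = FALSE)
  expect_equal(nested_cv_predict(cf, cfg)$accuracy, 1)

  # shuffled canary must not stay perfect
  m[, 1] <- sample(m[, 1])
  cf2 <- cohort_features(list("1" = m), labs)
  expect_lt(nested_cv_predict(cf2, cfg)$accuracy, 1)
})

test_that("stratified folds keep both classes in every training fold", {
  # unbalanced cohort where plain folds regularly drop the minority class
  set.seed(63)
  m <- matrix(rnorm(12 * 6), 12, 6)
  colnames(m) <- sprintf("f%d", 1:6)
  labs <- c(rep("ASD", 3), rep("NT", 9))
  m[labs == "ASD", 1] <- m[labs == "ASD", 1] + 8
  cf <- cohort_features(list("1" = m), labs)
  cfg <- cv_config(outer_folds = 3, repeats = 10, inner_folds = 2,
                   tw_grid = 1, seed = 64, store_weights = FALSE,
                   stratify = TRUE)
  res <- nested_cv_predict(cf, cfg)   # plain folds would hit class-less folds
  expect_gt(res$accuracy, 0.9)
})

test_that("loocv_predict equals nested CV with n folds and one repeat", {
  cf <- separable_features(n_per_class = 6, shift = 8, seed = 65)
  loo <- loocv_predict(cf)
  expect_identical(as.character(loo), cf$labels)  # separable -> all correct

  cfg <- cv_config(outer_folds = length(cf$labels), repeats = 1,
                   tw_grid = c(1, 2))
  res <- facesync:::.run_cv(cf, cfg, shuffle = FALSE)
  expect_identical(as.character(loo), unname(res$predictions[1, ]))
})

test_that("participant_accuracy averages per-repeat correctness", {
  cf <- separable_features(n_per_class = 8, seed = 66)
  acc <- participant_accuracy(cf, k_folds = 4, repeats = 6,
                              cfg = cv_config(tw_grid = c(1, 2), seed = 67,
                                              inner_folds = 2))
  expect_true(all(acc == 1))   # separable case

  # counting identity: mean per-participant accuracy == pooled accuracy
  res <- attr(acc, "cv")
  expect_equal(mean(acc), res$accuracy)
  # reproducibility
  acc2 <- participant_accuracy(cf, k_folds = 4, repeats = 6,
                               cfg = cv_config(tw_grid = c(1, 2), seed = 67,
                                               inner_folds = 2))
  expect_identical(unname(acc), unname(acc2))
})

test_that("compute_metrics matches the closed forms", {
  perfect <- compute_metrics(c("ASD", "NT"), c("ASD", "NT"))
  expect_equal(unlist(perfect[c("accuracy", "ppv", "npv", "sensitivity",
                                "specificity")]),
               c(accuracy = 1, ppv = 1, npv = 1, sensitivity = 1,
                 specificity = 1))

  # TP=3 FN=2 TN=9 FP=1
  truth <- c(rep("ASD", 5), rep("NT", 10))
  pred <- c("ASD", "ASD", "ASD", "NT", "NT",
            "ASD", rep("NT", 9))
  m <- compute_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 9 / 11)
  expect_equal(m$accuracy, 12 / 15)
  expect_length(m$undefined, 0)

  # no predicted positives -> PPV is NA with a flag, not 0
  m2 <- compute_metrics(rep("NT", 4), c("ASD", "ASD", "NT", "NT"))
  expect_true(is.na(m2$ppv))
  expect_identical(m2$undefined, "ppv")
})

test_that("average_feature_weights matches direct recomputation", {
  cf <- separable_features(n_per_class = 6, M = 8, seed = 68)
  cfg <- cv_config(outer_folds = 3, repeats = 2, inner_folds = 2,
                   tw_grid = c(1, 2), seed = 69)
  res <- nested_cv_predict(cf, cfg)
  aw <- average_feature_weights(res)
  expect_equal(aw$mean_abs_weight, unname(colMeans(abs(res$weights))))
  expect_equal(aw$se,
               unname(apply(abs(res$weights), 2, stats::sd) /
                        sqrt(nrow(res$weights))))

  # single fold: |weights| unchanged, zero-ish se undefined -> se = 0 rule
  cfg1 <- cv_config(outer_folds = 2, repeats = 1, inner_folds = 2,
                    tw_grid = 1, seed = 70)
  res1 <- nested_cv_predict(cf, cfg1)
  w1 <- average_feature_weights(res1)
  expect_equal(w1$mean_abs_weight, unname(colMeans(abs(res1$weights))))

  # equal weights across folds -> zero standard error
  res_eq <- res
  res_eq$weights <- matrix(rep(res$weights[1, ], each = 4), 4,
                           ncol(res$weights),
                           dimnames = dimnames(res$weights[rep(1, 4), ]))
  expect_true(all(average_feature_weights(res_eq)$se == 0))
})
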