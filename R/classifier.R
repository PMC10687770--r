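# Diagnosis classification under the study's cross-validation schemes.

#' Bundle per-window-length feature tables for a cohort
#'
#' @param tw_tables Named list (names = window lengths in seconds as
#'   character) of participants x M feature matrices, same row order in each.
#' @param labels Diagnosis labels, one per participant, two classes
#'   (canonically `"ASD"` / `"NT"`).
#' @param ids Optional participant identifiers.
#' @return Object of class `cohort_features`.
#' @export
cohort_features <- function(tw_tables, labels, ids = NULL) {
  if (!length(tw_tables)) stop("need at least one feature table")
  if (is.null(names(tw_tables))) stop("tw_tables must be named by window length")
  n <- nrow(tw_tables[[1L]])
  for (tab in tw_tables) {
    if (nrow(tab) != n) stop("feature tables disagree on participant count")
    if (anyNA(tab)) stop("feature tables must not contain missing values")
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per participant")
  if (is.null(ids)) ids <- rownames(tw_tables[[1L]])
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(n))
  structure(list(tw_tables = tw_tables, labels = labels, ids = ids),
            class = "cohort_features")
}

#' Cross-validation configuration
#'
#' Defaults mirror the study design: 10 outer folds repeated 100 times with
#' shuffled participant order, 5 inner folds selecting the window length over
#' the grid 1, 2, 4, 6 seconds, linear SVM at C = 1, per-feature z-scoring
#' fit on training folds only.
#'
#' @param outer_folds Outer fold count (default 10).
#' @param repeats Number of shuffled repeats (default 100).
#' @param inner_folds Inner fold count for window-length selection (default 5).
#' @param tw_grid Candidate window lengths, seconds (default `c(1, 2, 4, 6)`).
#' @param cost SVM cost C (default 1).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param standardize Z-score features on training statistics (default TRUE).
#' @param store_weights Keep per-fold weight vectors (default TRUE).
#' @param stratify Balance class proportions across outer folds (default
#'   FALSE: plain folds of the shuffled participant order).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, repeats = 100L, inner_folds = 5L,
                      tw_grid = c(1, 2, 4, 6), cost = 1, seed = 1L,
                      standardize = TRUE, store_weights = TRUE,
                      stratify = FALSE) {
  if (outer_folds < 2L) stop("outer_folds must be at least 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 tw_grid = sort(as.numeric(tw_grid)), cost = cost,
                 seed = as.integer(seed), standardize = isTRUE(standardize),
                 store_weights = isTRUE(store_weights),
                 stratify = isTRUE(stratify)),
            class = "cv_config")
}

.fit_scaler <- function(x, standardize) {
  if (!standardize)
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  center <- colMeans(x)
  sc <- sqrt(colMeans(sweep(x, 2L, center)^2) * nrow(x) / max(nrow(x) - 1L, 1L))
  sc[sc == 0] <- 1
  list(center = center, scale = sc)
}

.apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center), 2L, sc$scale, "/")
}

# contiguous fold ids for a sequence of length n
.fold_ids <- function(n, k) sort(rep_len(seq_len(k), n))

# inner CV window-length selection on a training subset; returns the name of
# the winning table (ties -> smallest Tw, guaranteed by sorted tw_grid)
.select_tw <- function(features, train, cfg) {
  tws <- as.character(cfg$tw_grid)
  tws <- tws[tws %in% names(features$tw_tables)]
  if (!length(tws)) stop("tw_grid does not match the available feature tables")
  if (length(tws) == 1L) return(tws)
  y <- features$labels[train]
  k <- min(cfg$inner_folds, length(train))
  ids <- .fold_ids(length(train), k)
  correct <- stats::setNames(numeric(length(tws)), tws)
  for (f in seq_len(k)) {
    tr <- train[ids != f]; te <- train[ids == f]
    ytr <- features$labels[tr]
    if (length(unique(ytr)) < 2L)
      stop("inner training fold ", f, " lacks a class")
    for (tw in tws) {
      X <- features$tw_tables[[tw]]
      sc <- .fit_scaler(X[tr, , drop = FALSE], cfg$standardize)
      fit <- linear_svm(.apply_scaler(X[tr, , drop = FALSE], sc), ytr,
                        C = cfg$cost)
      pred <- predict(fit, .apply_scaler(X[te, , drop = FALSE], sc))
      correct[tw] <- correct[tw] + sum(pred == features$labels[te])
    }
  }
  tws[which.max(correct)]   # first max = smallest Tw on ties
}

.run_cv <- function(features, cfg, shuffle = TRUE) {
  stopifnot(inherits(features, "cohort_features"), inherits(cfg, "cv_config"))
  n <- length(features$labels)
  if (min(table(features$labels)) < 2L)
    stop("need at least 2 participants per class")
  k <- cfg$outer_folds
  if (k > n) stop("more outer folds than participants")
  M <- ncol(features$tw_tables[[1L]])
  feat_names <- colnames(features$tw_tables[[1L]])

  predictions <- matrix(NA_character_, cfg$repeats, n,
                        dimnames = list(NULL, features$ids))
  scores <- matrix(NA_real_, cfg$repeats, n,
                   dimnames = list(NULL, features$ids))
  selected_tw <- matrix(NA_real_, cfg$repeats, k)
  weights <- if (cfg$store_weights)
    matrix(NA_real_, cfg$repeats * k, M,
           dimnames = list(NULL, feat_names)) else NULL

  for (r in seq_len(cfg$repeats)) {
    ord <- if (shuffle) {
      set.seed(cfg$seed + r - 1L)
      sample.int(n)
    } else seq_len(n)
    ids <- if (cfg$stratify) {
      # round-robin fold assignment within each class, in shuffled order
      fid <- integer(n)
      for (cl in unique(features$labels))
        fid[features$labels[ord] == cl] <-
          rep_len(seq_len(k), sum(features$labels == cl))
      fid
    } else .fold_ids(n, k)
    for (f in seq_len(k)) {
      test <- ord[ids == f]
      train <- ord[ids != f]
      ytr <- features$labels[train]
      if (length(unique(ytr)) < 2L)
        stop("training fold ", f, " (repeat ", r, ") lacks a class")
      tw <- .select_tw(features, train, cfg)
      X <- features$tw_tables[[tw]]
      sc <- .fit_scaler(X[train, , drop = FALSE], cfg$standardize)
      fit <- linear_svm(.apply_scaler(X[train, , drop = FALSE], sc), ytr,
                        C = cfg$cost)
      sco <- predict(fit, .apply_scaler(X[test, , drop = FALSE], sc),
                     type = "score")
      neg <- setdiff(fit$levels, fit$positive)
      predictions[r, test] <- ifelse(sco > 0, fit$positive, neg)
      scores[r, test] <- sco
      selected_tw[r, f] <- as.numeric(tw)
      if (cfg$store_weights) weights[(r - 1L) * k + f, ] <- fit$weights
    }
  }
  acc_per_repeat <- rowMeans(predictions ==
                               matrix(features$labels, cfg$repeats, n,
                                      byrow = TRUE))
  structure(list(predictions = predictions, scores = scores,
                 selected_tw = selected_tw, weights = weights,
                 labels = features$labels, ids = features$ids, config = cfg,
                 accuracy = mean(acc_per_repeat),
                 accuracy_per_repeat = acc_per_repeat),
            class = "cv_result")
}

#' Nested cross-validation prediction
#'
#' Outer folds estimate out-of-sample accuracy while inner folds select the
#' window length Tw (the only tuned hyper-parameter; the SVM cost stays at its
#' default). Per repeat, participants are shuffled with a seeded RNG and split
#' into `outer_folds` contiguous groups; inner 5-fold CV on each outer
#' training set picks the Tw with the highest inner accuracy (ties go to the
#' smaller Tw); a linear SVM is trained at C on training-standardized
#' features and applied to the held-out fold. Deterministic given the seed.
#'
#' @param features A [cohort_features()].
#' @param cfg A [cv_config()].
#' @return Object of class `cv_result`: per-repeat predictions and decision
#'   scores (every participant predicted exactly once per repeat), per-fold
#'   selected Tw and weight vectors (in standardized feature space), pooled
#'   accuracy.
#' @export
nested_cv_predict <- function(features, cfg = cv_config()) {
  .run_cv(features, cfg, shuffle = TRUE)
}

#' Leave-one-out cross-validation prediction
#'
#' [nested_cv_predict()] with one fold per participant and a single repeat;
#' no shuffling is needed, so the result is deterministic without a seed.
#'
#' @param features A [cohort_features()].
#' @param cfg A [cv_config()]; `outer_folds` and `repeats` are overridden.
#' @return Named character vector of per-participant predicted labels, with
#'   the full `cv_result` attached as attribute `cv`.
#' @export
loocv_predict <- function(features, cfg = cv_config()) {
  n <- length(features$labels)
  cfg$outer_folds <- n
  cfg$repeats <- 1L
  res <- .run_cv(features, cfg, shuffle = FALSE)
  out <- stats::setNames(res$predictions[1L, ], features$ids)
  attr(out, "cv") <- res
  out
}

#' Per-participant prediction accuracy under repeated k-fold CV
#'
#' Repeats k-fold cross-validation with reshuffled participant order and
#' reports, for each participant, the fraction of repeats in which they were
#' predicted correctly (the study uses 5 folds and 1000 repeats for this).
#'
#' @param features A [cohort_features()].
#' @param k_folds Fold count (default 5).
#' @param repeats Number of repeats (default 1000).
#' @param cfg A [cv_config()] supplying seed, grid, cost; fold/repeat fields
#'   are overridden.
#' @return Named numeric vector of per-participant accuracies in `[0, 1]`,
#'   with the `cv_result` attached as attribute `cv`.
#' @export
participant_accuracy <- function(features, k_folds = 5L, repeats = 1000L,
                                 cfg = cv_config()) {
  cfg$outer_folds <- as.integer(k_folds)
  cfg$repeats <- as.integer(repeats)
  cfg$store_weights <- FALSE
  res <- .run_cv(features, cfg, shuffle = TRUE)
  truth <- matrix(features$labels, repeats, length(features$labels),
                  byrow = TRUE)
  out <- stats::setNames(colMeans(res$predictions == truth), features$ids)
  attr(out, "cv") <- res
  out
}

#' Confusion-matrix performance metrics
#'
#' Accuracy, positive/negative predictive value, sensitivity and specificity
#' from predicted and true labels. A metric whose denominator is empty (e.g.
#' PPV with no predicted positives) is returned as `NA` and listed in the
#' `undefined` field rather than being coerced to 0.
#'
#' @param predicted,truth Label vectors of equal length.
#' @param positive Positive class (default `"ASD"`).
#' @return Object of class `classification_metrics`: list with `accuracy`,
#'   `ppv`, `npv`, `sensitivity`, `specificity`, the confusion counts, and
#'   `undefined`.
#' @export
compute_metrics <- function(predicted, truth, positive = "ASD") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  pos_t <- truth == positive; pos_p <- predicted == positive
  tp <- sum(pos_p & pos_t); fp <- sum(pos_p & !pos_t)
  fn <- sum(!pos_p & pos_t); tn <- sum(!pos_p & !pos_t)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = safe(tp + tn, tp + tn + fp + fn),
              ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
              sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              tp = tp, fp = fp, fn = fn, tn = tn)
  out$undefined <- names(which(vapply(out[1:5], is.na, logical(1))))
  structure(out, class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | ppv %.3f | npv %.3f | sensitivity %.3f | specificity %.3f\n",
    x$accuracy, x$ppv, x$npv, x$sensitivity, x$specificity))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d repeats x %d participants, accuracy %.3f\n",
              nrow(x$predictions), ncol(x$predictions), x$accuracy))
  invisible(x)
}

#' Average absolute feature weights across cross-validation folds
#'
#' @param cvresult A `cv_result` fitted with `store_weights = TRUE`.
#' @return Data frame with one row per feature: `feature`,
#'   `mean_abs_weight`, `se` (standard error of |weight| across folds).
#' @export
average_feature_weights <- function(cvresult) {
  stopifnot(inherits(cvresult, "cv_result"))
  W <- cvresult$weights
  if (is.null(W)) stop("cv_result was computed with store_weights = FALSE")
  A <- abs(W)
  nfit <- nrow(A)
  m <- colMeans(A)
  se <- if (nfit > 1L) {
    sqrt(colMeans(sweep(A, 2L, m)^2) * nfit / (nfit - 1L)) / sqrt(nfit)
  } else rep(0, ncol(A))
  data.frame(feature = colnames(A), mean_abs_weight = unname(m),
             se = unname(se), stringsAsFactors = FALSE)
}
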