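# Linear maximum-margin classifier (L2-regularized hinge-loss SVM).
#
# Solved in the dual by coordinate descent (the liblinear L1-loss dual CD
# algorithm) on the Gram matrix, which is the cheap formulation when the
# number of samples is far below the feature dimension. The intercept is an
# augmented constant feature and is therefore regularized, matching
# liblinear / scikit-learn LinearSVC(loss = "hinge") with intercept scaling 1.
# Updates sweep the samples in a fixed cyclic order, so the fit is
# deterministic and independent of the global RNG state.

#' Fit a linear hinge-loss support vector classifier
#'
#' Minimizes `0.5 * ||w||^2 + C * sum(max(0, 1 - y * (x %*% w + b)))` with the
#' intercept included in the regularized weight vector via an augmented
#' constant feature. `C = 1` is the package-wide default.
#'
#' @param x Numeric n x p feature matrix.
#' @param y Labels: a factor/character with exactly two classes, or a +-1
#'   numeric vector.
#' @param C Soft-margin cost (default 1).
#' @param positive Label treated as +1 (default `"ASD"` when present, else
#'   the first level).
#' @param tol Stop when the largest projected dual gradient falls below this
#'   (default 1e-8).
#' @param max_epochs Maximum passes over the data (default 20000).
#' @return Object of class `linear_svm` with `weights`, `intercept`, `alpha`,
#'   `levels`, `positive`, `converged`, `epochs`.
#' @export
linear_svm <- function(x, y, C = 1, positive = NULL, tol = 1e-8,
                       max_epochs = 20000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    lv <- c("-1", "1")
    if (is.null(positive)) positive <- "1"
    yv <- as.numeric(y)
  } else {
    y <- as.character(y)
    lv <- sort(unique(y))
    if (length(lv) != 2L) stop("y must contain exactly two classes")
    if (is.null(positive)) positive <- if ("ASD" %in% lv) "ASD" else lv[1L]
    if (!positive %in% lv) stop("positive class '", positive, "' not in y")
    yv <- ifelse(y == positive, 1, -1)
  }
  if (length(yv) != n) stop("length(y) must equal nrow(x)")

  K <- tcrossprod(x) + 1          # Gram with augmented intercept feature
  Q <- K * tcrossprod(yv)
  qd <- diag(Q)
  alpha <- numeric(n)
  Qa <- numeric(n)                # Q %*% alpha, maintained incrementally
  converged <- FALSE
  epochs <- 0L
  for (epoch in seq_len(max_epochs)) {
    epochs <- epoch
    maxpg <- 0
    for (i in seq_len(n)) {
      G <- Qa[i] - 1
      a <- alpha[i]
      if (a <= 0) PG <- min(G, 0)
      else if (a >= C) PG <- max(G, 0)
      else PG <- G
      apg <- abs(PG)
      if (apg > maxpg) maxpg <- apg
      if (apg > 1e-14) {
        newa <- min(max(a - G / qd[i], 0), C)
        d <- newa - a
        if (d != 0) {
          alpha[i] <- newa
          Qa <- Qa + d * Q[, i]
        }
      }
    }
    if (maxpg < tol) { converged <- TRUE; break }
  }
  coefy <- alpha * yv
  structure(list(weights = drop(crossprod(x, coefy)),
                 intercept = sum(coefy),
                 alpha = alpha, levels = lv, positive = positive,
                 C = C, converged = converged, epochs = epochs),
            class = "linear_svm")
}

#' Predict from a linear SVM
#'
#' Decision scores are signed distances scaled by the weight norm
#' (`x %*% w + b`); the class boundary is at score 0, positive scores map to
#' the positive class.
#'
#' @param object A fitted [linear_svm()].
#' @param newx Numeric matrix (or single row vector) of features.
#' @param type `"class"` for labels (default) or `"score"` for raw decision
#'   values.
#' @param ... Unused.
#' @return Character vector of labels or numeric score vector.
#' @export
predict.linear_svm <- function(object, newx, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  score <- drop(as.matrix(newx) %*% object$weights + object$intercept)
  if (type == "score") return(score)
  neg <- setdiff(object$levels, object$positive)
  ifelse(score > 0, object$positive, neg)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, C = %g, %s after %d epochs\n",
              length(x$weights), x$C,
              if (x$converged) "converged" else "NOT converged", x$epochs))
  invisible(x)
}
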