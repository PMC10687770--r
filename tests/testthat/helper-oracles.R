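# Independent oracles and small fixture builders. These deliberately avoid
# the package's kernels: correlations via stats::cor on explicit segments,
# nearest neighbours via exhaustive loops.

# exhaustive per-window, per-lag forward cross-correlation maxima
oracle_max_xcorr <- function(Y, W, step, L) {
  C <- nrow(Y)
  starts <- seq(1L, ncol(Y) - W + 1L, by = step)
  res <- array(NA_real_, c(C, C, length(starts)))
  for (w in seq_along(starts)) {
    s <- starts[w]
    for (i in seq_len(C)) for (j in seq_len(C)) {
      best <- -Inf
      for (l in 0:L) {
        a <- Y[i, s:(s + W - 1L - l)]
        b <- Y[j, (s + l):(s + W - 1L)]
        r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
        best <- max(best, r)
      }
      res[i, j, w] <- best
    }
  }
  res
}

# oracle feature vector (mu then sigma, row-major ordered pairs) from the
# brute-force maxima; population standard deviation
oracle_features <- function(Y, W, step, L) {
  arr <- oracle_max_xcorr(Y, W, step, L)
  C <- nrow(Y)
  mu <- sig <- matrix(NA_real_, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    v <- arr[i, j, ]
    mu[i, j] <- mean(v)
    sig[i, j] <- sqrt(mean((v - mean(v))^2))
  }
  c(as.vector(t(mu)), as.vector(t(sig)))
}

# uniformly random proper rotation via QR with determinant fix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# tiny deterministic rater panel used by the closed-form comparison tests:
# 3 raters (2 expert, 1 non-expert) x 4 participants
toy_panel <- function() {
  truth <- c("ASD", "ASD", "NT", "NT")
  preds <- rbind(
    c("ASD", "NT", "NT", "NT"),   # expert, 3/4 correct
    c("ASD", "NT", "ASD", "NT"),  # expert, 2/4 correct
    c("NT",  "NT", "NT", "NT"))   # non-expert, 2/4 correct
  rater_panel(preds, c("expert", "expert", "non_expert"), truth,
              rater_ids = c("r1", "r2", "r3"),
              participant_ids = c("p1", "p2", "p3", "p4"))
}

# separable two-Gaussian feature tables for classifier tests
separable_features <- function(n_per_class = 10L, M = 12L, shift = 4,
                               tw = c("1", "2"), seed = 11L) {
  set.seed(seed)
  n <- 2L * n_per_class
  labs <- rep(c("ASD", "NT"), each = n_per_class)
  tabs <- lapply(tw, function(x) {
    m <- matrix(stats::rnorm(n * M), n, M)
    m[labs == "ASD", 1:3] <- m[labs == "ASD", 1:3] + shift
    colnames(m) <- sprintf("f%03d", seq_len(M))
    m
  })
  names(tabs) <- tw
  cohort_features(tabs, labs)
}
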