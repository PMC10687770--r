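# Windowed forward-lag cross-correlation features.
#
# For every ordered channel pair (i, j) the series are cut into windows of
# Tw seconds with 50% overlap; within each window the Pearson correlation
# between channel i and channel j shifted forward by lag l (i leading j) is
# maximized over l = 0..max_lag. The per-window maxima are summarized by
# their mean (mu) and population standard deviation (sigma), giving
# M = 2 * C^2 features for C channels.

#' Windowing configuration
#'
#' @param window_seconds Window length Tw in seconds (candidate grid used for
#'   model selection downstream: 1, 2, 4, 6).
#' @param frame_rate Frames per second (default 30).
#' @param max_lag_frames Maximum forward lag in frames; default
#'   `floor(window_frames / 2)`, which keeps at least a half-window of
#'   overlap between the correlated segments. Must satisfy
#'   `0 <= max_lag_frames <= window_frames - 3`.
#' @return Object of class `window_config` with elements `window_seconds`,
#'   `frame_rate`, `window_frames` (nearest-integer `Tw * fps`, at least 4),
#'   `step_frames` (`floor(window_frames / 2)`), `max_lag_frames`.
#' @export
window_config <- function(window_seconds, frame_rate = 30,
                          max_lag_frames = NULL) {
  wf <- as.integer(round(window_seconds * frame_rate))
  if (wf < 4L) stop("window of ", wf, " frames is too short (need >= 4)")
  step <- wf %/% 2L
  if (is.null(max_lag_frames)) max_lag_frames <- wf %/% 2L
  max_lag_frames <- as.integer(max_lag_frames)
  if (max_lag_frames < 0L || max_lag_frames > wf - 3L)
    stop("max_lag_frames must lie in [0, window_frames - 3] = [0, ", wf - 3L, "]")
  structure(list(window_seconds = window_seconds, frame_rate = frame_rate,
                 window_frames = wf, step_frames = step,
                 max_lag_frames = max_lag_frames),
            class = "window_config")
}

#' Window start indices
#'
#' Starts are 1, 1 + step, 1 + 2*step, ... while the full window fits; a
#' trailing partial window is discarded.
#'
#' @param n_frames Series length T in frames.
#' @param cfg A [window_config()].
#' @return Integer vector of 1-based start indices.
#' @export
window_starts <- function(n_frames, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  wf <- cfg$window_frames
  if (n_frames < wf)
    stop("series too short: ", n_frames, " frames < window of ", wf)
  seq.int(1L, n_frames - wf + 1L, by = cfg$step_frames)
}

# Core kernel: per-window maxima of the forward-lag Pearson correlation for
# ALL ordered channel pairs at once. Returns a C x C x n_windows array where
# [i, j, w] is the maximum over lags l = 0..L of cor(i-segment, j-segment
# shifted forward by l) in window w. Zero-variance segments contribute
# correlation 0 at that lag. Implemented in C++ (src/xcorr.cpp): one small
# BLAS product per (window, lag) plus cumulative-sum segment moments.
.window_max_xcorr_all <- function(Y, cfg) {
  starts <- window_starts(ncol(Y), cfg)
  window_max_xcorr_cpp(Y, as.integer(starts), cfg$window_frames,
                       cfg$max_lag_frames)
}

#' Per-window maxima of the forward-lag cross-correlation of two series
#'
#' For each window, the Pearson correlation between `a[s : s+W-1-l]` and
#' `b[s+l : s+W-1]` (b shifted forward: a leading b) is computed for lags
#' l = 0..max_lag and the maximum signed correlation is recorded.
#' Zero-variance segments yield correlation 0 at that lag.
#'
#' @param a,b Numeric series of equal length (at least one window).
#' @param cfg A [window_config()].
#' @return Numeric vector of per-window maxima, one per window start.
#' @export
windowed_max_xcorr <- function(a, b, cfg) {
  if (length(a) != length(b))
    stop("series lengths differ: ", length(a), " vs ", length(b))
  arr <- .window_max_xcorr_all(rbind(as.numeric(a), as.numeric(b)), cfg)
  arr[1L, 2L, ]
}

#' Extract the coordination feature vector from a behavior matrix
#'
#' For every ordered channel pair (i, j), including i = j, the per-window
#' forward-lag correlation maxima are summarized by their mean `mu(i->j)` and
#' population (ddof 0) standard deviation `sigma(i->j)`. Features are ordered
#' deterministically: all mu in row-major (i, j) order, then all sigma.
#' For C channels the vector has M = 2 * C^2 entries (6272 for C = 56).
#'
#' @param behavior A [behavior_matrix()] or plain channels x T matrix.
#' @param cfg A [window_config()].
#' @return Object of class `coord_features`: list with `values` (named
#'   numeric vector of length M), `names`, and `config`.
#' @export
extract_features <- function(behavior, cfg) {
  if (inherits(behavior, "behavior_matrix")) {
    Y <- behavior$values
    ch <- behavior$channel_descriptors
  } else {
    Y <- as.matrix(behavior)
    ch <- rownames(Y)
    if (is.null(ch)) ch <- sprintf("ch_%02d", seq_len(nrow(Y)))
  }
  C <- nrow(Y)
  arr <- .window_max_xcorr_all(Y, cfg)
  nwin <- dim(arr)[3L]
  m <- matrix(arr, C * C, nwin)          # column-major: (i,j) with i fastest
  mu <- rowMeans(m)
  sig <- sqrt(rowMeans((m - mu)^2))      # two-pass population sd: exact zeros
  # reorder to row-major (i outer, j inner)
  rm_idx <- as.vector(t(matrix(seq_len(C * C), C, C)))
  mu <- mu[rm_idx]; sig <- sig[rm_idx]
  iname <- rep(ch, each = C); jname <- rep(ch, times = C)
  nms <- c(sprintf("mu(%s->%s)", iname, jname),
           sprintf("sigma(%s->%s)", iname, jname))
  vals <- c(mu, sig)
  names(vals) <- nms
  structure(list(values = vals, names = nms, config = cfg),
            class = "coord_features")
}

#' @export
print.coord_features <- function(x, ...) {
  cat(sprintf("coord_features: %d features (Tw = %g s, max lag %d frames)\n",
              length(x$values), x$config$window_seconds,
              x$config$max_lag_frames))
  invisible(x)
}

#' @export
as.numeric.coord_features <- function(x, ...) x$values

#' Extract feature tables for a whole cohort over a window-length grid
#'
#' Runs [extract_features()] for every participant and every candidate window
#' length, producing the per-Tw feature tables consumed by the classifier.
#'
#' @param cohort A `behavior_cohort` from [gen_behavior_cohort()], or a plain
#'   list of `behavior_matrix` objects plus a `labels` vector.
#' @param tw_grid Candidate window lengths in seconds (default `c(1, 2, 4, 6)`).
#' @param labels Diagnosis labels, required when `cohort` is a plain list.
#' @param max_lag_frames Optional fixed max lag; default per-Tw
#'   `floor(window_frames/2)`.
#' @return A [cohort_features()] object.
#' @export
extract_cohort_features <- function(cohort, tw_grid = c(1, 2, 4, 6),
                                    labels = NULL, max_lag_frames = NULL) {
  if (inherits(cohort, "behavior_cohort")) {
    mats <- lapply(cohort$participants, `[[`, "behavior")
    labels <- cohort$labels
    ids <- vapply(cohort$participants, `[[`, "", "id")
  } else {
    mats <- cohort
    if (is.null(labels)) stop("labels are required for a plain cohort list")
    ids <- names(mats)
    if (is.null(ids)) ids <- sprintf("p%02d", seq_along(mats))
  }
  fps <- mats[[1L]]$frame_rate
  tw_tables <- lapply(tw_grid, function(tw) {
    cfg <- window_config(tw, frame_rate = fps, max_lag_frames = max_lag_frames)
    rows <- lapply(mats, function(bm) extract_features(bm, cfg)$values)
    tab <- do.call(rbind, rows)
    rownames(tab) <- ids
    tab
  })
  names(tw_tables) <- as.character(tw_grid)
  cohort_features(tw_tables, labels, ids)
}
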