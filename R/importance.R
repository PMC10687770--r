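# Category-level summaries of classifier feature weights.

.FEATURE_CATEGORIES <- c("brow", "eye", "mouth", "pose")

# channel descriptor -> category ("brow_03" -> "brow", "pose_yaw" -> "pose")
.channel_category <- function(ch) sub("_.*$", "", ch)

#' Tag coordination features with their facial-category pair
#'
#' Parses feature names of the form `mu(chA->chB)` / `sigma(chA->chB)` and
#' maps each side's channel to its facial category (`brow`, `eye`, `mouth`,
#' `pose`). A feature touching two categories belongs to both; the unordered
#' pair label (e.g. `"eye-pose"`) is also derived.
#'
#' @param feature_names Character vector of feature names as produced by
#'   [extract_features()].
#' @return Data frame with columns `feature`, `stat` (mu/sigma), `side_a`,
#'   `side_b` (categories), `pair` (unordered label, alphabetical).
#' @export
tag_features <- function(feature_names) {
  m <- regmatches(feature_names,
                  regexec("^(mu|sigma)\\((.+)->(.+)\\)$", feature_names))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("unparseable feature name(s), e.g. ", feature_names[which(bad)[1L]])
  stat <- vapply(m, `[`, "", 2L)
  a <- .channel_category(vapply(m, `[`, "", 3L))
  b <- .channel_category(vapply(m, `[`, "", 4L))
  known <- c(.FEATURE_CATEGORIES, "nose")
  if (!all(c(a, b) %in% known))
    stop("unknown channel category in feature names")
  pair <- ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  data.frame(feature = feature_names, stat = stat, side_a = a, side_b = b,
             pair = pair, stringsAsFactors = FALSE)
}

#' Mean and standard deviation of |weight| per facial-region pair
#'
#' Groups features by their unordered category pair (eye-eye, eye-pose,
#' mouth-pose, ...) and summarizes the absolute classifier weights within
#' each group.
#'
#' @param weights Numeric vector of (average) feature weights, aligned with
#'   `map`.
#' @param map Feature tags from [tag_features()].
#' @return Data frame with columns `pair`, `mean_abs_weight`, `sd_abs_weight`,
#'   `n_features`, sorted by decreasing mean.
#' @export
region_pair_weight_summary <- function(weights, map) {
  if (length(weights) != nrow(map))
    stop("weights and map lengths differ")
  w <- abs(as.numeric(weights))
  mean_w <- tapply(w, map$pair, mean)
  sd_w <- tapply(w, map$pair, stats::sd)
  n <- tapply(w, map$pair, length)
  out <- data.frame(pair = names(mean_w), mean_abs_weight = as.numeric(mean_w),
                    sd_abs_weight = as.numeric(sd_w),
                    n_features = as.integer(n), stringsAsFactors = FALSE)
  out[order(-out$mean_abs_weight), , drop = FALSE]
}

#' Category ratios among the top-k weighted features
#'
#' Ranks features by weight (descending, ties broken by feature name) and
#' reports, for each facial category and each k, its share of the top-k
#' features. Two counting conventions are implemented:
#'
#' * `"slot"` (default): each feature contributes its two sides separately,
#'   so the ratio is category slots / (2k) and the four categories sum to 1
#'   at every k. The k = M baseline equals the channel-marginal rate (e.g.
#'   3/56 for pose with 3 pose channels of 56).
#' * `"membership"`: a feature counts once for every category it touches, so
#'   ratios may sum to more than 1.
#'
#' The k = M row is the baseline rate and is independent of the weights.
#'
#' @param weights Numeric vector of feature weights (use mean |weight| across
#'   folds), aligned with `map`.
#' @param map Feature tags from [tag_features()].
#' @param ks Integer vector of list lengths (default
#'   `c(10, 100, 1000, length(weights))`).
#' @param convention `"slot"` or `"membership"`.
#' @return Data frame with columns `category`, `k`, `ratio`, `convention`.
#' @export
topk_category_ratio <- function(weights, map,
                                ks = c(10L, 100L, 1000L, length(weights)),
                                convention = c("slot", "membership")) {
  convention <- match.arg(convention)
  if (length(weights) != nrow(map))
    stop("weights and map lengths differ")
  ks <- as.integer(ks)
  if (any(ks < 1L) || any(ks > nrow(map)))
    stop("ks must lie in 1..number of features")
  ord <- order(-as.numeric(weights), map$feature)
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    top <- map[ord[seq_len(k)], , drop = FALSE]
    ratio <- vapply(.FEATURE_CATEGORIES, function(cat) {
      if (convention == "slot")
        (sum(top$side_a == cat) + sum(top$side_b == cat)) / (2 * k)
      else
        mean(top$side_a == cat | top$side_b == cat)
    }, 0)
    out[[i]] <- data.frame(category = .FEATURE_CATEGORIES, k = k,
                           ratio = unname(ratio), convention = convention,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Enrichment of a feature set among the top-k weights
#'
#' Convenience check used to verify that planted signal (e.g. the coupled
#' channel pairs of a synthetic cohort) rises to the top of the weight
#' ranking: the share of `target_features` among the k highest-weighted
#' features divided by their share of the whole pool.
#'
#' @param weights Numeric weights aligned with `feature_names`.
#' @param feature_names All feature names.
#' @param target_features Subset of feature names of interest.
#' @param k Top-list size (default 100).
#' @return List with `top_fraction`, `baseline`, `enrichment`.
#' @export
topk_enrichment <- function(weights, feature_names, target_features, k = 100L) {
  if (length(weights) != length(feature_names))
    stop("weights and feature_names lengths differ")
  ord <- order(-as.numeric(weights), feature_names)
  top <- feature_names[ord[seq_len(k)]]
  top_fraction <- mean(top %in% target_features)
  baseline <- mean(feature_names %in% target_features)
  list(top_fraction = top_fraction, baseline = baseline,
       enrichment = if (baseline > 0) top_fraction / baseline else NA_real_)
}
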