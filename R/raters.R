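# Human-rater panels and human-vs-model comparison statistics.

#' Construct a rater panel
#'
#' @param predictions Character matrix, raters x participants, of predicted
#'   labels (no missing cells).
#' @param expertise Character vector per rater, `"expert"` or `"non_expert"`.
#' @param truth True labels, one per participant.
#' @param rater_ids,participant_ids Optional identifiers.
#' @return Object of class `rater_panel`.
#' @export
rater_panel <- function(predictions, expertise, truth,
                        rater_ids = NULL, participant_ids = NULL) {
  predictions <- as.matrix(predictions)
  if (anyNA(predictions)) stop("predictions must not contain missing cells")
  nr <- nrow(predictions); np <- ncol(predictions)
  if (nr < 1L) stop("need at least one rater")
  expertise <- as.character(expertise)
  if (length(expertise) != nr) stop("expertise must have one entry per rater")
  if (!all(expertise %in% c("expert", "non_expert")))
    stop("expertise entries must be 'expert' or 'non_expert'")
  truth <- as.character(truth)
  if (length(truth) != np) stop("truth must have one entry per participant")
  if (is.null(rater_ids)) rater_ids <- rownames(predictions)
  if (is.null(rater_ids)) rater_ids <- sprintf("r%02d", seq_len(nr))
  if (is.null(participant_ids)) participant_ids <- colnames(predictions)
  if (is.null(participant_ids)) participant_ids <- sprintf("p%02d", seq_len(np))
  dimnames(predictions) <- list(rater_ids, participant_ids)
  structure(list(predictions = predictions, expertise = expertise,
                 truth = truth, rater_ids = rater_ids,
                 participant_ids = participant_ids),
            class = "rater_panel")
}

.correct_matrix <- function(panel) {
  sweep(panel$predictions, 2L, panel$truth, "==") * 1
}

#' @export
print.rater_panel <- function(x, ...) {
  cat(sprintf("rater_panel: %d raters (%d expert, %d non-expert) x %d participants\n",
              length(x$rater_ids), sum(x$expertise == "expert"),
              sum(x$expertise == "non_expert"), length(x$participant_ids)))
  invisible(x)
}

#' Group-level rater accuracy
#'
#' Mean over raters of each rater's fraction of correct predictions, for the
#' whole panel and within each expertise stratum. The all-rater value is the
#' rater-count-weighted mean of the strata.
#'
#' @param panel A [rater_panel()].
#' @return Named list `all`, `expert`, `non_expert` (strata absent from the
#'   panel are `NA`).
#' @export
group_accuracy <- function(panel) {
  stopifnot(inherits(panel, "rater_panel"))
  per_rater <- rowMeans(.correct_matrix(panel))
  stratum <- function(s) {
    v <- per_rater[panel$expertise == s]
    if (length(v)) mean(v) else NA_real_
  }
  list(all = mean(per_rater), expert = stratum("expert"),
       non_expert = stratum("non_expert"))
}

#' Per-participant human accuracy
#'
#' Fraction of raters predicting each participant's diagnosis correctly.
#'
#' @param panel A [rater_panel()].
#' @return Named numeric vector over participants, values in `[0, 1]`.
#' @export
participant_human_accuracy <- function(panel) {
  stopifnot(inherits(panel, "rater_panel"))
  stats::setNames(colMeans(.correct_matrix(panel)), panel$participant_ids)
}

#' Participants mispredicted by most human raters
#'
#' Returns the participants whose per-participant human accuracy is strictly
#' below the threshold (default 0.5, i.e. mispredicted by most raters), sorted
#' by ascending human accuracy, joined with the model's per-participant
#' accuracy and its leave-one-out prediction. Ties at exactly the threshold
#' are excluded.
#'
#' @param panel A [rater_panel()].
#' @param ai_participant_acc Named numeric vector of model per-participant
#'   accuracies (e.g. from [participant_accuracy()]).
#' @param ai_loocv Named character vector of leave-one-out predictions
#'   (e.g. from [loocv_predict()]).
#' @param threshold Human-accuracy cutoff (default 0.5).
#' @return Data frame with columns `participant`, `truth`, `human_accuracy`,
#'   `ai_accuracy`, `ai_prediction`.
#' @export
hard_cases <- function(panel, ai_participant_acc, ai_loocv, threshold = 0.5) {
  stopifnot(inherits(panel, "rater_panel"))
  human <- participant_human_accuracy(panel)
  keep <- which(human < threshold)
  keep <- keep[order(human[keep])]
  data.frame(participant = panel$participant_ids[keep],
             truth = panel$truth[keep],
             human_accuracy = unname(human[keep]),
             ai_accuracy = unname(ai_participant_acc[keep]),
             ai_prediction = unname(ai_loocv[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Human-model agreement correlation
#'
#' Pearson correlation between per-participant human accuracy and model
#' accuracy, optionally after removing the participants that at least a given
#' fraction of raters classified correctly (the easy cases dominating the
#' upper-right of the agreement plot). The exclusion compares the human
#' accuracy fraction to the cutoff with `>=`.
#'
#' @param human_acc,ai_acc Numeric vectors of per-participant accuracies,
#'   equal length.
#' @param exclude_correct_at_least Optional fraction in (0, 1]; participants
#'   with `human_acc >=` this value are removed before correlating (`NULL` =
#'   no exclusion; the study's filter is 0.95).
#' @return Pearson correlation over the retained participants.
#' @export
human_ai_agreement <- function(human_acc, ai_acc,
                               exclude_correct_at_least = NULL) {
  if (length(human_acc) != length(ai_acc))
    stop("accuracy vectors must have equal length")
  keep <- if (is.null(exclude_correct_at_least)) seq_along(human_acc)
          else which(human_acc < exclude_correct_at_least)
  if (length(keep) < 3L)
    stop("fewer than 3 participants remain after exclusion")
  h <- human_acc[keep]; a <- ai_acc[keep]
  if (stats::sd(h) == 0 || stats::sd(a) == 0)
    stop("correlation undefined: an accuracy vector is constant after exclusion")
  stats::cor(h, a)
}
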