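# Plain-text interchange formats: per-participant series, feature tables,
# labels, rater panels. All delimited (tab-separated) with headers.

#' Write a per-participant behavior series file
#'
#' One row per frame, columns `e01..eNN` (expression coefficients) followed
#' by `yaw`, `pitch`, `roll`.
#'
#' @param behavior A [behavior_matrix()] whose last three channels are pose.
#' @param path Output file path.
#' @export
write_series <- function(behavior, path) {
  stopifnot(inherits(behavior, "behavior_matrix"))
  C <- nrow(behavior$values)
  tab <- t(behavior$values)
  colnames(tab) <- c(sprintf("e%02d", seq_len(C - 3L)), "yaw", "pitch", "roll")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-participant behavior series file
#'
#' Expects the format written by [write_series()]: header `e01..eNN, yaw,
#' pitch, roll`. Expression columns are renamed to the default channel
#' descriptors when there are 53 of them (the default basis layout).
#'
#' @param path Input file path.
#' @param frame_rate Frames per second (default 30).
#' @param fill_gaps Linearly interpolate NA frames with [interpolate_gaps()]
#'   (default FALSE; gap-free input is required otherwise).
#' @return A [behavior_matrix()].
#' @export
read_series <- function(path, frame_rate = 30, fill_gaps = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  cn <- colnames(tab)
  if (!all(c("yaw", "pitch", "roll") %in% cn))
    stop("series file must contain yaw, pitch, roll columns")
  tab <- as.matrix(tab)
  if (fill_gaps) tab <- interpolate_gaps(tab)
  ne <- ncol(tab) - 3L
  desc <- if (ne == 53L) default_channel_descriptors()
          else c(cn[seq_len(ne)], "pose_yaw", "pose_pitch", "pose_roll")
  behavior_matrix(t(tab), desc, frame_rate)
}

#' Read a raw per-frame fit file
#'
#' Alternative input format for upstream face-model fits: one row per frame
#' with 9 rotation-matrix entries `r11..r33` (row-major) followed by the
#' global/localized expression coefficients `c01..cNN`. Rotation is converted
#' to yaw/pitch/roll and the nose/cheek coefficients are dropped via the
#' supplied basis.
#'
#' @param path Input file path.
#' @param basis The `localized_basis` the coefficients refer to.
#' @param frame_rate Frames per second (default 30).
#' @return A [behavior_matrix()].
#' @export
read_raw_fits <- function(path, basis, frame_rate = 30) {
  tab <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  ncomp <- length(basis$component_region)
  if (ncol(tab) != 9L + ncomp)
    stop("expected 9 rotation columns + ", ncomp, " coefficient columns")
  angles <- t(apply(tab[, 1:9, drop = FALSE], 1L, function(r) {
    rotation_to_euler(matrix(r, 3L, 3L, byrow = TRUE))
  }))
  expr <- select_expression_channels(tab[, -(1:9), drop = FALSE], basis)
  assemble_behavior(expression_series(expr, basis_channel_names(basis)),
                    pose_series(angles), frame_rate)
}

#' Write / read a cohort feature table
#'
#' One row per participant (row names = ids), one column per feature; the
#' first column holds the diagnosis label.
#'
#' @param features A [cohort_features()].
#' @param dir Output directory; one file per window length
#'   (`features_tw<j>.tsv`).
#' @return Invisibly, the written paths.
#' @export
write_feature_tables <- function(features, dir) {
  stopifnot(inherits(features, "cohort_features"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tw in names(features$tw_tables)) {
    tab <- data.frame(id = features$ids, label = features$labels,
                      features$tw_tables[[tw]], check.names = FALSE)
    p <- file.path(dir, sprintf("features_tw%s.tsv", tw))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_feature_tables
#' @param paths Named character vector of table paths (names = window
#'   lengths).
#' @export
read_feature_tables <- function(paths) {
  if (is.null(names(paths))) stop("paths must be named by window length")
  tabs <- list(); labels <- NULL; ids <- NULL
  for (tw in names(paths)) {
    tab <- utils::read.table(paths[[tw]], header = TRUE, sep = "\t",
                             check.names = FALSE)
    ids <- tab$id; labels <- tab$label
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(m) <- ids
    tabs[[tw]] <- m
  }
  cohort_features(tabs, labels, ids)
}

#' Write / read a rater panel file
#'
#' Tab-separated: columns `rater_id`, `expertise`, then one column per
#' participant holding the predicted label. True labels live in a separate
#' two-column labels file (`id`, `label`).
#'
#' @param panel A [rater_panel()].
#' @param panel_path,labels_path Output paths.
#' @export
write_rater_panel <- function(panel, panel_path, labels_path) {
  stopifnot(inherits(panel, "rater_panel"))
  tab <- data.frame(rater_id = panel$rater_ids, expertise = panel$expertise,
                    panel$predictions, check.names = FALSE)
  utils::write.table(tab, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(id = panel$participant_ids,
                                label = panel$truth),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_rater_panel
#' @export
read_rater_panel <- function(panel_path, labels_path) {
  tab <- utils::read.table(panel_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t")
  preds <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!identical(colnames(preds), as.character(lab$id)))
    stop("participant ids disagree between panel and labels files")
  rater_panel(preds, tab$expertise, lab$label,
              rater_ids = tab$rater_id, participant_ids = lab$id)
}
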