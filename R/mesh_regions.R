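# Facial regions and the localized expression basis.

#' Facial region labels
#'
#' The four mesh regions used throughout the package, in their canonical
#' order: brows/forehead, eyes, nose/cheeks, mouth/chin.
#'
#' @format Character vector of length 4.
#' @export
FACE_REGIONS <- c("brows_forehead", "eyes", "nose_cheeks", "mouth_chin")

# landmark feature label -> mesh region
.FEATURE_REGION <- c(brow = "brows_forehead", eye = "eyes",
                     nose = "nose_cheeks", mouth = "mouth_chin")

#' Construct a face mesh
#'
#' A face mesh is the neutral (identity) geometry of a face: `P` dense 3D
#' points plus a sparse set of annotated landmarks. Landmarks carry a facial
#' feature label (`brow`, `eye`, `nose` or `mouth`) that drives the region
#' partition in [assign_regions()]. The canonical landmark set is the 51-point
#' inner-face annotation (10 brow, 12 eye, 9 nose, 20 mouth points), but any
#' landmark set covering all four features is accepted.
#'
#' @param identity_points Numeric 3 x P matrix of mesh point coordinates
#'   (arbitrary length units).
#' @param landmark_indices Integer vector of distinct indices into the P
#'   points (1-based).
#' @param landmark_feature Character vector, same length, with entries in
#'   `c("brow", "eye", "nose", "mouth")`.
#' @return An object of class `face_mesh`.
#' @export
face_mesh <- function(identity_points, landmark_indices, landmark_feature) {
  identity_points <- as.matrix(identity_points)
  if (nrow(identity_points) != 3L)
    stop("identity_points must be a 3 x P matrix")
  if (!all(is.finite(identity_points)))
    stop("identity_points must be finite")
  P <- ncol(identity_points)
  landmark_indices <- as.integer(landmark_indices)
  if (anyDuplicated(landmark_indices))
    stop("landmark_indices must be distinct")
  if (any(landmark_indices < 1L) || any(landmark_indices > P))
    stop("landmark_indices out of range 1..P")
  landmark_feature <- as.character(landmark_feature)
  if (length(landmark_feature) != length(landmark_indices))
    stop("landmark_feature must match landmark_indices in length")
  bad <- setdiff(unique(landmark_feature), names(.FEATURE_REGION))
  if (length(bad))
    stop("unknown landmark feature label(s): ", paste(bad, collapse = ", "))
  structure(list(identity_points = identity_points,
                 landmark_indices = landmark_indices,
                 landmark_feature = landmark_feature),
            class = "face_mesh")
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("face_mesh: %d points, %d landmarks (%s)\n",
              ncol(x$identity_points), length(x$landmark_indices),
              paste(names(table(x$landmark_feature)), table(x$landmark_feature),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Partition mesh points into facial regions
#'
#' Each mesh point is assigned to the region of the facial feature whose
#' landmark is nearest in Euclidean distance on the neutral geometry:
#' brow landmarks map to `brows_forehead`, eye to `eyes`, nose to
#' `nose_cheeks`, mouth to `mouth_chin`. Distance ties are broken towards the
#' landmark listed first (lowest position in the landmark list), which makes
#' the partition deterministic.
#'
#' @param mesh A [face_mesh()].
#' @return An object of class `region_partition` with element
#'   `region_of_point`, a factor of length P with levels [FACE_REGIONS].
#' @export
assign_regions <- function(mesh) {
  stopifnot(inherits(mesh, "face_mesh"))
  if (length(unique(mesh$landmark_feature)) < 4L)
    stop("cannot partition mesh: landmarks cover fewer than 4 distinct features")
  pts <- mesh$identity_points                       # 3 x P
  lms <- pts[, mesh$landmark_indices, drop = FALSE] # 3 x L
  P <- ncol(pts); L <- ncol(lms)
  # squared Euclidean distances, P x L
  d2 <- matrix(colSums(pts^2), P, L) +
    matrix(colSums(lms^2), P, L, byrow = TRUE) -
    2 * crossprod(pts, lms)
  nearest <- max.col(-d2, ties.method = "first")
  region <- unname(.FEATURE_REGION[mesh$landmark_feature[nearest]])
  structure(list(region_of_point = factor(region, levels = FACE_REGIONS)),
            class = "region_partition")
}

.default_region_counts <- function() {
  c(brows_forehead = 19L, eyes = 20L, nose_cheeks = 7L, mouth_chin = 14L)
}

# row indices (into the 3P-long stacked coordinate vector) of a point set
.point_rows <- function(points) {
  as.vector(rbind(3L * points - 2L, 3L * points - 1L, 3L * points))
}

#' Build a region-localized expression basis
#'
#' Takes a global (PCA-style) expression basis over the full mesh and turns it
#' into a localized basis: for each region, the global components are masked
#' (coordinates of points outside the region are zeroed), the masked columns
#' are orthonormalized by QR, and the first `region_counts[r]` components are
#' retained. Components of different regions have disjoint support and are
#' therefore mutually orthogonal; within a region they are orthonormal, so the
#' full basis has orthonormal columns.
#'
#' The default component counts are 19 (brows/forehead), 20 (eyes),
#' 7 (nose/cheeks) and 14 (mouth/chin), totalling 60.
#'
#' @param global Numeric 3P x K matrix of global basis components, or a list
#'   with element `components`.
#' @param partition A `region_partition` from [assign_regions()].
#' @param region_counts Named integer vector over [FACE_REGIONS] summing
#'   to the desired number of components (default 60).
#' @return An object of class `localized_basis` with elements `components`
#'   (3P x sum(region_counts), unit-norm columns), `component_region`
#'   (factor), and `region_counts`.
#' @export
build_localized_basis <- function(global, partition,
                                  region_counts = .default_region_counts()) {
  if (is.list(global) && !is.null(global$components)) global <- global$components
  global <- as.matrix(global)
  stopifnot(inherits(partition, "region_partition"))
  region <- partition$region_of_point
  P <- length(region)
  if (nrow(global) != 3L * P)
    stop("global basis has ", nrow(global), " rows; expected 3P = ", 3L * P)
  if (!all(FACE_REGIONS %in% names(region_counts)))
    stop("region_counts must name all four regions")
  region_counts <- as.integer(region_counts[FACE_REGIONS])
  names(region_counts) <- FACE_REGIONS
  K <- ncol(global)
  if (K < max(region_counts))
    stop("global basis has too few components (K = ", K, ")")
  ncomp <- sum(region_counts)

  comps <- matrix(0, nrow(global), ncomp)
  labels <- character(ncomp)
  at <- 0L
  for (r in FACE_REGIONS) {
    cnt <- region_counts[[r]]
    if (cnt == 0L) next
    rows <- .point_rows(which(region == r))
    if (length(rows) == 0L)
      stop("region ", r, " has no mesh points; cannot localize")
    masked <- matrix(0, nrow(global), K)
    masked[rows, ] <- global[rows, , drop = FALSE]
    dec <- qr(masked)
    if (dec$rank < cnt)
      stop("deficient region ", r, ": masked components have rank ",
           dec$rank, " < requested ", cnt)
    Q <- qr.Q(dec)[, seq_len(cnt), drop = FALSE]
    # enforce exact support on the region and exact unit norms
    Q[-rows, ] <- 0
    Q <- sweep(Q, 2L, sqrt(colSums(Q^2)), "/")
    comps[, at + seq_len(cnt)] <- Q
    labels[at + seq_len(cnt)] <- r
    at <- at + cnt
  }
  structure(list(components = comps,
                 component_region = factor(labels, levels = FACE_REGIONS),
                 region_counts = region_counts),
            class = "localized_basis")
}

#' @export
print.localized_basis <- function(x, ...) {
  cat(sprintf("localized_basis: %d components over %d mesh points (%s)\n",
              ncol(x$components), nrow(x$components) / 3,
              paste(names(x$region_counts), x$region_counts,
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Project a per-frame deformation onto the localized basis
#'
#' Returns the coefficient vector minimizing the Euclidean norm of the
#' residual between the (flattened) deformation field and its reconstruction
#' from the localized basis. Because the basis columns are orthonormal the
#' least-squares minimizer is the plain inner-product projection.
#'
#' @param deformation Numeric 3 x P deformation matrix (per-point offsets
#'   from the neutral face), or its flattened length-3P vector, or a T x 3P
#'   matrix of stacked frames (one frame per row).
#' @param basis A `localized_basis`.
#' @return Coefficient vector of length `ncol(basis$components)`, or a matrix
#'   with one coefficient row per frame when given stacked frames.
#' @export
project_expression <- function(deformation, basis) {
  stopifnot(inherits(basis, "localized_basis"))
  W <- basis$components
  n3p <- nrow(W)
  if (is.matrix(deformation) && nrow(deformation) == 3L &&
      3L * ncol(deformation) == n3p) {
    v <- as.vector(deformation)
  } else if (is.matrix(deformation) && ncol(deformation) == n3p) {
    v <- t(deformation)   # frames in columns
  } else if (length(deformation) == n3p) {
    v <- as.numeric(deformation)
  } else {
    stop("deformation does not match basis dimension 3P = ", n3p)
  }
  if (!all(is.finite(v))) stop("deformation contains non-finite entries")
  out <- crossprod(W, v)
  if (is.matrix(out) && ncol(out) > 1L) t(out) else drop(out)
}

#' Drop nose/cheek components from a coefficient vector
#'
#' Removes the coefficients of the components labeled `nose_cheeks`,
#' preserving the order of the remaining components. With the default region
#' counts this keeps 53 of the 60 coefficients.
#'
#' @param coeffs Coefficient vector (length = number of components) or a
#'   T x ncomp matrix of per-frame coefficients.
#' @param basis The `localized_basis` the coefficients refer to.
#' @return Vector/matrix with the nose/cheek columns removed.
#' @export
select_expression_channels <- function(coeffs, basis) {
  stopifnot(inherits(basis, "localized_basis"))
  keep <- which(basis$component_region != "nose_cheeks")
  if (is.matrix(coeffs)) {
    if (ncol(coeffs) != length(basis$component_region))
      stop("coeffs has ", ncol(coeffs), " columns; expected ",
           length(basis$component_region))
    coeffs[, keep, drop = FALSE]
  } else {
    if (length(coeffs) != length(basis$component_region))
      stop("coeffs has length ", length(coeffs), "; expected ",
           length(basis$component_region))
    coeffs[keep]
  }
}

#' Channel names of the retained expression components
#'
#' Names the non-nose components by facial category and within-region index
#' (`brow_01`, ..., `eye_01`, ..., `mouth_01`, ...), the naming used for the
#' rows of the behavior matrix and hence inside feature names.
#'
#' @param basis A `localized_basis`.
#' @return Character vector, one name per retained (non-nose) component.
#' @export
basis_channel_names <- function(basis) {
  stopifnot(inherits(basis, "localized_basis"))
  short <- c(brows_forehead = "brow", eyes = "eye",
             nose_cheeks = "nose", mouth_chin = "mouth")
  reg <- as.character(basis$component_region)
  keep <- reg != "nose_cheeks"
  reg <- reg[keep]
  idx <- stats::ave(seq_along(reg), reg, FUN = seq_along)
  sprintf("%s_%02d", short[reg], idx)
}
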