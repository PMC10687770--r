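test_that("face_mesh validates its invariants", {
  pts <- matrix(rnorm(3 * 60), 3, 60)
  expect_s3_class(face_mesh(pts, 1:51, rep(c("brow", "eye", "nose", "mouth"),
                                           times = c(10, 12, 9, 20))),
                  "face_mesh")
  expect_error(face_mesh(pts[1:2, ], 1:4, rep("brow", 4)), "3 x P")
  expect_error(face_mesh(pts, c(1, 1, 2, 3), rep("eye", 4)), "distinct")
  expect_error(face_mesh(pts, c(1, 2, 3, 99), rep("eye", 4)), "range")
  expect_error(face_mesh(pts, 1:4, c("brow", "eye", "nose", "ear")),
               "unknown landmark feature")
})

test_that("assign_regions labels a point coincident with a landmark", {
  set.seed(3)
  mesh <- gen_mesh(P = 80, seed = 3)
  eye_lm <- mesh$landmark_indices[mesh$landmark_feature == "eye"][1]
  # append a point exactly on that eye landmark
  pts <- cbind(mesh$identity_points, mesh$identity_points[, eye_lm])
  mesh2 <- face_mesh(pts, mesh$landmark_indices, mesh$landmark_feature)
  part <- assign_regions(mesh2)
  expect_equal(as.character(part$region_of_point[ncol(pts)]), "eyes")
})

test_that("assign_regions matches an exhaustive nearest-landmark scan", {
  mesh <- gen_mesh(P = 200, seed = 7)
  part <- assign_regions(mesh)
  expect_length(part$region_of_point, 200)          # partition totality
  expect_true(all(table(part$region_of_point) > 0)) # four nonempty regions

  # brute-force oracle: loop over points and landmarks
  region_of <- c(brow = "brows_forehead", eye = "eyes",
                 nose = "nose_cheeks", mouth = "mouth_chin")
  pts <- mesh$identity_points
  lms <- pts[, mesh$landmark_indices]
  expected <- character(ncol(pts))
  for (p in seq_len(ncol(pts))) {
    d <- apply(lms, 2, function(l) sqrt(sum((pts[, p] - l)^2)))
    expected[p] <- region_of[[mesh$landmark_feature[which.min(d)]]]
  }
  expect_identical(as.character(part$region_of_point), expected)
})

test_that("assign_regions is invariant to rigid rotation of the mesh", {
  mesh <- gen_mesh(P = 150, seed = 5)
  set.seed(8)
  R <- random_rotation()
  rotated <- face_mesh(R %*% mesh$identity_points, mesh$landmark_indices,
                       mesh$landmark_feature)
  expect_identical(assign_regions(mesh)$region_of_point,
                   assign_regions(rotated)$region_of_point)
})

test_that("assign_regions rejects meshes missing a feature", {
  pts <- matrix(rnorm(3 * 30), 3, 30)
  mesh <- face_mesh(pts, 1:9, rep(c("brow", "eye", "nose"), each = 3))
  expect_error(assign_regions(mesh), "fewer than 4")
})

test_that("build_localized_basis reproduces the documented structure", {
  mesh <- gen_mesh(P = 120, seed = 2)
  part <- assign_regions(mesh)
  glob <- gen_global_basis(mesh, K = 60, seed = 2)
  basis <- build_localized_basis(glob, part)

  expect_equal(ncol(basis$components), 60)
  expect_equal(sum(basis$component_region == "nose_cheeks"), 7)
  expect_equal(unname(basis$region_counts),
               c(19L, 20L, 7L, 14L))

  # zero support outside each component's region
  for (r in FACE_REGIONS) {
    outside <- facesync:::.point_rows(which(part$region_of_point != r))
    cols <- which(basis$component_region == r)
    expect_equal(max(abs(basis$components[outside, cols])), 0)
  }

  # per-region Gram matrices are the identity; cross-region blocks vanish
  G <- crossprod(basis$components)
  expect_lt(max(abs(G - diag(60))), 1e-8)
})

test_that("build_localized_basis accepts custom counts and flags deficiency", {
  mesh <- gen_mesh(P = 100, seed = 4)
  part <- assign_regions(mesh)
  glob <- gen_global_basis(mesh, K = 40, seed = 4)

  counts <- c(brows_forehead = 5L, eyes = 6L, nose_cheeks = 0L,
              mouth_chin = 4L)
  b <- build_localized_basis(glob, part, counts)
  expect_equal(ncol(b$components), 15)
  expect_equal(sum(b$component_region == "nose_cheeks"), 0)

  # rank-deficient region: global basis with duplicated columns
  dup <- glob$components[, c(1:10, 1:10, 1:10, 1:10)]
  expect_error(build_localized_basis(dup, part), "deficient region")
  expect_error(build_localized_basis(glob$components[, 1:10], part),
               "too few components")
})

test_that("project_expression is the least-squares minimizer", {
  mesh <- gen_mesh(P = 90, seed = 9)
  part <- assign_regions(mesh)
  basis <- build_localized_basis(gen_global_basis(mesh, K = 60, seed = 9),
                                 part)
  W <- basis$components
  P <- ncol(mesh$identity_points)

  # zero deformation -> zero coefficients
  expect_equal(project_expression(matrix(0, 3, P), basis), rep(0, 60))

  # exact representability: W %*% e recovers e
  set.seed(10)
  e <- rnorm(60)
  dx <- matrix(W %*% e, 3, P)
  expect_equal(project_expression(dx, basis), e, tolerance = 1e-8)

  # random deformation matches the normal-equations oracle
  dx <- matrix(rnorm(3 * P), 3, P)
  oracle <- solve(crossprod(W), crossprod(W, as.vector(dx)))
  expect_equal(project_expression(dx, basis), drop(oracle), tolerance = 1e-8)

  dx[1, 1] <- NA
  expect_error(project_expression(dx, basis), "non-finite")
})

test_that("projection residual shrinks as components are added", {
  mesh <- gen_mesh(P = 80, seed = 12)
  part <- assign_regions(mesh)
  glob <- gen_global_basis(mesh, K = 30, seed = 12)
  small <- build_localized_basis(glob, part,
    c(brows_forehead = 4L, eyes = 4L, nose_cheeks = 2L, mouth_chin = 3L))
  large <- build_localized_basis(glob, part,
    c(brows_forehead = 8L, eyes = 8L, nose_cheeks = 4L, mouth_chin = 6L))
  set.seed(13)
  dx <- rnorm(3 * 80)
  resid <- function(b) {
    e <- project_expression(dx, b)
    sqrt(sum((dx - b$components %*% e)^2))
  }
  # the first k components per region are nested by construction (same QR)
  expect_lte(resid(large), resid(small) + 1e-12)
})

test_that("select_expression_channels drops exactly the nose components", {
  mesh <- gen_mesh(P = 110, seed = 6)
  part <- assign_regions(mesh)
  basis <- build_localized_basis(gen_global_basis(mesh, K = 60, seed = 6),
                                 part)
  coeffs <- seq_len(60)
  kept <- select_expression_channels(coeffs, basis)
  expect_length(kept, 53)
  expect_identical(setdiff(coeffs, kept),
                   which(basis$component_region == "nose_cheeks"))

  # matrix input: one row per frame
  mat <- rbind(coeffs, coeffs + 100)
  expect_equal(dim(select_expression_channels(mat, basis)), c(2L, 53L))

  # zero nose components requested -> identity pass-through
  b0 <- build_localized_basis(gen_global_basis(mesh, K = 60, seed = 6), part,
    c(brows_forehead = 19L, eyes = 20L, nose_cheeks = 0L, mouth_chin = 21L))
  expect_identical(select_expression_channels(seq_len(60), b0), seq_len(60))

  expect_error(select_expression_channels(1:10, basis), "length")
})

test_that("basis channel names follow region order and counts", {
  mesh <- gen_mesh(P = 100, seed = 14)
  basis <- build_localized_basis(gen_global_basis(mesh, K = 60, seed = 14),
                                 assign_regions(mesh))
  nm <- basis_channel_names(basis)
  expect_length(nm, 53)
  expect_identical(nm, default_channel_descriptors()[1:53])
})
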