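# Synthetic data: meshes, lag-coupled behavior cohorts, and rater panels.
#
# The generator emulates the data shape of the study the package targets:
# 3-minute recordings at 30 fps (T = 5400 frames), 56 behavior channels
# (53 expression + 3 pose), a cohort of 15 + 27 participants, and a panel of
# 8 expert + 11 non-expert raters. Group structure is planted as additive
# lagged linear coupling between channel pairs whose strength depends on the
# diagnostic group.

#' Default planted channel couplings
#'
#' A deterministic list of 20 ordered (source, target, lag) couplings:
#' sources are channels 1..20, targets 31..50, lag 3 frames (0.1 s at
#' 30 fps — within the default forward-lag search range of every candidate
#' window length).
#'
#' @param n_pairs Number of couplings (default 20).
#' @param lag Lag in frames (default 3).
#' @return Data frame with columns `source`, `target`, `lag`.
#' @export
default_coupled_pairs <- function(n_pairs = 20L, lag = 3L) {
  if (n_pairs > 20L) stop("default layout supports at most 20 pairs")
  data.frame(source = seq_len(n_pairs), target = 30L + seq_len(n_pairs),
             lag = as.integer(lag))
}

#' Specification of a synthetic behavior cohort
#'
#' Each channel is an AR(1) process `x[t] = phi * x[t-1] + eta[t]` with
#' Gaussian innovations; each coupled target channel additionally receives
#' `beta_g * source[t - lag]` inside the recursion, where `beta_g` is the
#' participant's group coupling strength. All randomness flows from `seed`
#' via per-participant substreams (`seed + 7919 * participant`), so cohorts
#' are reproducible piecewise.
#'
#' @param n_asd,n_nt Group sizes (defaults 15 and 27).
#' @param n_frames Frames per recording (default 5400 = 3 min at 30 fps).
#' @param frame_rate Frames per second (default 30).
#' @param n_channels Number of behavior channels (default 56).
#' @param ar_coefficient AR(1) coefficient phi in [0, 1) (default 0.6).
#' @param coupled_pairs Data frame `source`, `target`, `lag`
#'   (default [default_coupled_pairs()]).
#' @param coupling_strength Named vector `c(asd = , nt = )` of coupling
#'   strengths (defaults 0.9 and 0).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param seed Integer seed (default 1).
#' @param burn_in Discarded leading frames (default 200).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 15L, n_nt = 27L, n_frames = 5400L,
                        frame_rate = 30, n_channels = 56L,
                        ar_coefficient = 0.6,
                        coupled_pairs = default_coupled_pairs(),
                        coupling_strength = c(asd = 0.9, nt = 0),
                        noise_sd = 1, seed = 1L, burn_in = 200L) {
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  if (!all(c("asd", "nt") %in% names(coupling_strength)))
    stop("coupling_strength must name 'asd' and 'nt'")
  if (!all(is.finite(coupling_strength))) stop("coupling strengths must be finite")
  cp <- coupled_pairs
  if (nrow(cp)) {
    if (any(cp$lag < 1L)) stop("coupling lags must be >= 1")
    if (any(cp$lag >= n_frames)) stop("coupling lag must be smaller than n_frames")
    chans <- c(cp$source, cp$target)
    if (any(chans < 1L) || any(chans > n_channels))
      stop("coupled channels out of range 1..", n_channels)
    if (anyDuplicated(cp$target))
      stop("each channel may be the target of at most one coupling")
  }
  structure(list(n_asd = as.integer(n_asd), n_nt = as.integer(n_nt),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 n_channels = as.integer(n_channels),
                 ar_coefficient = ar_coefficient, coupled_pairs = cp,
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 seed = as.integer(seed), burn_in = as.integer(burn_in)),
            class = "cohort_spec")
}

# topological generation order: plain channels first, then targets whose
# sources are ready; errors on cyclic coupling chains
.generation_order <- function(spec) {
  cp <- spec$coupled_pairs
  targets <- cp$target
  plain <- setdiff(seq_len(spec$n_channels), targets)
  done <- plain
  pending <- targets
  order_t <- integer(0)
  while (length(pending)) {
    ready <- pending[cp$source[match(pending, cp$target)] %in% done]
    if (!length(ready)) stop("cyclic coupling between channels; cannot generate")
    order_t <- c(order_t, ready)
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  list(plain = plain, targets = order_t)
}

#' Generate a synthetic behavior cohort
#'
#' Draws one behavior matrix per participant under a [cohort_spec()]:
#' ASD-labelled participants use `coupling_strength["asd"]`, NT participants
#' `coupling_strength["nt"]`. The planted ground truth travels with the
#' result. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `behavior_cohort`: `participants` (list of
#'   `list(id, behavior, label)`), `labels`, and `ground_truth`
#'   (coupled pairs, strengths, per-participant seeds).
#' @export
gen_behavior_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("ASD", spec$n_asd), rep("NT", spec$n_nt))
  n <- length(labels)
  ord <- .generation_order(spec)
  cp <- spec$coupled_pairs
  Ttot <- spec$n_frames + spec$burn_in
  desc <- if (spec$n_channels == 56L) default_channel_descriptors()
          else sprintf("ch_%02d", seq_len(spec$n_channels))
  seeds <- spec$seed + 7919L * seq_len(n)

  participants <- vector("list", n)
  for (p in seq_len(n)) {
    set.seed(seeds[p])
    beta <- unname(spec$coupling_strength[if (labels[p] == "ASD") "asd" else "nt"])
    eta <- matrix(stats::rnorm(spec$n_channels * Ttot, 0, spec$noise_sd),
                  spec$n_channels, Ttot)
    X <- matrix(0, spec$n_channels, Ttot)
    for (c in ord$plain)
      X[c, ] <- as.numeric(stats::filter(eta[c, ], spec$ar_coefficient,
                                         method = "recursive"))
    for (tch in ord$targets) {
      row <- cp[cp$target == tch, ]
      lagged <- c(rep(0, row$lag), X[row$source, seq_len(Ttot - row$lag)])
      X[tch, ] <- as.numeric(stats::filter(eta[tch, ] + beta * lagged,
                                           spec$ar_coefficient,
                                           method = "recursive"))
    }
    Y <- X[, (spec$burn_in + 1L):Ttot, drop = FALSE]
    participants[[p]] <- list(id = sprintf("p%02d", p),
                              behavior = behavior_matrix(Y, desc,
                                                         spec$frame_rate),
                              label = labels[p])
  }
  structure(list(participants = participants, labels = labels,
                 ground_truth = list(coupled_pairs = cp,
                                     coupling_strength = spec$coupling_strength,
                                     channel_descriptors = desc,
                                     seeds = seeds)),
            class = "behavior_cohort")
}

#' @export
print.behavior_cohort <- function(x, ...) {
  cat(sprintf("behavior_cohort: %d participants (%s)\n",
              length(x$participants),
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Feature names of the planted couplings
#'
#' The mu and sigma features of the ordered (source -> target) coupled pairs
#' of a synthetic cohort — the features the planted group difference should
#' surface in.
#'
#' @param cohort A `behavior_cohort`.
#' @return Character vector of feature names (2 per coupled pair).
#' @export
planted_feature_names <- function(cohort) {
  gt <- cohort$ground_truth
  src <- gt$channel_descriptors[gt$coupled_pairs$source]
  tgt <- gt$channel_descriptors[gt$coupled_pairs$target]
  c(sprintf("mu(%s->%s)", src, tgt), sprintf("sigma(%s->%s)", src, tgt))
}

#' Generate a synthetic face mesh
#'
#' An ellipsoidal face-like point cloud with 51 designated landmarks in four
#' anatomically arranged bands (10 brow, 12 eye, 9 nose, 20 mouth — the
#' standard inner-face annotation counts). The landmarks are the first 51
#' points; the remaining points are scattered over the facial dome.
#' Deterministic per seed. This is a synthetic stand-in for a real dense
#' face-model mesh.
#'
#' @param P Total number of mesh points (default 200, minimum 51).
#' @param seed Integer seed (default 1).
#' @return A [face_mesh()].
#' @export
gen_mesh <- function(P = 200L, seed = 1L) {
  if (P < 51L) stop("need at least 51 points")
  set.seed(seed)
  arc <- function(x0, x1, y, z, n)
    cbind(seq(x0, x1, length.out = n), rep(y, n), rep(z, n))
  ring <- function(cx, cy, rx, ry, z, n) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    cbind(cx + rx * cos(th), cy + ry * sin(th), rep(z, n))
  }
  lm <- rbind(
    arc(-0.60, -0.15, 0.50, 0.45, 5), arc(0.15, 0.60, 0.50, 0.45, 5),  # brows
    ring(-0.35, 0.25, 0.13, 0.07, 0.40, 6), ring(0.35, 0.25, 0.13, 0.07, 0.40, 6),
    cbind(rep(0, 4), seq(0.25, -0.02, length.out = 4),
          seq(0.60, 0.75, length.out = 4)),                            # nose bridge
    arc(-0.20, 0.20, -0.12, 0.60, 5),                                  # nose base
    ring(0, -0.50, 0.30, 0.13, 0.45, 12), ring(0, -0.50, 0.17, 0.06, 0.45, 8))
  lm <- lm + matrix(stats::rnorm(nrow(lm) * 3L, 0, 0.01), nrow(lm), 3L)
  feature <- rep(c("brow", "eye", "nose", "mouth"), times = c(10L, 12L, 9L, 20L))
  extra <- P - 51L
  pts <- lm
  if (extra > 0L) {
    x <- stats::runif(extra, -0.85, 0.85)
    y <- stats::runif(extra, -0.95, 0.85)
    z <- 0.8 * sqrt(pmax(1 - (x / 0.95)^2 - (y / 1.1)^2, 0)) +
      stats::rnorm(extra, 0, 0.01)
    pts <- rbind(lm, cbind(x, y, z))
  }
  face_mesh(t(pts), seq_len(51L), feature)
}

#' Generate a synthetic global expression basis
#'
#' A random orthonormal 3P x K basis standing in for a PCA expression model
#' over the mesh — raw material for [build_localized_basis()]. Synthetic:
#' it carries no anatomical deformation structure.
#'
#' @param mesh A [face_mesh()].
#' @param K Number of global components (default 60).
#' @param seed Integer seed (default 1).
#' @return List with element `components` (3P x K, orthonormal columns).
#' @export
gen_global_basis <- function(mesh, K = 60L, seed = 1L) {
  stopifnot(inherits(mesh, "face_mesh"))
  set.seed(seed)
  n <- 3L * ncol(mesh$identity_points)
  M <- matrix(stats::rnorm(n * K), n, K)
  list(components = qr.Q(qr(M)), K = K)
}

#' Specification of a synthetic rater panel
#'
#' Raters draw a latent skill per stratum and participants a latent
#' difficulty; a rater predicts a participant correctly with probability
#' `plogis(skill + difficulty)`. Defaults (8 experts at mean skill 1.7,
#' 11 non-experts at 1.2, skill sd 0.4, difficulty mean 0.5, sd 1.5) put the
#' panel accuracy near 0.8 with a realistic spread of hard cases.
#'
#' @param n_experts,n_nonexperts Stratum sizes (defaults 8 and 11).
#' @param skill_mean Named vector `c(expert = , non_expert = )` of mean
#'   skills on the logit scale.
#' @param skill_sd Skill standard deviation (default 0.4).
#' @param difficulty_mean,difficulty_sd Participant-difficulty distribution
#'   on the logit scale (defaults 0.5 and 1.5; higher = easier).
#' @param seed Integer seed (default 1).
#' @return Object of class `rater_spec`.
#' @export
rater_spec <- function(n_experts = 8L, n_nonexperts = 11L,
                       skill_mean = c(expert = 1.7, non_expert = 1.2),
                       skill_sd = 0.4, difficulty_mean = 0.5,
                       difficulty_sd = 1.5, seed = 1L) {
  if (!all(c("expert", "non_expert") %in% names(skill_mean)))
    stop("skill_mean must name 'expert' and 'non_expert'")
  structure(list(n_experts = as.integer(n_experts),
                 n_nonexperts = as.integer(n_nonexperts),
                 skill_mean = skill_mean, skill_sd = skill_sd,
                 difficulty_mean = difficulty_mean,
                 difficulty_sd = difficulty_sd, seed = as.integer(seed)),
            class = "rater_spec")
}

#' Generate a synthetic rater panel
#'
#' Draws skills, difficulties and per-cell Bernoulli outcomes under a
#' [rater_spec()]; a correct draw reproduces the participant's true label, an
#' incorrect draw flips it. Deterministic per seed.
#'
#' @param rspec A [rater_spec()].
#' @param truth True labels, one per participant (two classes).
#' @return A [rater_panel()], with the latent skills and difficulties
#'   attached as attribute `latent`.
#' @export
gen_rater_panel <- function(rspec, truth) {
  stopifnot(inherits(rspec, "rater_spec"))
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (length(classes) != 2L) stop("truth must contain exactly two classes")
  set.seed(rspec$seed)
  nr <- rspec$n_experts + rspec$n_nonexperts
  np <- length(truth)
  expertise <- rep(c("expert", "non_expert"),
                   times = c(rspec$n_experts, rspec$n_nonexperts))
  skill <- stats::rnorm(nr, rspec$skill_mean[expertise], rspec$skill_sd)
  difficulty <- stats::rnorm(np, rspec$difficulty_mean, rspec$difficulty_sd)
  p_correct <- stats::plogis(outer(skill, difficulty, "+"))
  correct <- matrix(stats::runif(nr * np), nr, np) < p_correct
  flip <- stats::setNames(rev(classes), classes)
  predictions <- matrix(truth[col(correct)], nr, np)
  predictions[!correct] <- flip[predictions[!correct]]
  panel <- rater_panel(predictions, expertise, truth)
  attr(panel, "latent") <- list(skill = skill, difficulty = difficulty)
  panel
}
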