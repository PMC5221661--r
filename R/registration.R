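# Mirror-and-register: align the reflected right-side pattern onto the left.
#
# The manual protocol this automates anchors the overlay on canal neuromasts
# ("place markers"), nudges the overlay toward maximal visual coincidence, and
# repeats the whole alignment three times, averaging the scores. Here:
# closed-form landmark Procrustes on canal points, score-maximizing local
# refinement, and seeded jittered restarts standing in for inter-attempt
# operator variability.

#' Registration configuration
#'
#' @param allow_scale Permit a uniform scale in the landmark fit? Default
#'   FALSE: left and right images of one specimen at one magnification are
#'   rigidly related.
#' @param refine Run score-maximizing refinement after the landmark fit?
#'   Default TRUE.
#' @param jitter_sigma SD of the per-trial initialization perturbation, in
#'   pixels (translation) and degrees (rotation). Default 2: emulates the
#'   spread between independent manual alignment attempts.
#' @param n_trials Number of technical replicates averaged per individual,
#'   default 3.
#' @param seed Integer seed; mandatory for reproducibility of the jittered
#'   trials.
#' @param axis Mirror axis handed to [reflect_pattern()]. Default
#'   `"vertical_line"` (left-right mirror): overlaying contralateral lateral
#'   views requires a horizontal flip of the image content. The literal
#'   top-bottom reading is selectable.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(allow_scale = FALSE, refine = TRUE,
                                jitter_sigma = 2, n_trials = 3, seed = 1L,
                                axis = c("vertical_line", "horizontal_line")) {
  axis <- match.arg(axis)
  stopifnot(n_trials >= 1, jitter_sigma >= 0, is.logical(allow_scale),
            is.logical(refine))
  structure(list(allow_scale = allow_scale, refine = refine,
                 jitter_sigma = as.numeric(jitter_sigma),
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed), axis = axis),
            class = "registration_config")
}

#' Closed-form least-squares landmark fit (Kabsch/Procrustes)
#'
#' Finds the rigid (or, with `allow_scale`, similarity) transform minimizing
#' the summed squared distances between corresponding landmarks: centroid
#' alignment plus SVD of the cross-covariance, with the determinant corrected
#' so no extra reflection can be introduced.
#'
#' @param moving,fixed [point_pattern()]s in the same frame (the moving
#'   pattern is the already-reflected right side).
#' @param correspondence A 2-column matrix of 1-based point indices,
#'   `(moving_index, fixed_index)`; at least 2 rows (3 or more recommended).
#' @param allow_scale Estimate a uniform scale? Default FALSE.
#' @return A list with `transform` ([rigid_transform()], origin-centred) and
#'   `rms` (root-mean-square landmark residual in px).
#' @export
landmark_fit <- function(moving, fixed, correspondence, allow_scale = FALSE) {
  cp <- as.matrix(correspondence)
  if (nrow(cp) < 2L) stop("at least 2 correspondence pairs are required")
  M <- pattern_xy(moving)[cp[, 1], , drop = FALSE]
  F <- pattern_xy(fixed)[cp[, 2], , drop = FALSE]
  mM <- colMeans(M); mF <- colMeans(F)
  Mc <- sweep(M, 2, mM); Fc <- sweep(F, 2, mF)
  H <- t(Mc) %*% Fc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    denom <- sum(Mc^2)
    if (denom <= 0) stop("degenerate landmarks: zero spread in moving set")
    s <- sum(diag(D) * sv$d) / denom
    if (s <= 0) stop("degenerate landmarks: non-positive scale estimate")
    if (abs(det(H)) < 1e-12 * sum(Mc^2) * max(sum(Fc^2), 1))
      warning("collinear landmarks: rotation may be ill-conditioned")
  }
  theta <- atan2(R[2, 1], R[1, 1])
  tv <- mF - s * (R %*% mM)
  tr <- rigid_transform(FALSE, theta, tv[1], tv[2], s)
  res <- transform_xy(M, tr) - F
  list(transform = tr, rms = sqrt(mean(rowSums(res^2))))
}

# Auto-pair canal landmarks by rank order along the anteroposterior (x) axis.
# Used when no correspondence file is given; requires equal canal counts.
auto_canal_pairs <- function(fixed, moving) {
  fi <- which(fixed$type == "canal")
  mi <- which(moving$type == "canal")
  if (length(fi) < 2L || length(mi) < 2L)
    stop("at least 2 canal landmarks per side are required")
  if (length(fi) != length(mi))
    stop("canal counts differ between sides; supply an explicit correspondence")
  cbind(moving = mi[order(moving$x[mi])], fixed = fi[order(fixed$x[fi])])
}

#' Score-maximizing local refinement of a registration
#'
#' Emulates the human "nudge toward best visual overlap". Two phases, both
#' accepting a candidate only if the score does not decrease (so the returned
#' transform always scores at least as well as `init`):
#'
#' 1. ICP-style polish: match each transformed moving point to its nearest
#'    fixed point, closed-form Procrustes refit on those correspondences,
#'    iterate while the score improves. Needed because the raster score is
#'    piecewise constant, so grid descent alone cannot land on the exact
#'    optimum.
#' 2. Coordinate descent over (rotation about the moving centroid, tx, ty) on
#'    a coarse-to-fine grid, halving steps until below 0.25 px and 0.25
#'    degrees.
#'
#' The search is a trust-region local search: candidates deviating from
#' `anchor` (default `init`) by more than `max_shift` px at the moving
#' centroid or `max_rot` degrees are rejected. In pipeline use the anchor is
#' the canal-landmark fit — the manual protocol uses canal neuromasts as
#' place markers and only nudges the overlay locally around them, so an
#' unbounded overlap maximization would both misrepresent the protocol and
#' inflate scores of truly asymmetric patterns by overfitting the alignment.
#'
#' @param moving,fixed [point_pattern()]s (all point types participate in the
#'   ICP matching; the scorer decides what it scores).
#' @param init Initial [rigid_transform()] (origin-centred).
#' @param scorer Function mapping a transform to a finite real score (larger
#'   is better), e.g. the colocalization R.
#' @param allow_scale Allow the ICP refits to estimate scale? Default FALSE.
#' @param anchor Trust-region centre, a [rigid_transform()]; default `init`.
#' @param max_shift,max_rot Trust-region radii (px at the moving centroid /
#'   degrees), default unbounded.
#' @return A list with `transform`, `score`, and `n_eval`.
#' @export
refine_by_score <- function(moving, fixed, init, scorer, allow_scale = FALSE,
                            anchor = init, max_shift = Inf, max_rot = Inf) {
  best <- init
  best_score <- scorer(init)
  if (!is.finite(best_score)) stop("scorer returned a non-finite value")
  n_eval <- 1L
  mxy <- pattern_xy(moving)
  fxy <- pattern_xy(fixed)
  centroid <- colMeans(mxy)
  in_trust <- function(t) {
    d <- compose_transforms(t, inverse_transform(anchor))
    rot_ok <- abs(d$theta) <= max_rot * pi / 180 + 1e-12
    at <- transform_xy(matrix(centroid, 1), t)
    aa <- transform_xy(matrix(centroid, 1), anchor)
    rot_ok && sqrt(sum((at - aa)^2)) <= max_shift + 1e-9
  }

  # Phase 1: ICP polish, score-gated.
  for (iter in seq_len(10L)) {
    cur <- transform_xy(mxy, best)
    nn <- vapply(seq_len(nrow(cur)), function(i) {
      which.min((fxy[, 1] - cur[i, 1])^2 + (fxy[, 2] - cur[i, 2])^2)
    }, integer(1))
    cand <- tryCatch(
      landmark_fit(moving, fixed, cbind(seq_len(nrow(mxy)), nn), allow_scale)$transform,
      error = function(e) NULL)
    if (is.null(cand) || !in_trust(cand)) break
    sc <- scorer(cand); n_eval <- n_eval + 1L
    if (is.finite(sc) && sc >= best_score) {
      improved <- sc > best_score
      same <- isTRUE(all.equal(unclass(cand), unclass(best), tolerance = 1e-12))
      best <- cand; best_score <- sc
      if (!improved || same) break
    } else break
  }

  # Phase 2: coarse-to-fine coordinate descent about the moving centroid.
  step_t <- 4; step_a <- 4 * pi / 180
  min_t <- 0.25; min_a <- 0.25 * pi / 180
  while (step_t >= min_t || step_a >= min_a) {
    repeat {
      moved <- FALSE
      for (k in 1:3) {
        for (sgn in c(1, -1)) {
          delta <- switch(k,
            rigid_transform(FALSE, sgn * step_a, 0, 0),
            rigid_transform(FALSE, 0, sgn * step_t, 0),
            rigid_transform(FALSE, 0, 0, sgn * step_t))
          cand <- compose_transforms(about_center(delta, centroid), best)
          if (!in_trust(cand)) next
          sc <- scorer(cand); n_eval <- n_eval + 1L
          if (is.finite(sc) && sc > best_score) {
            best <- cand; best_score <- sc; moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    step_t <- step_t / 2; step_a <- step_a / 2
  }
  list(transform = best, score = best_score, n_eval = n_eval)
}

#' Triplicate mirror-registration protocol
#'
#' Reflects the raw right-side pattern, landmark-fits it onto the left on
#' canal neuromasts, then runs `n_trials` independent refinements, each
#' starting from the landmark fit perturbed by seeded Gaussian jitter of
#' `jitter_sigma` px (translation) and `jitter_sigma` degrees (rotation about
#' the moving centroid). Fully reproducible given `cfg$seed`.
#'
#' @param left,right [point_pattern()]s; `right` is raw (unreflected).
#' @param canal_pairs Optional 2-column matrix of (left, right) canal indices
#'   into the full patterns; NULL selects rank-order pairing along x.
#' @param cfg A [registration_config()].
#' @param ras_cfg A [raster_config()] defining the dot radius (and optional
#'   canvas) of the internal colocalization scorer.
#' @return A list of `cfg$n_trials` elements, each
#'   `list(transform, r, init_r, landmark_rms)`, with attributes `canvas`
#'   (the common [raster_canvas()]), `moving` (the reflected right pattern)
#'   and `base` (the unjittered landmark fit).
#' @export
triplicate_align <- function(left, right, canal_pairs = NULL,
                             cfg = registration_config(),
                             ras_cfg = raster_config()) {
  stopifnot(inherits(left, "point_pattern"), inherits(right, "point_pattern"))
  if (sum(left$type == "superficial") == 0L)
    stop("left pattern has no superficial points")
  if (sum(right$type == "superficial") == 0L)
    stop("right pattern has no superficial points")
  moving <- reflect_pattern(right, cfg$axis)

  pairs <- if (is.null(canal_pairs)) {
    auto_canal_pairs(left, moving)
  } else {
    cp <- as.matrix(canal_pairs)
    cbind(moving = cp[, 2], fixed = cp[, 1])  # (left, right) -> (moving, fixed)
  }
  fit <- landmark_fit(moving, left, pairs[, c("moving", "fixed"), drop = FALSE],
                      cfg$allow_scale)
  base <- fit$transform

  lsup <- subset_type(left, "superficial")
  msup <- subset_type(moving, "superficial")
  canvas <- ras_cfg$canvas
  if (is.null(canvas)) {
    aligned0 <- apply_transform(msup, base)
    pad <- ras_cfg$dot_radius + ceiling(3 * cfg$jitter_sigma) + 4
    canvas <- canvas_for_patterns(list(lsup, aligned0), pad = pad)
  }
  scorer <- make_overlap_scorer(pattern_xy(lsup), pattern_xy(msup),
                                canvas, ras_cfg$dot_radius)
  centroid <- colMeans(pattern_xy(msup))

  trials <- with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_trials), function(i) {
      dth <- rnorm(1, 0, cfg$jitter_sigma) * pi / 180
      dtr <- rnorm(2, 0, cfg$jitter_sigma)
      jit <- about_center(rigid_transform(FALSE, dth, dtr[1], dtr[2]), centroid)
      init <- compose_transforms(jit, base)
      init_r <- scorer(init)
      if (cfg$refine) {
        # Trust region around the canal-anchored fit: wide enough to undo any
        # plausible jitter draw (3 sigma) plus one pixel/degree of play.
        ref <- refine_by_score(moving, left, init, scorer, cfg$allow_scale,
                               anchor = base,
                               max_shift = 3 * cfg$jitter_sigma + 1,
                               max_rot = 3 * cfg$jitter_sigma + 1)
        list(transform = ref$transform, r = ref$score, init_r = init_r,
             landmark_rms = fit$rms)
      } else {
        list(transform = init, r = init_r, init_r = init_r,
             landmark_rms = fit$rms)
      }
    })
  })
  attr(trials, "canvas") <- canvas
  attr(trials, "moving") <- moving
  attr(trials, "base") <- base
  trials
}
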