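# Seeded synthetic world with known ground truth: paired bilateral neuromast
# patterns with parameterized asymmetry, rendered fluorescence spot images,
# and cohorts calibrated to target score moments.
#
# Asymmetry model: a common "developmental template" of base positions is
# drawn uniformly in a facial region; each side observes the template (the
# right one mirrored) through independent Gaussian positional jitter, plus
# unilateral dropout and gain on the right, plus an optional acquisition
# misalignment. No richer generative model is claimed: clustering of real
# neuromasts along canals is a declared simplification.

#' Asymmetry parameters for the bilateral generator
#'
#' @param sigma Independent per-side positional jitter SD, px (>= 0). The
#'   knob calibrated against target symmetry scores.
#' @param dropout Probability in \[0, 1\] that a right-side superficial point
#'   is absent (unilateral loss).
#' @param gain Expected count of unilateral extra right-side points (Poisson).
#' @param misalign_px SD of a simulated acquisition translation offset, px.
#' @param misalign_deg SD of a simulated acquisition rotation offset, degrees.
#' @param seed Integer seed (mandatory).
#' @return An object of class `asymmetry_params`.
#' @export
asymmetry_params <- function(sigma = 0, dropout = 0, gain = 0,
                             misalign_px = 0, misalign_deg = 0, seed = 1L) {
  stopifnot(sigma >= 0, dropout >= 0, dropout <= 1, gain >= 0,
            misalign_px >= 0, misalign_deg >= 0)
  structure(list(sigma = as.numeric(sigma), dropout = as.numeric(dropout),
                 gain = as.numeric(gain), misalign_px = as.numeric(misalign_px),
                 misalign_deg = as.numeric(misalign_deg),
                 seed = as.integer(seed)),
            class = "asymmetry_params")
}

#' Default facial region and frame for simulations
#'
#' A 240 x 180 px frame at 0.01 mm/px (a realistic scale for a juvenile
#' tetra head under low magnification) with a 12-gon region standing in for
#' the facial field over the third suborbital bone.
#'
#' @return A list with `frame` ([image_frame()]) and `region`
#'   ([roi_polygon()]).
#' @export
default_face_region <- function() {
  frame <- image_frame(240, 180, 0.01)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  v <- cbind(120 + 85 * cos(ang), 92 + 55 * sin(ang))
  list(frame = frame,
       region = roi_polygon(v, label = "other", frame = frame))
}

# Rejection-sample n points uniformly inside a polygon, at least min_spacing
# apart from each other and from `avoid`.
sample_points_in_region <- function(n, region, min_spacing, avoid = NULL) {
  v <- region$vertices
  bx <- range(v[, 1]); by <- range(v[, 2])
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L; max_tries <- 400L * n + 400L
  while (nrow(pts) < n) {
    if (tries >= max_tries)
      stop("region too small to place ", n, " points with spacing ", min_spacing)
    tries <- tries + 1L
    cand <- c(runif(1, bx[1], bx[2]), runif(1, by[1], by[2]))
    if (!points_in_polygon_xy(cand[1], cand[2], v)) next
    all_pts <- rbind(pts, avoid)
    if (nrow(all_pts) &&
        min((all_pts[, 1] - cand[1])^2 + (all_pts[, 2] - cand[2])^2) < min_spacing^2)
      next
    pts <- rbind(pts, cand)
  }
  unname(pts)
}

clamp_to_frame <- function(xy, frame) {
  cbind(pmin(pmax(xy[, 1], 0), frame$width),
        pmin(pmax(xy[, 2], 0), frame$height))
}

#' Generate a paired bilateral point pattern with known ground truth
#'
#' Draws a base template uniformly in `region` (superficial points plus canal
#' landmarks, with minimum spacing), then builds `left = template + jitter`
#' and `right = mirror(template) + jitter`, applies dropout and gain to the
#' right superficial points only (canal landmarks are never dropped), and
#' finally a random acquisition misalignment to the whole right side. The
#' returned correspondence maps left indices to surviving right indices.
#' Deterministic given `params$seed`.
#'
#' @param n_superficial Superficial point count (>= 1), default 25.
#' @param n_canal Canal landmark count (>= 2), default 6.
#' @param region An [roi_polygon()]; default [default_face_region()].
#' @param params An [asymmetry_params()].
#' @param min_spacing Minimum template point spacing in px, default 8.
#' @return A list with `left`, `right` ([point_pattern()]s) and `truth`
#'   (data.frame `left_index`, `right_index`).
#' @export
generate_bilateral_pattern <- function(n_superficial = 25, n_canal = 6,
                                       region = NULL,
                                       params = asymmetry_params(),
                                       min_spacing = 8) {
  stopifnot(n_superficial >= 1, n_canal >= 2)
  if (is.null(region)) region <- default_face_region()$region
  frame <- region$frame
  with_local_seed(params$seed, {
    canal_base <- sample_points_in_region(n_canal, region, min_spacing)
    sup_base <- sample_points_in_region(n_superficial, region, min_spacing,
                                        avoid = canal_base)
    base <- rbind(sup_base, canal_base)
    types <- c(rep("superficial", n_superficial), rep("canal", n_canal))
    nb <- nrow(base)

    left_xy <- base + matrix(rnorm(2 * nb, 0, params$sigma), nb, 2)
    mirrored <- cbind(frame$width - base[, 1], base[, 2])
    right_xy <- mirrored + matrix(rnorm(2 * nb, 0, params$sigma), nb, 2)

    keep_sup <- runif(n_superficial) >= params$dropout
    keep <- c(keep_sup, rep(TRUE, n_canal))
    right_xy <- right_xy[keep, , drop = FALSE]
    right_types <- types[keep]

    n_gain <- if (params$gain > 0) rpois(1, params$gain) else 0L
    if (n_gain > 0) {
      mreg <- roi_polygon(cbind(frame$width - region$vertices[, 1],
                                region$vertices[, 2]),
                          label = region$label, frame = frame)
      extra <- sample_points_in_region(n_gain, mreg, min_spacing,
                                       avoid = right_xy)
      right_xy <- rbind(right_xy, extra)
      right_types <- c(right_types, rep("superficial", n_gain))
    }

    if (params$misalign_px > 0 || params$misalign_deg > 0) {
      dth <- rnorm(1, 0, params$misalign_deg) * pi / 180
      dtr <- rnorm(2, 0, params$misalign_px)
      ctr <- colMeans(right_xy)
      mis <- about_center(rigid_transform(FALSE, dth, dtr[1], dtr[2]), ctr)
      right_xy <- transform_xy(right_xy, mis)
    }

    left_xy <- clamp_to_frame(left_xy, frame)
    right_xy <- clamp_to_frame(right_xy, frame)

    left <- point_pattern(left_xy[, 1], left_xy[, 2], types, "left", frame)
    right <- point_pattern(right_xy[, 1], right_xy[, 2], right_types,
                           "right", frame)
    truth <- data.frame(left_index = which(keep),
                        right_index = seq_len(sum(keep)))
    list(left = left, right = right, truth = truth)
  })
}

#' Render a synthetic fluorescence spot image
#'
#' Sums isotropic Gaussian spots of SD `spot_sigma` centred on the pattern's
#' points (sampled at integer lattice sites), adds a constant background and
#' seeded Gaussian read noise. The noise-free integral of one interior spot
#' is `amplitude * 2 * pi * spot_sigma^2` to within 1%.
#'
#' @param p A [point_pattern()].
#' @param spot_sigma Spot SD in px (> 0), default 2.
#' @param amplitude Peak amplitude per spot, default 100.
#' @param background Constant background level, default 10.
#' @param noise_sd Gaussian noise SD, default 0.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @return A numeric matrix (frame height x frame width).
#' @export
render_fluorescence_image <- function(p, spot_sigma = 2, amplitude = 100,
                                      background = 10, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(spot_sigma > 0)
  fr <- p$frame
  img <- matrix(background, nrow = fr$height, ncol = fr$width)
  half <- ceiling(6 * spot_sigma)
  for (i in seq_len(n_points(p))) {
    cx <- p$x[i]; cy <- p$y[i]
    cs <- max(0L, floor(cx) - half):min(fr$width - 1L, ceiling(cx) + half)
    rs <- max(0L, floor(cy) - half):min(fr$height - 1L, ceiling(cy) + half)
    gx <- exp(-(cs - cx)^2 / (2 * spot_sigma^2))
    gy <- exp(-(rs - cy)^2 / (2 * spot_sigma^2))
    img[rs + 1L, cs + 1L] <- img[rs + 1L, cs + 1L] + amplitude * outer(gy, gx)
  }
  if (noise_sd > 0) {
    img <- img + with_local_seed(seed,
      matrix(rnorm(length(img), 0, noise_sd), nrow = fr$height))
  }
  img
}

# Pool-adjacent-violators: project y onto the nonincreasing cone (L2).
pava_decreasing <- function(y, w = rep(1, length(y))) {
  z <- -y
  n <- length(z)
  val <- z; wt <- w; idx <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- z[i]; wt[k] <- w[i]; idx[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / tot
      wt[k - 1L] <- tot; idx[k - 1L] <- idx[k - 1L] + idx[k]
      k <- k - 1L
    }
  }
  -rep(val[seq_len(k)], idx[seq_len(k)])
}

#' Calibrate jitter SD against a target mean symmetry score
#'
#' Monte-Carlo estimates `E[mean_r]` on a grid of jitter sigmas (`m` seeded
#' replicates of the full generate-and-score pipeline per grid point),
#' enforces monotone nonincrease by isotonic projection, and inverts by
#' linear interpolation.
#'
#' @param target_mean_r Target expected mean R.
#' @param sigma_grid Grid of jitter SDs (px), default: 13 values from 0 to 64 px with
#'   near-geometric spacing, covering the full achievable score range.
#' @param m Replicates per grid point, default 200.
#' @param n_superficial,n_canal,region Passed to
#'   [generate_bilateral_pattern()].
#' @param reg_cfg,ras_cfg Scoring configuration.
#' @param seed Integer seed.
#' @return An object of class `asymmetry_calibration`: `sigma` (the
#'   estimate), `grid`, `e_mean_r` (isotonic curve), `raw_mean_r`,
#'   `resid_sd` (between-replicate SD of mean_r per grid point), `range`.
#' @export
calibrate_asymmetry <- function(target_mean_r, sigma_grid = c(0, 1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64),
                                m = 200, n_superficial = 25, n_canal = 6,
                                region = NULL,
                                reg_cfg = registration_config(),
                                ras_cfg = raster_config(), seed = 1L) {
  curve <- calibration_curve(sigma_grid, m, n_superficial, n_canal, region,
                             reg_cfg, ras_cfg, seed)
  sig <- invert_calibration(curve, target_mean_r)
  curve$sigma <- sig
  curve$target_mean_r <- target_mean_r
  curve
}

calibration_curve <- function(sigma_grid, m, n_superficial, n_canal, region,
                              reg_cfg, ras_cfg, seed) {
  stopifnot(length(sigma_grid) >= 2, m >= 2)
  raw <- matrix(NA_real_, length(sigma_grid), m)
  for (g in seq_along(sigma_grid)) {
    for (j in seq_len(m)) {
      s_ij <- derive_seed(seed, g * 100000L + j)
      pat <- generate_bilateral_pattern(
        n_superficial, n_canal, region,
        asymmetry_params(sigma = sigma_grid[g], seed = s_ij))
      rc <- reg_cfg; rc$seed <- derive_seed(s_ij, 7L)
      raw[g, j] <- symmetry_index(pat$left, pat$right, NULL, rc, ras_cfg)$mean_r
    }
  }
  raw_mean <- rowMeans(raw)
  structure(list(grid = as.numeric(sigma_grid),
                 e_mean_r = pava_decreasing(raw_mean),
                 raw_mean_r = raw_mean,
                 resid_sd = apply(raw, 1, sd),
                 m = m,
                 range = range(raw_mean)),
            class = "asymmetry_calibration")
}

invert_calibration <- function(curve, target) {
  e <- curve$e_mean_r; g <- curve$grid
  lo <- min(e); hi <- max(e)
  if (target > hi + 1e-12 || target < lo - 1e-12)
    stop(sprintf("target %.4f outside achievable mean-R range [%.4f, %.4f]",
                 target, lo, hi))
  target <- min(max(target, lo), hi)
  if (target >= e[1]) return(g[1])
  i <- max(which(e >= target))          # e nonincreasing: bracket [i, i+1]
  if (i >= length(e) || abs(e[i] - e[i + 1]) < 1e-12) return(g[i])
  # E(sigma) decays roughly as a power law on the geometric grid, so the
  # inverse interpolates in log-log space where both coordinates allow it
  if (g[i] > 0 && e[i] > 0 && e[i + 1] > 0) {
    f <- (log(e[i]) - log(target)) / (log(e[i]) - log(e[i + 1]))
    exp(log(g[i]) + f * (log(g[i + 1]) - log(g[i])))
  } else {
    f <- (e[i] - target) / (e[i] - e[i + 1])
    g[i] + f * (g[i + 1] - g[i])
  }
}

#' @export
print.asymmetry_calibration <- function(x, ...) {
  cat("<asymmetry_calibration>\n")
  print(data.frame(sigma = x$grid, e_mean_r = round(x$e_mean_r, 4),
                   resid_sd = round(x$resid_sd, 4)))
  if (!is.null(x$sigma))
    cat(sprintf("target %.4f -> sigma %.3f px\n", x$target_mean_r, x$sigma))
  invisible(x)
}

#' Generate a cohort of synthetic individuals targeting score moments
#'
#' For each population row, per-individual jitter sigmas are drawn so the
#' cohort's realized mean/SD of the symmetry index approach the targets:
#' individual target scores are sampled from
#' `Normal(target_mean_r, sd_eff)` with `sd_eff^2 = max(target_sd^2 -
#' resid_sd^2, 0)` (the pipeline's own between-replicate noise `resid_sd`,
#' interpolated from the calibration, already contributes spread), clamped to
#' the achievable range, and mapped to sigma through the inverse calibration
#' curve. Every individual then runs the full generate-and-score pipeline, so
#' all scores have complete point-pattern provenance. Realized moments are
#' reported alongside targets.
#'
#' @param cohort_spec A data.frame with columns `population`, `n`,
#'   `target_mean_r`, `target_sd`.
#' @param calibration An `asymmetry_calibration`; computed (expensively) if
#'   NULL.
#' @param n_superficial,n_canal,region,reg_cfg,ras_cfg,m As in
#'   [calibrate_asymmetry()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_cohort`: `scores` (data.frame
#'   `individual_id`, `population`, `sigma`, `target_r`, `mean_r`),
#'   `summary` (realized vs target moments), `calibration`, and `patterns`
#'   (optionally NULL, see `keep_patterns`).
#' @param keep_patterns Keep the generated point patterns in the result?
#'   Default FALSE (cohorts can be large).
#' @export
generate_cohort <- function(cohort_spec, calibration = NULL,
                            n_superficial = 25, n_canal = 6, region = NULL,
                            reg_cfg = registration_config(),
                            ras_cfg = raster_config(), m = 200, seed = 1L,
                            keep_patterns = FALSE) {
  stopifnot(all(c("population", "n", "target_mean_r", "target_sd") %in%
                  names(cohort_spec)),
            all(cohort_spec$n >= 2))
  if (is.null(calibration))
    calibration <- calibration_curve(c(0, 1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64), m,
                                     n_superficial, n_canal, region,
                                     reg_cfg, ras_cfg, derive_seed(seed, 991L))
  e <- calibration$e_mean_r
  achievable <- max(e) - min(e)
  if (any(cohort_spec$target_sd > achievable))
    stop(sprintf("infeasible target_sd: exceeds achievable spread %.4f",
                 achievable))
  rows <- list(); pats <- list()
  counter <- 0L
  for (k in seq_len(nrow(cohort_spec))) {
    popn <- cohort_spec$population[k]
    n <- cohort_spec$n[k]
    mu <- cohort_spec$target_mean_r[k]
    sdt <- cohort_spec$target_sd[k]
    resid <- stats::approx(x = rev(e), y = rev(calibration$resid_sd),
                           xout = min(max(mu, min(e)), max(e)),
                           ties = "ordered")$y
    sd_eff <- sqrt(max(sdt^2 - resid^2, 0))
    targets <- with_local_seed(derive_seed(seed, 5000L + k),
                               rnorm(n, mu, sd_eff))
    targets <- pmin(pmax(targets, min(e) + 1e-6), max(e) - 1e-6)
    for (i in seq_len(n)) {
      counter <- counter + 1L
      sig <- invert_calibration(calibration, targets[i])
      s_i <- derive_seed(seed, 90000L + counter)
      pat <- generate_bilateral_pattern(
        n_superficial, n_canal, region,
        asymmetry_params(sigma = sig, seed = s_i))
      rc <- reg_cfg; rc$seed <- derive_seed(s_i, 13L)
      res <- symmetry_index(pat$left, pat$right, NULL, rc, ras_cfg)
      id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "_", popn), i)
      rows[[counter]] <- data.frame(individual_id = id, population = popn,
                                    sigma = sig, target_r = targets[i],
                                    mean_r = res$mean_r)
      if (keep_patterns) pats[[id]] <- pat
    }
  }
  scores <- do.call(rbind, rows)
  realized <- do.call(rbind, lapply(seq_len(nrow(cohort_spec)), function(k) {
    s <- scores$mean_r[scores$population == cohort_spec$population[k]]
    data.frame(population = cohort_spec$population[k],
               target_mean_r = cohort_spec$target_mean_r[k],
               realized_mean_r = mean(s),
               target_sd = cohort_spec$target_sd[k],
               realized_sd = sd(s), n = length(s))
  }))
  structure(list(scores = scores, summary = realized,
                 calibration = calibration,
                 patterns = if (keep_patterns) pats else NULL),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
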