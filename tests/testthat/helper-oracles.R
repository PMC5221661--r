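# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package's own code paths for the quantity they check.

# Winding-number point-in-polygon oracle (angle-sum formulation), with the
# same edge-inclusive convention as the implementation under test.
oracle_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  # on-edge check
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    dx <- v[j, 1] - v[i, 1]; dy <- v[j, 2] - v[i, 2]
    L2 <- dx^2 + dy^2
    tt <- if (L2 > 0) min(1, max(0, ((px - v[i, 1]) * dx + (py - v[i, 2]) * dy) / L2)) else 0
    if ((px - (v[i, 1] + tt * dx))^2 + (py - (v[i, 2] + tt * dy))^2 <= eps^2)
      return(TRUE)
  }
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(v[i, 2] - py, v[i, 1] - px)
    a2 <- atan2(v[j, 2] - py, v[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# Brute-force Pearson over full pixel arrays (the independent route for the
# binary-mask closed form).
oracle_pearson <- function(a, b) stats::cor(as.vector(a), as.vector(b))

# Brute-force landmark-fit oracle: sweep theta on a fixed grid; for each
# theta the optimal translation is the centroid offset in closed form (exact
# minimizer given theta). Returns the grid minimizer.
oracle_landmark_theta <- function(M, F, step = 0.001) {
  thetas <- seq(-pi, pi - step, by = step)
  mM <- colMeans(M); mF <- colMeans(F)
  Mc <- sweep(M, 2, mM); Fc <- sweep(F, 2, mF)
  best <- Inf; best_theta <- NA
  for (th in thetas) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sse <- sum((Mc %*% t(R) - Fc)^2)
    if (sse < best) { best <- sse; best_theta <- th }
  }
  list(theta = best_theta, rms = sqrt(best / nrow(M) + sum((mF - mF)^2)))
}

# Small deterministic fixture pattern: an asymmetric 7-point superficial set
# plus 3 canal landmarks in a 100 x 80 frame.
fixture_pattern <- function(side = "left") {
  fr <- image_frame(100, 80, 0.02)
  point_pattern(x = c(20, 35, 42, 55, 61, 70, 30, 25, 50, 75),
                y = c(30, 22, 47, 33, 55, 28, 60, 15, 70, 50),
                type = c(rep("superficial", 7), rep("canal", 3)),
                side = side, frame = fr)
}

# Exact-mirror pair built from the fixture: right side is the vertical-line
# mirror of the left within the same frame.
fixture_mirror_pair <- function() {
  left <- fixture_pattern("left")
  right <- reflect_pattern(left, "vertical_line")
  right$side <- "right"
  list(left = left, right = right)
}

random_rigid <- function() {
  rigid_transform(reflect = runif(1) < 0.5,
                  theta = runif(1, -pi, pi),
                  tx = runif(1, -50, 50), ty = runif(1, -50, 50),
                  scale = exp(runif(1, -0.3, 0.3)))
}

# Cached expensive artefacts shared between test files (computed on first
# use; deterministic given the fixed seeds baked in here).
.test_cache <- new.env(parent = emptyenv())

get_reference_calibration <- function() {
  if (is.null(.test_cache$cal)) {
    .test_cache$cal <- neuromastsym:::calibration_curve(
      sigma_grid = c(0, 1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64), m = 200,
      n_superficial = 25, n_canal = 6, region = NULL,
      reg_cfg = registration_config(), ras_cfg = raster_config(),
      seed = 20240901L)
  }
  .test_cache$cal
}
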