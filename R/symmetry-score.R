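# Dot-mask rasterization and the JACoP-style Pearson colocalization score.
#
# The score deliberately mimics the manual protocol it automates: each
# neuromast becomes a small filled circle on a blank background, the two
# binary masks share one canvas, and R is the Pearson product-moment
# correlation over ALL canvas pixels (background zeros included). R therefore
# depends on the canvas: the default canvas rule (union bounding box of both
# patterns plus dot-radius padding) is echoed into every result.

#' Rasterization configuration
#'
#' @param dot_radius Dot radius in pixels (>= 0), default 3. A canvas pixel is
#'   on iff its lattice site lies within Euclidean distance `dot_radius` of
#'   some point.
#' @param canvas Optional [raster_canvas()]. When NULL the canvas is derived
#'   from the data (union bounding box of both patterns + `dot_radius`
#'   padding).
#' @return An object of class `raster_config`.
#' @export
raster_config <- function(dot_radius = 3, canvas = NULL) {
  stopifnot(is.numeric(dot_radius), length(dot_radius) == 1L,
            is.finite(dot_radius), dot_radius >= 0)
  if (!is.null(canvas)) stopifnot(inherits(canvas, "raster_canvas"))
  structure(list(dot_radius = as.numeric(dot_radius), canvas = canvas),
            class = "raster_config")
}

#' Raster canvas
#'
#' A rectangular pixel lattice. Canvas pixel (row i, col j), 1-based, samples
#' the frame location (x0 + j - 1, y0 + i - 1): lattice sites sit at integer
#' coordinate offsets from the canvas origin.
#'
#' @param x0,y0 Frame coordinates of the first lattice site.
#' @param width,height Canvas size in pixels (>= 1).
#' @export
raster_canvas <- function(x0, y0, width, height) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 1L, height >= 1L, is.finite(x0), is.finite(y0))
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 width = width, height = height),
            class = "raster_canvas")
}

#' Canvas enclosing a set of patterns
#'
#' Implements the default canvas rule: the union bounding box of all supplied
#' patterns, padded by `pad` pixels on every side, snapped to the integer
#' lattice.
#'
#' @param patterns A list of [point_pattern()]s (empty ones are ignored).
#' @param pad Padding in pixels (typically `dot_radius` plus a search margin).
#' @return A [raster_canvas()].
#' @export
canvas_for_patterns <- function(patterns, pad = 3) {
  xs <- unlist(lapply(patterns, `[[`, "x"))
  ys <- unlist(lapply(patterns, `[[`, "y"))
  if (!length(xs)) stop("cannot derive a canvas from empty patterns")
  x0 <- floor(min(xs) - pad); y0 <- floor(min(ys) - pad)
  x1 <- ceiling(max(xs) + pad); y1 <- ceiling(max(ys) + pad)
  raster_canvas(x0, y0, x1 - x0 + 1L, y1 - y0 + 1L)
}

# 0-based linear indices (col + row * width) of lattice sites within `radius`
# of any (x, y), clipped to the canvas. The workhorse behind both the public
# rasterizer and the fast registration scorer.
dot_pixel_set <- function(x, y, canvas, radius) {
  if (!length(x)) return(integer(0))
  u <- x - canvas$x0; v <- y - canvas$y0        # lattice coordinates
  h <- as.integer(ceiling(radius)) + 1L
  off <- seq.int(-h, h)
  k <- length(off)
  cu <- round(u); cv <- round(v)
  # n x k^2 candidate grid around each point
  cc <- rep(cu, each = k * k) + rep(rep(off, each = k), times = length(x))
  rr <- rep(cv, each = k * k) + rep(rep(off, times = k), times = length(x))
  du <- cc - rep(u, each = k * k)
  dv <- rr - rep(v, each = k * k)
  # boundary pixels count as on, with a small tolerance so membership cannot
  # flip under ~1e-12 px numerical noise in a registered coordinate
  keep <- (du * du + dv * dv) <= radius^2 + 1e-7 &
    cc >= 0 & cc < canvas$width & rr >= 0 & rr < canvas$height
  unique(as.integer(cc[keep] + rr[keep] * canvas$width))
}

#' Rasterize a point pattern into a binary dot mask
#'
#' A canvas pixel is 1 iff its lattice site lies within `dot_radius` of any
#' pattern point; everything else is 0 (blank background). With `dot_radius`
#' 0 a point at an exact lattice site turns on exactly one pixel.
#'
#' @param p A [point_pattern()].
#' @param cfg A [raster_config()]; if its canvas is NULL one is derived from
#'   `p` alone.
#' @param clip Clip off-canvas content silently (as an image export would)
#'   instead of erroring? Default FALSE: points outside the canvas raise an
#'   error listing the offending indices.
#' @return An integer matrix (height x width) of 0/1 values.
#' @export
rasterize <- function(p, cfg = raster_config(), clip = FALSE) {
  canvas <- cfg$canvas
  if (is.null(canvas)) canvas <- canvas_for_patterns(list(p), pad = cfg$dot_radius)
  if (n_points(p) && !clip) {
    bad <- which(p$x < canvas$x0 | p$x > canvas$x0 + canvas$width - 1L |
                   p$y < canvas$y0 | p$y > canvas$y0 + canvas$height - 1L)
    if (length(bad))
      stop("points outside canvas at indices: ", paste(bad, collapse = ", "))
  }
  m <- matrix(0L, nrow = canvas$height, ncol = canvas$width)
  idx <- dot_pixel_set(p$x, p$y, canvas, cfg$dot_radius)
  if (length(idx)) {
    # linear index is 0-based col + row*width; matrix is row = y, col = x
    m[cbind(idx %/% canvas$width + 1L, idx %% canvas$width + 1L)] <- 1L
  }
  m
}

# Pearson correlation of two binary masks from their on-counts. For on
# fractions pA, pB and joint fraction pAB this is
# (pAB - pA pB) / sqrt(pA (1 - pA) pB (1 - pB)).
pearson_from_counts <- function(nA, nB, nAB, N) {
  num <- N * nAB - nA * nB
  den2 <- (N * nA - nA^2) * (N * nB - nB^2)
  if (den2 <= 0) return(NA_real_)
  num / sqrt(den2)
}

#' Pearson colocalization coefficient of two binary masks
#'
#' The correlation is computed over every pixel of the canvas, matching how
#' pixel-wise colocalization tools score exported dot overlays. For binary
#' masks the closed form in on-fractions is used; it is algebraically
#' identical to `cor(as.vector(a), as.vector(b))`.
#'
#' @param a,b Binary matrices of identical dimensions, each with nonzero
#'   variance (at least one on and one off pixel).
#' @return Pearson R in \[-1, 1\].
#' @export
pearson_coloc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical dimensions")
  N <- length(a)
  nA <- sum(a != 0); nB <- sum(b != 0)
  if (nA == 0L || nA == N || nB == 0L || nB == N)
    stop("undefined correlation: mask has zero variance")
  nAB <- sum(a != 0 & b != 0)
  pearson_from_counts(nA, nB, nAB, N)
}

# Fast scorer used during registration refinement: holds the fixed mask's
# pixel set and scores a candidate transform of the moving points without
# materializing matrices. Points whose dots fall off-canvas are clipped, as
# an image-based tool would clip content outside the exported frame.
make_overlap_scorer <- function(fixed_xy, moving_xy, canvas, dot_radius,
                                center = c(0, 0)) {
  fixed_set <- dot_pixel_set(fixed_xy[, 1], fixed_xy[, 2], canvas, dot_radius)
  N <- canvas$width * canvas$height
  nA <- length(fixed_set)
  force(moving_xy); force(center)
  function(t) {
    xy <- transform_xy(moving_xy, t, center)
    mov <- dot_pixel_set(xy[, 1], xy[, 2], canvas, dot_radius)
    nB <- length(mov)
    nAB <- sum(!is.na(match(mov, fixed_set)))
    r <- pearson_from_counts(nA, nB, nAB, N)
    if (is.na(r)) -1 else r
  }
}

#' Per-individual symmetry result
#'
#' Assembled by [symmetry_index()]: one colocalization R per trial, their
#' mean, and the fitted transform per trial.
#'
#' @param trial_r Numeric vector of per-trial R values.
#' @param transforms List of per-trial [rigid_transform()]s.
#' @param n_left,n_right Superficial point counts entering the score.
#' @param canvas The [raster_canvas()] used.
#' @param config List echoing the registration/raster configuration.
#' @export
symmetry_result <- function(trial_r, transforms, n_left, n_right, canvas,
                            config = list()) {
  stopifnot(all(trial_r >= -1 - 1e-12 & trial_r <= 1 + 1e-12))
  structure(list(trial_r = as.numeric(trial_r),
                 mean_r = mean(trial_r),
                 transforms = transforms,
                 n_left = as.integer(n_left), n_right = as.integer(n_right),
                 canvas = canvas, config = config),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("<symmetry_result mean R = %.4f over %d trials (%s); n_left=%d n_right=%d>\n",
              x$mean_r, length(x$trial_r),
              paste(sprintf("%.4f", x$trial_r), collapse = ", "),
              x$n_left, x$n_right))
  invisible(x)
}

#' End-to-end bilateral symmetry index
#'
#' Runs the full per-individual protocol: mirror the right side, landmark-fit
#' on canal neuromasts, refine in triplicate from jittered starts
#' ([triplicate_align()]), then rasterize the left and aligned-right
#' superficial points on a common canvas and score each trial with
#' [pearson_coloc()]. The mean over trials is the individual's symmetry
#' index.
#'
#' @param left,right [point_pattern()]s for the two sides (`right` raw,
#'   unreflected).
#' @param canal_pairs Optional 2-column matrix of (left, right) canal point
#'   indices; defaults to rank-order pairing along the anteroposterior axis.
#' @param reg_cfg A [registration_config()].
#' @param ras_cfg A [raster_config()].
#' @return A [symmetry_result()].
#' @export
symmetry_index <- function(left, right, canal_pairs = NULL,
                           reg_cfg = registration_config(),
                           ras_cfg = raster_config()) {
  trials <- triplicate_align(left, right, canal_pairs, reg_cfg, ras_cfg)
  canvas <- attr(trials, "canvas")
  cfg <- raster_config(ras_cfg$dot_radius, canvas)
  lsup <- subset_type(left, "superficial")
  msup <- subset_type(attr(trials, "moving"), "superficial")
  mask_l <- rasterize(lsup, cfg)
  r <- vapply(trials, function(tr) {
    aligned <- apply_transform(msup, tr$transform)
    pearson_coloc(mask_l, rasterize(aligned, cfg, clip = TRUE))
  }, numeric(1))
  symmetry_result(
    trial_r = r,
    transforms = lapply(trials, `[[`, "transform"),
    n_left = n_points(lsup), n_right = n_points(msup),
    canvas = canvas,
    config = list(registration = unclass(reg_cfg),
                  dot_radius = ras_cfg$dot_radius))
}
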