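# Domain types and exact geometric primitives shared by every pipeline stage.
#
# Coordinate convention (documented once, used everywhere): 0-based, origin at
# the top-left pixel corner, x rightward, y downward. A point (x, y) is a
# continuous position in this frame; rasterization (see symmetry-score.R)
# samples the integer lattice.

#' Image frame metadata
#'
#' Describes the pixel grid a point pattern or ROI lives in, plus the physical
#' pixel size used for area conversion.
#'
#' @param width,height Frame size in pixels (integers >= 1).
#' @param scale_mm_per_px Physical size of one pixel in millimetres (> 0).
#' @return An object of class `image_frame`.
#' @examples
#' image_frame(240, 180, 0.01)
#' @export
image_frame <- function(width, height, scale_mm_per_px) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(length(width) == 1L, length(height) == 1L,
            !is.na(width), !is.na(height), width >= 1L, height >= 1L)
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("scale_mm_per_px must be a single positive number")
  structure(list(width = width, height = height,
                 scale_mm_per_px = as.numeric(scale_mm_per_px)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %d x %d px, %.6g mm/px>\n",
              x$width, x$height, x$scale_mm_per_px))
  invisible(x)
}

frames_identical <- function(a, b) {
  isTRUE(a$width == b$width) && isTRUE(a$height == b$height) &&
    isTRUE(all.equal(a$scale_mm_per_px, b$scale_mm_per_px))
}

#' Digitized neuromast point pattern
#'
#' An ordered set of 2D point coordinates with per-point type labels
#' (`"superficial"` points are scored for symmetry; `"canal"` points are the
#' registration landmarks), a side label, and the image frame the coordinates
#' refer to. Empty patterns are allowed (they are flagged downstream).
#'
#' @param x,y Numeric coordinate vectors (pixels), equal length.
#' @param type Per-point label, `"superficial"` or `"canal"`; recycled if
#'   length 1.
#' @param side `"left"` or `"right"`.
#' @param frame An [image_frame()].
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, type = "superficial", side = "left", frame) {
  stopifnot(inherits(frame, "image_frame"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(type) == 1L) type <- rep(type, length(x))
  if (length(type) != length(x)) stop("types and points must have equal length")
  if (!all(type %in% c("superficial", "canal")))
    stop("type must be 'superficial' or 'canal'")
  side <- match.arg(side, c("left", "right"))
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("point coordinates must be finite")
  if (length(x) && (any(x < 0 | x > frame$width) || any(y < 0 | y > frame$height)))
    stop("all points must lie within [0, width] x [0, height]")
  structure(list(x = x, y = y, type = type, side = side, frame = frame),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern side=%s: %d superficial, %d canal, frame %dx%d>\n",
              x$side, sum(x$type == "superficial"), sum(x$type == "canal"),
              x$frame$width, x$frame$height))
  invisible(x)
}

#' Number of points in a pattern
#' @param p A [point_pattern()].
#' @export
n_points <- function(p) length(p$x)

pattern_xy <- function(p) cbind(x = p$x, y = p$y)

#' Subset a point pattern by type
#' @param p A [point_pattern()].
#' @param type `"superficial"` or `"canal"`.
#' @return A `point_pattern` containing only points of the requested type.
#' @export
subset_type <- function(p, type) {
  keep <- p$type == type
  point_pattern(p$x[keep], p$y[keep], p$type[keep], p$side, p$frame)
}

replace_xy <- function(p, xy) {
  q <- p
  q$x <- as.numeric(xy[, 1]); q$y <- as.numeric(xy[, 2])
  q
}

#' Reflect a point pattern across a frame axis
#'
#' Mirrors the pattern within its frame. `"vertical_line"` maps
#' (x, y) -> (width - x, y): the left-right mirror used to lateralize the
#' right side before registration. `"horizontal_line"` maps
#' (x, y) -> (x, height - y), the literal top-bottom flip. Types and the side
#' label are preserved, and applying the same reflection twice returns the
#' input exactly.
#'
#' @param p A [point_pattern()].
#' @param axis `"vertical_line"` (default) or `"horizontal_line"`.
#' @return The reflected `point_pattern`.
#' @export
reflect_pattern <- function(p, axis = c("vertical_line", "horizontal_line")) {
  axis <- match.arg(axis)
  q <- p
  if (axis == "vertical_line") q$x <- p$frame$width - p$x
  else q$y <- p$frame$height - p$y
  q
}

#' Rigid (or similarity) planar transform
#'
#' Maps a point as `x' = scale * R(theta) * M * x + (tx, ty)`, where `M`
#' mirrors x -> -x when `reflect` is TRUE. The stored form is always
#' origin-centred; [apply_transform()] offers a rotation centre for
#' convenience.
#'
#' @param reflect Apply the x-mirror before rotating? Default FALSE.
#' @param theta Rotation angle in radians (counter-clockwise in the
#'   y-down image frame's algebraic sense).
#' @param tx,ty Translation in pixels.
#' @param scale Uniform scale factor (> 0), default 1.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(reflect = FALSE, theta = 0, tx = 0, ty = 0, scale = 1) {
  stopifnot(is.logical(reflect), length(reflect) == 1L,
            is.finite(theta), is.finite(tx), is.finite(ty),
            is.finite(scale), scale > 0)
  structure(list(reflect = reflect, theta = as.numeric(theta),
                 tx = as.numeric(tx), ty = as.numeric(ty),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform reflect=%s theta=%.4f rad tx=%.3f ty=%.3f scale=%.4f>\n",
              x$reflect, x$theta, x$tx, x$ty, x$scale))
  invisible(x)
}

# 2x2 linear part: scale * R(theta) %*% M
transform_matrix <- function(t) {
  R <- matrix(c(cos(t$theta), sin(t$theta), -sin(t$theta), cos(t$theta)), 2, 2)
  A <- t$scale * R
  if (t$reflect) A[, 1] <- -A[, 1]
  A
}

# Recover (reflect, theta, scale) from a similarity matrix A = s R M.
decompose_matrix <- function(A, tx = 0, ty = 0) {
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  reflect <- d < 0
  s <- sqrt(abs(d))
  B <- A
  if (reflect) B[, 1] <- -B[, 1]   # strip the mirror: B = s R
  theta <- atan2(B[2, 1], B[1, 1])
  rigid_transform(reflect = reflect, theta = theta, tx = tx, ty = ty, scale = s)
}

transform_xy <- function(xy, t, center = c(0, 0)) {
  if (!nrow(xy)) return(xy)
  A <- transform_matrix(t)
  out <- sweep(xy, 2, center) %*% t(A)
  sweep(out, 2, c(center[1] + t$tx, center[2] + t$ty), `+`)
}

#' Apply a transform to a point pattern
#'
#' Operation order is fixed: optional x-mirror, then scale and rotation (about
#' `center`, default the origin), then translation. The output keeps the input
#' frame unless `frame` is supplied.
#'
#' @param p A [point_pattern()].
#' @param t A [rigid_transform()].
#' @param center Rotation/scaling centre, default `c(0, 0)`. Pipeline code
#'   perturbs transforms about the pattern centroid via [compose_transforms()].
#' @param frame Optional target [image_frame()] for the result.
#' @return The transformed `point_pattern`. Coordinates are not clipped; a
#'   result outside the frame keeps its coordinates but drops frame validation.
#' @export
apply_transform <- function(p, t, center = c(0, 0), frame = NULL) {
  xy <- transform_xy(pattern_xy(p), t, center)
  q <- p
  if (!is.null(frame)) q$frame <- frame
  q$x <- as.numeric(xy[, 1]); q$y <- as.numeric(xy[, 2])
  q
}

#' Compose two transforms (apply `first`, then `second`)
#' @param second,first [rigid_transform()] objects, both origin-centred.
#' @return The origin-centred `rigid_transform` equal to `second o first`.
#' @export
compose_transforms <- function(second, first) {
  A2 <- transform_matrix(second); A1 <- transform_matrix(first)
  A <- A2 %*% A1
  tv <- A2 %*% c(first$tx, first$ty) + c(second$tx, second$ty)
  decompose_matrix(A, tv[1], tv[2])
}

#' Invert a transform
#' @param t A [rigid_transform()] (origin-centred form).
#' @return The inverse `rigid_transform`.
#' @export
inverse_transform <- function(t) {
  A <- transform_matrix(t)
  Ai <- solve(A)
  tv <- -Ai %*% c(t$tx, t$ty)
  decompose_matrix(Ai, tv[1], tv[2])
}

# Re-express "rotate/scale about center, then translate" as origin-centred.
about_center <- function(t, center) {
  A <- transform_matrix(t)
  tv <- c(center[1] + t$tx, center[2] + t$ty) - A %*% center
  decompose_matrix(A, tv[1], tv[2])
}

#' Region-of-interest polygon
#'
#' A simple (non-self-intersecting) polygon in frame coordinates with an
#' anatomical label. Validation happens at construction: at least 3 vertices,
#' vertices inside the frame, no proper edge crossings.
#'
#' @param vertices A 2-column numeric matrix (or coercible) of (x, y)
#'   vertices, in order, without a repeated closing vertex.
#' @param label One of `"SO3"`, `"SO3_fragment"`, `"crescent"`, `"other"`.
#' @param frame An [image_frame()].
#' @param side Optional side label (`"left"`, `"right"`, or NA).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = c("SO3", "SO3_fragment", "crescent", "other"),
                        frame, side = NA_character_) {
  label <- match.arg(label)
  stopifnot(inherits(frame, "image_frame"))
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3")
  if (any(!is.finite(v))) stop("vertices must be finite")
  if (any(v[, 1] < 0 | v[, 1] > frame$width | v[, 2] < 0 | v[, 2] > frame$height))
    stop("vertices must lie within the frame bounds")
  if (polygon_self_intersects(v))
    stop("polygon is self-intersecting: ROI rejected")
  if (!is.na(side)) side <- match.arg(side, c("left", "right"))
  structure(list(vertices = v, label = label, frame = frame, side = side),
            class = "roi_polygon")
}

# Proper-crossing test between non-adjacent edges (shared endpoints allowed).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (including the wrap-around pair)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon %s%s: %d vertices, area %.2f px^2>\n",
              x$label, if (is.na(x$side)) "" else paste0(" (", x$side, ")"),
              nrow(x$vertices), polygon_area_px(x)))
  invisible(x)
}

#' Polygon area in square pixels (shoelace formula)
#'
#' Absolute value of the signed shoelace sum, so the result is independent of
#' vertex orientation and always non-negative.
#'
#' @param roi An [roi_polygon()], or a bare n x 2 vertex matrix.
#' @return Area in px^2.
#' @export
polygon_area_px <- function(roi) {
  v <- if (inherits(roi, "roi_polygon")) roi$vertices else as.matrix(roi)
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  abs(sum(x * yn - xn * y)) / 2
}

#' Convert an area from px^2 to mm^2
#' @param area_px Area in square pixels (>= 0).
#' @param frame The [image_frame()] supplying the mm-per-pixel scale.
#' @return Area in mm^2 (`area_px * scale^2`).
#' @export
area_to_mm2 <- function(area_px, frame) {
  stopifnot(inherits(frame, "image_frame"))
  if (any(!is.finite(area_px)) || any(area_px < 0))
    stop("area_px must be non-negative")
  area_px * frame$scale_mm_per_px^2
}

# Vectorized even-odd (ray casting) membership with an edge-inclusive rule:
# points within `eps` of any polygon edge count as inside. Returns logical.
points_in_polygon_xy <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # crossing test (half-open on vertices for determinism)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # distance point -> segment
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2)) else 0
    qx <- xi + tt * dx; qy <- yi + tt * dy
    on_edge <- on_edge | ((px - qx)^2 + (py - qy)^2 <= eps^2)
    j <- i
  }
  inside | on_edge
}

#' Count pattern points inside an ROI polygon
#'
#' Even-odd ray-casting membership. Points lying exactly on a polygon edge
#' (within 1e-9 px) count as inside, so counts are reproducible.
#'
#' @param p A [point_pattern()].
#' @param roi An [roi_polygon()] sharing `p`'s frame.
#' @return A list with `count` (integer) and `mask` (logical per point).
#' @export
points_in_polygon <- function(p, roi) {
  stopifnot(inherits(p, "point_pattern"), inherits(roi, "roi_polygon"))
  if (!frames_identical(p$frame, roi$frame))
    stop("pattern and ROI must share a frame")
  mask <- if (n_points(p)) points_in_polygon_xy(p$x, p$y, roi$vertices) else logical(0)
  list(count = sum(mask), mask = mask)
}
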