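# Automated detection of fluorescent puncta: multi-scale scale-normalized
# Laplacian-of-Gaussian blob detection with non-maximum suppression and
# subpixel quadratic refinement. Replaces the manual dot-marking step.

#' Spot detection configuration
#'
#' @param sigma_min,sigma_max Scale range (px) of the LoG filter bank;
#'   `0 < sigma_min <= sigma_max`. Spot SD, not diameter.
#' @param threshold Relative response threshold in (0, 1\]: maxima below
#'   `threshold * max(response)` are discarded (hence invariant to positive
#'   intensity rescaling).
#' @param min_separation Minimum centre separation in px (>= 0); closer
#'   maxima are merged keeping the stronger response.
#' @param n_scales Number of geometrically spaced scales, default 4.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(sigma_min = 1.5, sigma_max = 3, threshold = 0.2,
                             min_separation = 4, n_scales = 4) {
  stopifnot(sigma_min > 0, sigma_max >= sigma_min,
            threshold > 0, threshold <= 1, min_separation >= 0, n_scales >= 1)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 threshold = threshold, min_separation = min_separation,
                 n_scales = as.integer(n_scales)),
            class = "detection_config")
}

# 1D Gaussian smoothing matrix with reflected boundary; smoothing the rows of
# an image I is K %*% I (and columns I %*% t(K)).
gaussian_band_matrix <- function(n, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  ker <- exp(-(-h:h)^2 / (2 * sigma^2))
  ker <- ker / sum(ker)
  K <- matrix(0, n, n)
  for (j in -h:h) {
    idx <- seq_len(n) + j
    idx <- ifelse(idx < 1L, 2L - idx, idx)          # reflect
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + ker[j + h + 1L]
  }
  K
}

gaussian_smooth <- function(img, sigma) {
  Kr <- gaussian_band_matrix(nrow(img), sigma)
  Kc <- gaussian_band_matrix(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

# Scale-normalized negative LoG response (bright blobs -> positive peaks).
log_response <- function(img, sigma) {
  s <- gaussian_smooth(img, sigma)
  n <- nrow(s); m <- ncol(s)
  up <- s[c(1, seq_len(n - 1)), ]; dn <- s[c(2:n, n), ]
  lf <- s[, c(1, seq_len(m - 1))]; rt <- s[, c(2:m, m)]
  -sigma^2 * (up + dn + lf + rt - 4 * s)
}

#' Detect fluorescent spots in a grayscale image
#'
#' Multi-scale LoG filtering, per-pixel maximum over scales, 8-neighbour
#' local maxima above a relative threshold, greedy merging of maxima closer
#' than `min_separation` (stronger response wins), and subpixel centre
#' refinement by a separable quadratic fit. The result is sorted by (y, x)
#' so downstream output is bit-stable.
#'
#' @param image A numeric matrix (rows = y, cols = x), at least 16 x 16,
#'   finite-valued. Matrix cell `[i, j]` samples frame location
#'   `(j - 1, i - 1)`.
#' @param cfg A [detection_config()].
#' @param frame Optional [image_frame()] for the returned pattern; defaults
#'   to the image dimensions at scale 1 mm/px.
#' @param side Side label for the returned pattern, default `"left"`.
#' @return A [point_pattern()] of detected superficial spot centres. A
#'   zero-dynamic-range image yields an empty pattern with a warning.
#' @export
detect_spots <- function(image, cfg = detection_config(), frame = NULL,
                         side = "left") {
  stopifnot(is.matrix(image), nrow(image) >= 16L, ncol(image) >= 16L)
  if (any(!is.finite(image))) stop("image must be finite-valued")
  if (is.null(frame)) frame <- image_frame(ncol(image), nrow(image), 1)
  empty <- point_pattern(numeric(0), numeric(0), character(0), side, frame)
  if (diff(range(image)) == 0) {
    warning("image has zero dynamic range; returning an empty pattern")
    return(empty)
  }
  sigmas <- if (cfg$n_scales == 1L) cfg$sigma_min else
    exp(seq(log(cfg$sigma_min), log(cfg$sigma_max), length.out = cfg$n_scales))
  resp <- log_response(image, sigmas[1])
  for (s in sigmas[-1]) resp <- pmax(resp, log_response(image, s))

  n <- nrow(resp); m <- ncol(resp)
  shift <- function(M, dr, dc) {
    ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
    ci <- pmin(pmax(seq_len(m) + dc, 1L), m)
    M[ri, ci]
  }
  is_max <- resp > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (resp >= shift(resp, dr, dc))
  }
  is_max <- is_max & (resp >= cfg$threshold * max(resp))
  # exclude the 1-px border (finite-difference artefacts)
  is_max[c(1, n), ] <- FALSE; is_max[, c(1, m)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)

  vals <- resp[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- idx[keep, , drop = FALSE]
    d2 <- (kept[, 1] - idx[i, 1])^2 + (kept[, 2] - idx[i, 2])^2
    if (all(d2 >= cfg$min_separation^2)) keep[i] <- TRUE
  }
  idx <- idx[keep, , drop = FALSE]

  # subpixel: separable quadratic fit on the response
  sub <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    off <- ifelse(abs(den) > 1e-12, 0.5 * (rm1 - rp1) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  ri <- idx[, 1]; ci <- idx[, 2]
  dy <- sub(resp[cbind(ri - 1L, ci)], resp[cbind(ri, ci)], resp[cbind(ri + 1L, ci)])
  dx <- sub(resp[cbind(ri, ci - 1L)], resp[cbind(ri, ci)], resp[cbind(ri, ci + 1L)])
  x <- (ci - 1L) + dx
  y <- (ri - 1L) + dy
  x <- pmin(pmax(x, 0), frame$width)
  y <- pmin(pmax(y, 0), frame$height)
  o <- order(y, x)
  point_pattern(x[o], y[o], "superficial", side, frame)
}

#' Match detections against ground truth
#'
#' Greedy nearest-neighbour matching within `tol`: pairs are accepted in
#' increasing distance order, each truth and each detected point used at most
#' once.
#'
#' @param detected,truth [point_pattern()]s.
#' @param tol Matching tolerance in px (> 0).
#' @return A list with `precision` (NA when nothing was detected), `recall`
#'   (NA when truth is empty), `n_matched`, and `match` (2-column matrix of
#'   detected/truth indices).
#' @export
match_detections <- function(detected, truth, tol = 2) {
  stopifnot(tol > 0)
  nd <- n_points(detected); nt <- n_points(truth)
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("detected", "truth")))
  if (nd && nt) {
    d2 <- outer(detected$x, truth$x, `-`)^2 + outer(detected$y, truth$y, `-`)^2
    cand <- which(d2 <= tol^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        a <- cand[i, 1]; b <- cand[i, 2]
        if (!used_d[a] && !used_t[b]) {
          used_d[a] <- TRUE; used_t[b] <- TRUE
          pairs <- rbind(pairs, c(a, b))
        }
      }
    }
  }
  nmatch <- nrow(pairs)
  list(precision = if (nd) nmatch / nd else NA_real_,
       recall = if (nt) nmatch / nt else NA_real_,
       n_matched = nmatch, match = pairs)
}
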