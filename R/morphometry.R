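# ROI morphometry: Crescent / SO3 areas in px^2 and mm^2, neuromast counts
# per region, and per-side fragment tallies. Overlapping ROIs are measured
# independently (a point may count in several regions).

#' Measure a set of ROI polygons against a point pattern
#'
#' Per ROI: shoelace area, mm^2 conversion through the frame scale, and an
#' edge-inclusive point-in-polygon neuromast count. For `"SO3"` rows,
#' `n_fragments` is the number of `"SO3_fragment"` polygons on the same side.
#' A failing ROI yields an error row (message captured) without stopping the
#' others. Rows are ordered by (side, label) for determinism.
#'
#' @param rois A list of [roi_polygon()]s.
#' @param pattern A [point_pattern()] sharing the frame.
#' @param frame The common [image_frame()].
#' @return A data.frame with columns `label`, `side`, `area_px`, `area_mm2`,
#'   `n_neuromasts`, `n_fragments`, `error`.
#' @export
measure_rois <- function(rois, pattern, frame) {
  stopifnot(inherits(frame, "image_frame"))
  if (!length(rois))
    return(data.frame(label = character(0), side = character(0),
                      area_px = numeric(0), area_mm2 = numeric(0),
                      n_neuromasts = integer(0), n_fragments = integer(0),
                      error = character(0)))
  sides <- vapply(rois, function(r) r$side %||% NA_character_, character(1))
  labels <- vapply(rois, `[[`, character(1), "label")
  frag_by_side <- table(sides[labels == "SO3_fragment"])
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    out <- data.frame(label = r$label, side = sides[i],
                      area_px = NA_real_, area_mm2 = NA_real_,
                      n_neuromasts = NA_integer_, n_fragments = NA_integer_,
                      error = NA_character_)
    tryCatch({
      if (!frames_identical(r$frame, frame))
        stop("ROI frame differs from the supplied frame")
      out$area_px <- polygon_area_px(r)
      out$area_mm2 <- area_to_mm2(out$area_px, frame)
      out$n_neuromasts <- points_in_polygon(pattern, r)$count
      if (r$label == "SO3") {
        out$n_fragments <- if (!is.na(sides[i]) && sides[i] %in% names(frag_by_side))
          as.integer(frag_by_side[[sides[i]]]) else sum(labels == "SO3_fragment")
      }
      out
    }, error = function(e) { out$error <- conditionMessage(e); out })
  })
  res <- do.call(rbind, rows)
  res[order(res$side, res$label), , drop = FALSE]
}

#' Per-individual left-right difference table
#'
#' For every ROI label present, reports left value, right value, signed
#' difference (L - R) and absolute difference for area (mm^2), neuromast
#' count, and fragment count. No statistical claim is attached. A label with
#' a missing side is flagged `incomplete` rather than dropped.
#'
#' @param measurements A data.frame as returned by [measure_rois()], with
#'   both sides present per label for complete rows.
#' @return A data.frame with one row per (label, quantity).
#' @export
bilateral_asymmetry_table <- function(measurements) {
  qty <- c("area_mm2", "n_neuromasts", "n_fragments")
  labs <- unique(measurements$label)
  rows <- list()
  for (lb in labs) {
    for (q in qty) {
      lrow <- measurements[measurements$label == lb &
                             measurements$side %in% "left", q]
      rrow <- measurements[measurements$label == lb &
                             measurements$side %in% "right", q]
      L <- if (length(lrow)) sum(lrow) else NA_real_
      R <- if (length(rrow)) sum(rrow) else NA_real_
      incomplete <- !length(lrow) || !length(rrow) || anyNA(c(L, R))
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, quantity = q, left = L, right = R,
        diff = if (incomplete) NA_real_ else L - R,
        abs_diff = if (incomplete) NA_real_ else abs(L - R),
        incomplete = incomplete)
    }
  }
  do.call(rbind, rows)
}
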