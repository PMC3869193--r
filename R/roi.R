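# Droplet ROI location. Native data model: one field of view per droplet
# (the droplet fills most of its frame). Grid mode derives the ROI from
# the layout geometry; detect mode finds the bright circular spot in the
# frame itself. Pixel coordinates are 0-based (row, col), pixel centers at
# integer coordinates, radii in pixels.

#' Construct a droplet ROI table
#'
#' @param droplet_id Integer droplet id(s).
#' @param center_row,center_col ROI center in 0-based pixel coordinates.
#' @param radius ROI (spot) radius in pixels.
#' @param shrink_factor Fraction of the radius used as the measurement
#'   disk (default 0.9; the rim is excluded).
#' @param frame_shape Optional `c(height, width)`; when given, the
#'   measurement disk is checked to lie fully inside the frame.
#' @return A tibble of class `droplet_roi`.
#' @export
droplet_roi <- function(droplet_id, center_row, center_col, radius,
                        shrink_factor = 0.9, frame_shape = NULL) {
  if (anyDuplicated(droplet_id))
    stop_domain("droplet ids must be unique within a layout")
  if (any(radius <= 0) || any(shrink_factor <= 0) || any(shrink_factor > 1))
    stop_domain("`radius` must be positive and `shrink_factor` in (0, 1]")
  roi <- tibble::tibble(droplet_id = as.integer(droplet_id),
                        center_row = as.numeric(center_row),
                        center_col = as.numeric(center_col),
                        radius = as.numeric(radius),
                        shrink_factor = as.numeric(shrink_factor))
  if (!is.null(frame_shape)) {
    r <- roi$radius * roi$shrink_factor
    if (any(roi$center_row - r < -0.5) || any(roi$center_col - r < -0.5) ||
        any(roi$center_row + r > frame_shape[1] - 0.5) ||
        any(roi$center_col + r > frame_shape[2] - 0.5))
      stop_domain("measurement disk extends outside the frame")
  }
  class(roi) <- c("droplet_roi", class(roi))
  roi
}

#' Locate droplet ROIs in a frame or stack
#'
#' Grid mode computes the ROI from the layout geometry: each droplet's
#' field of view is centered on its spot, so the ROI center is the frame
#' center and the radius the spot radius in pixels. Detect mode finds the
#' bright spot empirically: pixels at or above the frame's 75th intensity
#' percentile are thresholded, the largest 8-connected component is taken,
#' and the ROI is its centroid with radius `sqrt(area / pi)`.
#'
#' @param x A `droplet_stack`, an image array (height x width x frames),
#'   or a single frame matrix. Detect mode uses the first frame.
#' @param layout A [moca_layout()] (required for grid mode).
#' @param mode `"grid"` or `"detect"`.
#' @param droplet_id Droplet id(s) for the returned ROIs; defaults to the
#'   stack's droplet id, or all layout droplets in grid mode.
#' @param shrink_factor Measurement-disk fraction (default 0.9).
#' @return A [droplet_roi()] tibble with one row per droplet.
#' @export
locate_droplets <- function(x, layout = NULL, mode = c("grid", "detect"),
                            droplet_id = NULL, shrink_factor = 0.9) {
  mode <- match.arg(mode)
  frame <- first_frame(x)
  if (is.null(droplet_id))
    droplet_id <- if (inherits(x, "droplet_stack")) x$droplet_id
                  else if (!is.null(layout)) seq_len(layout$n_droplets) else 1L
  if (mode == "grid") {
    if (is.null(layout)) stop_domain("grid mode requires a `layout`")
    return(droplet_roi(droplet_id,
                       center_row = layout$frame_center,
                       center_col = layout$frame_center,
                       radius = layout$spot_radius_px,
                       shrink_factor = shrink_factor,
                       frame_shape = dim(frame)))
  }
  # detect mode
  if (diff(range(frame)) == 0)
    stop_domain("droplet detection failed: frame has no contrast")
  thr <- stats::quantile(frame, 0.75, names = FALSE)
  mask <- frame >= thr
  lab <- label_components(mask)
  if (max(lab) == 0L)
    stop_domain("droplet detection failed: no bright component")
  areas <- tabulate(lab[lab > 0L])
  big <- which.max(areas)
  if (areas[big] < 0.05 * length(frame))
    stop_domain(sprintf(
      "droplet detection failed: largest bright component covers %.1f%% of the frame (need >= 5%%)",
      100 * areas[big] / length(frame)))
  idx <- which(lab == big, arr.ind = TRUE)
  droplet_roi(droplet_id[1],
              center_row = mean(idx[, 1] - 1),
              center_col = mean(idx[, 2] - 1),
              radius = sqrt(areas[big] / pi),
              shrink_factor = shrink_factor,
              frame_shape = dim(frame))
}

first_frame <- function(x) {
  if (inherits(x, "droplet_stack")) return(x$pixels[, , 1])
  if (is.array(x) && length(dim(x)) == 3L) return(x[, , 1])
  if (is.matrix(x)) return(x)
  stop_domain("expected a droplet_stack, image array, or frame matrix")
}
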