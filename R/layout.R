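# Geometry of the droplet spot array, shared by the scene generator and
# the ROI extractor. Each droplet sits on a circular hydrophilic spot; the
# microscope images one field of view per droplet, sized to cover the whole
# spot with a margin.

#' Droplet-array layout
#'
#' Describes the spot array geometry: a grid of `n_rows` x `n_cols`
#' circular hydrophilic spots of diameter `spot_diameter` (mm) at
#' center-to-center `pitch` (mm), imaged at `pixels_per_mm`. Each droplet
#' has its own frame (field of view) whose side is derived so the spot fits
#' with a relative margin `frame_margin`.
#'
#' Pixel coordinates are 0-based `(row, col)` with pixel centers at integer
#' coordinates; this convention is used throughout the package.
#'
#' @param n_rows,n_cols Grid dimensions (default 4 x 6).
#' @param spot_diameter Spot (droplet) diameter in mm (default 3.18).
#' @param pitch Center-to-center spot distance in mm (default 4.5).
#' @param pixels_per_mm Image scale (default 100).
#' @param frame_margin Relative margin of the frame beyond the spot
#'   diameter (default 0.2, i.e. the frame side is 1.2 spot diameters).
#' @return An object of class `moca_layout`.
#' @examples
#' moca_layout()          # the default 4 x 6 array of 3.18-mm spots
#' @export
moca_layout <- function(n_rows = 4, n_cols = 6, spot_diameter = 3.18,
                        pitch = 4.5, pixels_per_mm = 100,
                        frame_margin = 0.2) {
  check_number(n_rows, "n_rows", lower = 1, integerish = TRUE)
  check_number(n_cols, "n_cols", lower = 1, integerish = TRUE)
  check_number(spot_diameter, "spot_diameter", lower = 0, strict_lower = TRUE)
  check_number(pitch, "pitch", lower = spot_diameter)
  check_number(pixels_per_mm, "pixels_per_mm", lower = 0, strict_lower = TRUE)
  check_number(frame_margin, "frame_margin", lower = 0)
  side <- 2L * as.integer(ceiling(spot_diameter * (1 + frame_margin) *
                                    pixels_per_mm / 2)) + 1L
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_droplets = as.integer(n_rows * n_cols),
         spot_diameter = spot_diameter, spot_radius = spot_diameter / 2,
         pitch = pitch, pixels_per_mm = pixels_per_mm,
         frame_shape = c(side, side),
         frame_center = (side - 1) / 2,
         spot_radius_px = spot_diameter / 2 * pixels_per_mm),
    class = "moca_layout")
}

#' @export
print.moca_layout <- function(x, ...) {
  cat(sprintf(
    "<moca_layout> %d x %d spots, %.2f mm diameter, %.1f px/mm, frame %d x %d px\n",
    x$n_rows, x$n_cols, x$spot_diameter, x$pixels_per_mm,
    x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}

#' Droplet grid positions
#'
#' Row-major droplet ids and their grid coordinates.
#'
#' @param layout A [moca_layout()].
#' @return A tibble with columns `droplet`, `row`, `col`.
#' @export
droplet_positions <- function(layout) {
  stopifnot(inherits(layout, "moca_layout"))
  tibble::tibble(
    droplet = seq_len(layout$n_droplets),
    row = rep(seq_len(layout$n_rows), each = layout$n_cols),
    col = rep(seq_len(layout$n_cols), times = layout$n_rows))
}

# squared distance (px^2) of every frame pixel from a center (row, col)
frame_dist2 <- function(shape, center_row, center_col) {
  outer((seq_len(shape[1]) - 1 - center_row)^2,
        (seq_len(shape[2]) - 1 - center_col)^2, "+")
}
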