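# Reduce frame stacks to per-droplet transmission time series: the mean
# gray level over the shrunk measurement disk, frame by frame. Pixels
# outside the measurement disk never influence the result.

#' Extract transmission time series from a frame stack
#'
#' @param x A `droplet_stack` (from [render_droplet()] / [read_stack()]),
#'   an image array (height x width x frames), or a single frame matrix.
#' @param rois A [droplet_roi()] tibble; each ROI is measured on `x`.
#' @param times Frame timestamps in hours; defaults to the stack's own
#'   times, or `0, 1, 2, ...` frame indices for bare arrays.
#' @return A tibble (`droplet_id`, `time_h`, `raw_mean_intensity`,
#'   `pixel_count`) in long format, the package's time-series carrier.
#' @examples
#' f <- matrix(200, 64, 64)
#' roi <- droplet_roi(1, 31.5, 31.5, 30)
#' extract_transmission(f, roi)
#' @export
extract_transmission <- function(x, rois, times = NULL) {
  stopifnot(inherits(rois, "droplet_roi") || is.data.frame(rois))
  if (inherits(x, "droplet_stack")) {
    if (is.null(times)) times <- x$times
    x <- x$pixels
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_domain("`x` must be a frame matrix or a height x width x frames array")
  H <- dim(x)[1]; W <- dim(x)[2]; nt <- dim(x)[3]
  if (is.null(times)) times <- seq_len(nt) - 1
  if (length(times) != nt)
    stop_domain("`times` must have one timestamp per frame")
  flat <- x
  dim(flat) <- c(H * W, nt)
  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    d2 <- frame_dist2(c(H, W), rois$center_row[i], rois$center_col[i])
    idx <- which(d2 <= (rois$shrink_factor[i] * rois$radius[i])^2)
    if (length(idx) == 0L)
      stop_domain(sprintf("ROI for droplet %d has an empty measurement disk",
                          rois$droplet_id[i]))
    out[[i]] <- tibble::tibble(
      droplet_id = rois$droplet_id[i],
      time_h = as.numeric(times),
      raw_mean_intensity = colMeans(flat[idx, , drop = FALSE]),
      pixel_count = length(idx))
  }
  do.call(rbind, out)
}
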