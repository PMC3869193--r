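# Microcolony counting: inside the measurement disk, pixels darker than a
# fraction of the median in-disk intensity are segmented into 8-connected
# components; components below an area floor are discarded. The threshold
# is relative to the droplet's own median so that per-droplet illumination
# differences (which normalization removes from the time series) do not
# bias the segmentation.

#' Count microcolonies in a single frame
#'
#' @param frame A single frame matrix (gray levels).
#' @param roi A one-row [droplet_roi()] for the droplet.
#' @param min_area Minimum component area in pixels (default 20).
#' @param rel_threshold Fraction of the median in-disk intensity below
#'   which a pixel counts as colony (default 0.85).
#' @return A list with `count` and `centroids` (tibble `label`, `row`,
#'   `col`, `area`; 0-based pixel coordinates). A blank droplet gives
#'   `count = 0`.
#' @examples
#' f <- matrix(200, 64, 64); f[20:26, 20:26] <- 40
#' count_microcolonies(f, droplet_roi(1, 31.5, 31.5, 30))$count
#' @export
count_microcolonies <- function(frame, roi, min_area = 20,
                                rel_threshold = 0.85) {
  if (!is.matrix(frame)) stop_domain("`frame` must be a single frame matrix")
  stopifnot(is.data.frame(roi), nrow(roi) == 1L)
  check_number(min_area, "min_area", lower = 1)
  check_number(rel_threshold, "rel_threshold", lower = 0, upper = 1)
  d2 <- frame_dist2(dim(frame), roi$center_row, roi$center_col)
  disk <- d2 <= (roi$shrink_factor * roi$radius)^2
  if (!any(disk)) stop_domain("ROI has an empty measurement disk")
  med <- median(frame[disk])
  mask <- disk & (frame < rel_threshold * med)
  lab <- label_components(mask)
  if (max(lab) == 0L)
    return(list(count = 0L,
                centroids = tibble::tibble(label = integer(0),
                                           row = numeric(0), col = numeric(0),
                                           area = integer(0))))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  cent <- lapply(seq_along(keep), function(i) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    tibble::tibble(label = i, row = mean(idx[, 1] - 1),
                   col = mean(idx[, 2] - 1), area = nrow(idx))
  })
  list(count = length(keep),
       centroids = if (length(keep)) do.call(rbind, cent)
                   else tibble::tibble(label = integer(0), row = numeric(0),
                                       col = numeric(0), area = integer(0)))
}

#' Label 8-connected components in a binary mask
#'
#' Run-based two-pass labeling with union-find: vertical runs per column
#' are merged across adjacent columns when they overlap or touch
#' diagonally (8-connectivity).
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop_domain("`mask` must be a matrix")
  mode(mask) <- "logical"
  H <- nrow(mask); W <- ncol(mask)
  run_s <- integer(0); run_e <- integer(0); run_c <- integer(0)
  parent <- integer(0)
  prev_ids <- integer(0)
  for (cc in seq_len(W)) {
    v <- mask[, cc]
    cur_ids <- integer(0)
    if (any(v)) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        id <- length(parent) + 1L
        parent[id] <- id
        run_s[id] <- starts[k]; run_e[id] <- ends[k]; run_c[id] <- cc
        cur_ids <- c(cur_ids, id)
        for (pid in prev_ids) {
          # touch with +/- 1 row slack: diagonal adjacency counts
          if (run_s[pid] <= ends[k] + 1L && run_e[pid] >= starts[k] - 1L) {
            a <- id; b <- pid
            while (parent[a] != a) a <- parent[a]
            while (parent[b] != b) b <- parent[b]
            if (a != b) parent[max(a, b)] <- min(a, b)
          }
        }
      }
    }
    prev_ids <- cur_ids
  }
  n <- length(parent)
  lab <- matrix(0L, H, W)
  if (n == 0L) return(lab)
  root <- integer(n)
  for (i in seq_len(n)) {
    a <- i
    while (parent[a] != a) a <- parent[a]
    root[i] <- a
  }
  labels <- match(root, unique(root))
  for (i in seq_len(n)) lab[run_s[i]:run_e[i], run_c[i]] <- labels[i]
  lab
}
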