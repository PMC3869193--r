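# Growth statistics on transmission time series. The raw mean intensity
# of each droplet is normalized to its initial value (so every curve
# starts at 1 and per-droplet illumination differences drop out); the
# threshold growth time is the first time the normalized curve intersects
# 0.99, found by linear interpolation between frames. Growth/no-growth
# classification adds a sustained-drop guard against single-frame noise
# dips, and rebound detection flags the post-peak brightening typical of
# sporulating droplets. Smoothing (a centered moving median, window 3) is
# applied only inside classification and rebound detection, never before
# thresholding: the threshold is taken on the raw normalized curve.

#' Normalize a transmission curve to its initial value
#'
#' Divides every value by the mean of the first `baseline_frames` values;
#' with the default single baseline frame, the first normalized value is
#' exactly 1.
#'
#' @param x Numeric vector of raw mean intensities, or a series tibble
#'   with columns `droplet_id` and `raw_mean_intensity` (normalized per
#'   droplet; a `normalized` column is added).
#' @param baseline_frames Number of leading frames averaged as baseline
#'   (default 1).
#' @return Normalized numeric vector, or the tibble with a `normalized`
#'   column.
#' @examples
#' normalize_curve(c(200, 100, 50))   # 1, 0.5, 0.25
#' @export
normalize_curve <- function(x, baseline_frames = 1) {
  check_number(baseline_frames, "baseline_frames", lower = 1,
               integerish = TRUE)
  if (is.data.frame(x)) {
    stopifnot(all(c("droplet_id", "raw_mean_intensity") %in% names(x)))
    x$normalized <- stats::ave(x$raw_mean_intensity, x$droplet_id,
                               FUN = function(v)
                                 normalize_curve(v, baseline_frames))
    return(x)
  }
  if (!is.numeric(x) || length(x) == 0L)
    stop_domain("`x` must be a non-empty numeric series")
  if (baseline_frames > length(x))
    stop_domain("`baseline_frames` exceeds the series length")
  base <- mean(x[seq_len(baseline_frames)])
  if (!is.finite(base) || base <= 0)
    stop_domain("cannot normalize: baseline mean is zero or negative")
  x / base
}

check_normalized <- function(values) {
  if (abs(values[1] - 1) > 1e-9)
    stop_domain("curve is not normalized: first value must be 1 (use normalize_curve())")
}

#' Threshold growth time of a normalized curve
#'
#' The time at which the normalized transmission first intersects the
#' threshold (default 0.99): the first frame pair with `value[i-1] >=
#' threshold > value[i]` defines a linear-interpolation crossing between
#' the two timestamps. Returns `NA` if the curve never falls below the
#' threshold.
#'
#' @param values Normalized curve (first value must be 1).
#' @param times Timestamps in hours, strictly increasing.
#' @param threshold Crossing level (default 0.99).
#' @return Crossing time in hours, or `NA_real_`.
#' @examples
#' threshold_growth_time(c(1, 0.98), c(0, 1))   # 0.5
#' @export
threshold_growth_time <- function(values, times, threshold = 0.99) {
  stopifnot(length(values) == length(times), all(diff(times) > 0))
  check_number(threshold, "threshold", lower = 0, upper = 1)
  check_normalized(values)
  below <- values < threshold
  above <- c(TRUE, values[-length(values)] >= threshold)
  i <- which(below & above)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1]
  if (i == 1L) return(times[1])  # only if threshold = 1 exactly
  frac <- (values[i - 1] - threshold) / (values[i - 1] - values[i])
  times[i - 1] + frac * (times[i] - times[i - 1])
}

# centered moving median, window 3
smooth3 <- function(x) {
  if (length(x) < 3L) return(x)
  stats::runmed(x, 3, endrule = "median")
}

#' Classify a droplet as grown or not
#'
#' A droplet grew iff its raw normalized curve crossed the threshold and
#' the smoothed curve ends at least `min_final_drop` below 1 — the
#' sustained-drop guard that rejects single-frame noise dips.
#'
#' @inheritParams threshold_growth_time
#' @param min_final_drop Required final drop of the smoothed curve
#'   (default 0.05).
#' @return Logical flag.
#' @export
classify_growth <- function(values, times, threshold = 0.99,
                            min_final_drop = 0.05) {
  check_number(min_final_drop, "min_final_drop", lower = 0, upper = 1)
  crossed <- !is.na(threshold_growth_time(values, times, threshold))
  final_sm <- tail(smooth3(values), 1)
  crossed && (final_sm <= 1 - min_final_drop)
}

#' Detect a post-peak transmission rebound
#'
#' Locates the global minimum of the smoothed curve; the droplet rebounds
#' if the curve thereafter rises by at least `min_rise` and stays above
#' `minimum + min_rise / 2` for at least `min_frames` consecutive frames.
#' The onset is the time of the minimum. Intended for droplets already
#' classified as grown.
#'
#' @inheritParams threshold_growth_time
#' @param min_rise Required rise above the minimum (default 0.05).
#' @param min_frames Required persistence in frames (default 6).
#' @return A list with `rebound` (logical) and `onset_h` (hours, `NA` if
#'   no rebound).
#' @export
detect_rebound <- function(values, times, min_rise = 0.05, min_frames = 6) {
  stopifnot(length(values) == length(times))
  check_number(min_rise, "min_rise", lower = 0)
  check_number(min_frames, "min_frames", lower = 1, integerish = TRUE)
  sm <- smooth3(values)
  i0 <- which.min(sm)
  if (i0 >= length(sm))
    return(list(rebound = FALSE, onset_h = NA_real_))
  after <- sm[(i0 + 1):length(sm)]
  m <- sm[i0]
  rises <- any(after >= m + min_rise)
  runs <- rle(after > m + min_rise / 2)
  persists <- any(runs$lengths[runs$values] >= min_frames)
  if (rises && persists)
    list(rebound = TRUE, onset_h = times[i0])
  else
    list(rebound = FALSE, onset_h = NA_real_)
}

#' Analyze all droplet series into growth results
#'
#' Normalizes each droplet's series, finds its threshold growth time,
#' classifies growth, and (for grown droplets) detects a rebound.
#'
#' @param series Series tibble (`droplet_id`, `time_h`,
#'   `raw_mean_intensity`), e.g. from [extract_transmission()] or
#'   [simulate_experiment()].
#' @param groups Optional tibble mapping `droplet_id` to a `group` label
#'   (e.g. the nominal cells per droplet).
#' @param threshold Crossing level (default 0.99).
#' @param baseline_frames Leading frames for the normalization baseline.
#' @param min_final_drop Sustained-drop guard for [classify_growth()].
#' @param min_rise,min_frames Rebound parameters for [detect_rebound()].
#' @return A tibble with one row per droplet: `droplet_id`, `group`,
#'   `grew`, `threshold_time_h`, `rebound`, `rebound_onset_h`. The
#'   threshold time is `NA` exactly when `grew` is `FALSE`.
#' @export
analyze_droplets <- function(series, groups = NULL, threshold = 0.99,
                             baseline_frames = 1, min_final_drop = 0.05,
                             min_rise = 0.05, min_frames = 6) {
  stopifnot(is.data.frame(series),
            all(c("droplet_id", "time_h", "raw_mean_intensity") %in%
                  names(series)))
  ids <- unique(series$droplet_id)
  rows <- lapply(ids, function(id) {
    s <- series[series$droplet_id == id, ]
    s <- s[order(s$time_h), ]
    v <- normalize_curve(s$raw_mean_intensity, baseline_frames)
    tt <- threshold_growth_time(v, s$time_h, threshold)
    grew <- classify_growth(v, s$time_h, threshold, min_final_drop)
    if (!grew) tt <- NA_real_  # grew == TRUE iff threshold_time present
    rb <- if (grew) detect_rebound(v, s$time_h, min_rise, min_frames)
          else list(rebound = FALSE, onset_h = NA_real_)
    tibble::tibble(droplet_id = id, grew = grew, threshold_time_h = tt,
                   rebound = rb$rebound, rebound_onset_h = rb$onset_h)
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) {
    stopifnot(all(c("droplet_id", "group") %in% names(groups)))
    out$group <- groups$group[match(out$droplet_id, groups$droplet_id)]
  } else {
    out$group <- NA
  }
  out[, c("droplet_id", "group", "grew", "threshold_time_h",
          "rebound", "rebound_onset_h")]
}
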