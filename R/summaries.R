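# Per-concentration summaries of threshold growth times (box-plot
# statistics, Tukey convention) and the linear dependence of threshold
# time on the log10 inoculum, the signature of exponential growth to a
# fixed detection level.

#' Summarize threshold growth times per group
#'
#' Per group: droplet counts, median and quartiles (linear-interpolation
#' quantile convention, R type 7) of the threshold times of grown
#' droplets, Tukey whiskers (most extreme values within 1.5 IQR of the
#' quartiles) and outliers beyond them. A group in which nothing grew
#' yields `n_grew = 0` with `NA` statistics — not an error.
#'
#' @param results Growth-results tibble with columns `group`, `grew`,
#'   `threshold_time_h` (see [analyze_droplets()]).
#' @return A tibble with one row per group: `group`, `n`, `n_grew`,
#'   `median_h`, `q1_h`, `q3_h`, `whisker_low_h`, `whisker_high_h`, and a
#'   list-column `outliers_h`.
#' @examples
#' r <- tibble::tibble(group = "marine", grew = TRUE,
#'                     threshold_time_h = c(10.51, 11.02, 11.16,
#'                                          9.43, 9.48, 15.37))
#' summarize_groups(r)$median_h   # 10.765
#' @export
summarize_groups <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("group", "threshold_time_h") %in% names(results)))
  if (!"grew" %in% names(results))
    results$grew <- !is.na(results$threshold_time_h)
  groups <- unique(results$group)
  rows <- lapply(groups, function(g) {
    sel <- results$group %in% g
    x <- results$threshold_time_h[sel & results$grew]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(tibble::tibble(group = g, n = sum(sel), n_grew = 0L,
                            median_h = NA_real_, q1_h = NA_real_,
                            q3_h = NA_real_, whisker_low_h = NA_real_,
                            whisker_high_h = NA_real_,
                            outliers_h = list(numeric(0))))
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    tibble::tibble(group = g, n = sum(sel), n_grew = length(x),
                   median_h = q[2], q1_h = q[1], q3_h = q[3],
                   whisker_low_h = min(inside), whisker_high_h = max(inside),
                   outliers_h = list(sort(x[x < lo_fence | x > hi_fence])))
  })
  do.call(rbind, rows)
}

#' Fit threshold time against log10 inoculum
#'
#' Least-squares fit of the threshold growth time against the base-10
#' logarithm of the nominal cells per droplet, over grown droplets.
#' For exponential growth at rate \eqn{\mu} to a fixed detection level
#' the slope is \eqn{-\ln(10)/\mu} hours per decade.
#'
#' @param results Growth-results tibble; `group` must be the nominal
#'   cells per droplet (numeric, > 0), or supply `cells_per_droplet`.
#' @param cells_per_droplet Optional numeric vector (one per result row)
#'   overriding `group` as the inoculum.
#' @return A list with `slope_h_per_decade`, `intercept_h`, `n`, and the
#'   underlying `fit` (an `lm`).
#' @export
fit_threshold_vs_log_inoculum <- function(results, cells_per_droplet = NULL) {
  stopifnot(is.data.frame(results), "threshold_time_h" %in% names(results))
  cpd <- if (is.null(cells_per_droplet)) {
    suppressWarnings(as.numeric(results$group))
  } else cells_per_droplet
  keep <- !is.na(results$threshold_time_h) & !is.na(cpd) & cpd > 0
  x <- log10(cpd[keep])
  y <- results$threshold_time_h[keep]
  if (length(unique(x)) < 2L)
    stop_domain("need grown droplets at >= 2 distinct nonzero inoculum levels")
  fit <- lm(y ~ x)
  list(slope_h_per_decade = unname(coef(fit)[2]),
       intercept_h = unname(coef(fit)[1]),
       n = length(y), fit = fit)
}
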