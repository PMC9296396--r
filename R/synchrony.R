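#' Synchrony computation settings
#'
#' Controls the moving-window lagged cross-correlation. Defaults follow the
#' method family's standard choices: 60-second windows over lags of up to
#' +/- 5 seconds at single-frame resolution, with a 30-second stride (50%
#' window overlap).
#'
#' @param window_s window length in seconds (default 60).
#' @param step_s stride between window starts in seconds (default 30).
#' @param max_lag_s largest lead/lag examined, in seconds (default 5).
#' @param lag_step_frames lag grid increment in frames (default 1, i.e.
#'   0.04 s at 25 fps; coarser grids trade resolution for speed).
#' @param r_clip correlations are clipped to `[-r_clip, r_clip]` before the
#'   Fisher transform so perfect correlation stays finite.
#' @param min_valid_cells minimum number of defined window-by-lag cells
#'   required to report a synchrony value.
#' @param smooth_s optional moving-average smoothing of the input series in
#'   seconds (0 = none, the default).
#' @return An object of class `sync_config`.
#' @export
sync_config <- function(window_s = 60, step_s = 30, max_lag_s = 5,
                        lag_step_frames = 1L, r_clip = 1 - 1e-7,
                        min_valid_cells = 1L, smooth_s = 0) {
  if (window_s <= 0 || step_s <= 0 || max_lag_s < 0) {
    stop("window_s and step_s must be positive, max_lag_s nonnegative", call. = FALSE)
  }
  if (lag_step_frames < 1) stop("'lag_step_frames' must be >= 1", call. = FALSE)
  if (r_clip <= 0 || r_clip >= 1) stop("'r_clip' must lie in (0, 1)", call. = FALSE)
  if (min_valid_cells < 1) stop("'min_valid_cells' must be >= 1", call. = FALSE)
  structure(list(window_s = window_s, step_s = step_s, max_lag_s = max_lag_s,
                 lag_step_frames = as.integer(lag_step_frames), r_clip = r_clip,
                 min_valid_cells = as.integer(min_valid_cells), smooth_s = smooth_s),
            class = "sync_config")
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
}

#' Moving-window lagged cross-correlation of two series
#'
#' For every window start (stride `step_s`) and every lag on the grid
#' `-max_lag_s .. +max_lag_s`, computes the Pearson correlation between the
#' windowed segment of series A and the lag-shifted segment of series B. A
#' positive lag pairs `A[t]` with `B[t + lag]`, i.e. B trailing A. Shifted
#' segments are truncated to the overlap inside the window (no padding), so
#' a lag-`l` cell correlates `window - |l|` frame pairs. Windows in which
#' either segment has zero variance yield `NA`, never 0: Pearson is
#' undefined there and coding it as 0 would bias the aggregate downward.
#'
#' @param series_a,series_b [motion_energy_series] (or numeric vectors, with
#'   `fps` supplied) of equal length and frame rate, at least one window long.
#' @param config a [sync_config].
#' @param fps frame rate, required only when plain vectors are given.
#' @return An object of class `crosscorr_matrix`: list with `r` (windows x
#'   lags matrix), `lags_frames`, `window_starts_frames`, `fps`.
#' @export
windowed_crosscorr <- function(series_a, series_b, config = sync_config(), fps = NULL) {
  fa <- me_fps(series_a, fps); fb <- me_fps(series_b, fps)
  if (is.null(fa) || is.null(fb)) stop("supply 'fps' when passing plain vectors", call. = FALSE)
  if (!isTRUE(all.equal(fa, fb))) stop("frame-rate mismatch between series", call. = FALSE)
  x <- as_me_values(series_a); y <- as_me_values(series_b)
  if (length(x) != length(y)) stop("series length mismatch", call. = FALSE)
  if (config$smooth_s > 0) {
    k <- max(1L, as.integer(round(config$smooth_s * fa)))
    x <- moving_average(x, k); y <- moving_average(y, k)
  }
  n <- length(x)
  w <- as.integer(round(config$window_s * fa))
  if (w < 4L) stop("window shorter than 4 frames", call. = FALSE)
  if (n < w) stop(sprintf("series (%d frames) shorter than one %d-frame window", n, w),
                  call. = FALSE)
  step <- max(1L, as.integer(round(config$step_s * fa)))
  maxlag <- as.integer(round(config$max_lag_s * fa))
  lags <- seq.int(-maxlag, maxlag, by = config$lag_step_frames)
  if (!0L %in% lags) lags <- sort(unique(c(lags, 0L)))
  starts <- seq.int(1L, n - w + 1L, by = step)

  r <- matrix(NA_real_, nrow = length(starts), ncol = length(lags),
              dimnames = list(window = NULL, lag = lags))
  for (wi in seq_along(starts)) {
    s0 <- starts[[wi]]; s1 <- s0 + w - 1L
    for (li in seq_along(lags)) {
      l <- lags[[li]]
      t0 <- max(s0, s0 - l); t1 <- min(s1, s1 - l)
      if (t1 - t0 + 1L < 4L) next
      xa <- x[t0:t1]; yb <- y[(t0 + l):(t1 + l)]
      if (anyNA(xa) || anyNA(yb)) next
      sa <- sd(xa); sb <- sd(yb)
      if (sa == 0 || sb == 0) next
      r[wi, li] <- cor(xa, yb)
    }
  }
  structure(list(r = r, lags_frames = lags, window_starts_frames = starts,
                 fps = fa),
            class = "crosscorr_matrix")
}

#' @export
print.crosscorr_matrix <- function(x, ...) {
  cat(sprintf("<crosscorr_matrix> %d windows x %d lags (%+d..%+d frames @ %g fps), %d NA cells\n",
              nrow(x$r), ncol(x$r), min(x$lags_frames), max(x$lags_frames),
              x$fps, sum(is.na(x$r))))
  invisible(x)
}

#' Fisher Z transform of correlations
#'
#' `atanh` of the correlation, variance-stabilising so correlations can be
#' averaged. Values are clipped to `[-r_clip, r_clip]` first so that perfect
#' correlations (exactly +/-1, as arise in degenerate synthetic cases) map to
#' a large finite value instead of infinity. `NA` propagates.
#'
#' @param r correlations in `[-1, 1]` (vector or matrix).
#' @param r_clip clip bound in (0, 1); default `1 - 1e-7`.
#' @return Transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, r_clip = 1 - 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations outside [-1, 1]", call. = FALSE)
  }
  atanh(pmin(pmax(r, -r_clip), r_clip))
}

#' Aggregate a cross-correlation matrix into one synchrony value
#'
#' Interpersonal synchrony (IPS) is the mean over all defined window-by-lag
#' cells of the absolute Fisher-Z-transformed correlation. Taking absolute
#' values after the transform counts in-phase and anti-phase coordination
#' alike; the mean runs over the whole recording, yielding one scalar per
#' dyad and ROI.
#'
#' @param mat a [windowed_crosscorr] result.
#' @param config a [sync_config] (supplies `r_clip` and `min_valid_cells`).
#' @param dyad_id,roi_label labels carried on the result.
#' @return An object of class `synchrony_value`: list with `ips`,
#'   `n_cells_used`, `dyad_id`, `roi_label`.
#' @export
aggregate_ips <- function(mat, config = sync_config(), dyad_id = NA_character_,
                          roi_label = NA_character_) {
  if (!inherits(mat, "crosscorr_matrix")) stop("'mat' must be a crosscorr_matrix", call. = FALSE)
  z <- abs(fisher_z(mat$r, config$r_clip))
  n_used <- sum(!is.na(z))
  if (n_used < config$min_valid_cells) {
    stop(sprintf("only %d defined correlation cells (need >= %d)",
                 n_used, config$min_valid_cells), call. = FALSE)
  }
  structure(list(ips = mean(z, na.rm = TRUE), n_cells_used = n_used,
                 dyad_id = as.character(dyad_id), roi_label = as.character(roi_label)),
            class = "synchrony_value")
}

#' @export
print.synchrony_value <- function(x, ...) {
  cat(sprintf("<synchrony_value> dyad=%s roi=%s  ips=%.4f (%d cells)\n",
              x$dyad_id, x$roi_label, x$ips, x$n_cells_used))
  invisible(x)
}

#' Interpersonal synchrony of one series pair
#'
#' Convenience wrapper: [windowed_crosscorr] followed by [aggregate_ips],
#' returning the scalar IPS.
#'
#' @inheritParams windowed_crosscorr
#' @return A single nonnegative number.
#' @export
dyad_ips <- function(series_a, series_b, config = sync_config(), fps = NULL) {
  aggregate_ips(windowed_crosscorr(series_a, series_b, config, fps), config)$ips
}

#' Frame-wise total-body series
#'
#' Adds the head and upper-body series of one person. The two ROIs are
#' disjoint, so their changed-pixel counts are additive and the sum is the
#' person's whole-upper-body motion energy.
#'
#' @param head,body [motion_energy_series] of the same person, length and
#'   frame rate.
#' @return A [motion_energy_series] labelled `"total"`.
#' @export
total_roi_series <- function(head, body) {
  stopifnot(inherits(head, "motion_energy_series"), inherits(body, "motion_energy_series"))
  if (!is.na(head$person_id) && !is.na(body$person_id) &&
      !identical(head$person_id, body$person_id)) {
    stop("series belong to different persons", call. = FALSE)
  }
  if (length(head$values) != length(body$values)) stop("length mismatch", call. = FALSE)
  if (!isTRUE(all.equal(head$fps, body$fps))) stop("frame-rate mismatch", call. = FALSE)
  area <- if (is.na(head$roi_area) || is.na(body$roi_area)) NA_real_
          else head$roi_area + body$roi_area
  motion_energy_series(head$values + body$values, head$fps, head$person_id,
                       "total", area)
}

#' Combine the synchrony values of a split vignette
#'
#' When a recording had to be split (e.g. the interaction was interrupted
#' midway), synchrony is computed per part and the parts averaged with equal
#' weight; the defined-cell counts are summed.
#'
#' @param ips_part1,ips_part2 [aggregate_ips] results for the same dyad and
#'   ROI.
#' @return A single `synchrony_value`.
#' @export
combine_split_vignette <- function(ips_part1, ips_part2) {
  stopifnot(inherits(ips_part1, "synchrony_value"), inherits(ips_part2, "synchrony_value"))
  same <- function(a, b) is.na(a) || is.na(b) || identical(a, b)
  if (!same(ips_part1$dyad_id, ips_part2$dyad_id)) {
    stop("parts belong to different dyads", call. = FALSE)
  }
  if (!same(ips_part1$roi_label, ips_part2$roi_label)) {
    stop("parts belong to different ROIs", call. = FALSE)
  }
  structure(list(ips = (ips_part1$ips + ips_part2$ips) / 2,
                 n_cells_used = ips_part1$n_cells_used + ips_part2$n_cells_used,
                 dyad_id = ips_part1$dyad_id, roi_label = ips_part1$roi_label),
            class = "synchrony_value")
}
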