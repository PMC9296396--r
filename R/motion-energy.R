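#' Region-of-interest mask
#'
#' A fixed rectangular region covering one person's head or upper body in a
#' statically framed recording. Coordinates are 0-based pixel coordinates
#' with `x` the column and `y` the row; the rectangle is half-open, i.e. it
#' covers columns `x0 .. x0 + width - 1` and rows `y0 .. y0 + height - 1`.
#' Head and body ROIs of the same person must not overlap (their motion
#' energies are additive).
#'
#' @param person_id identifier of the person.
#' @param label ROI label, `"head"` or `"body"`.
#' @param x0,y0 top-left corner (0-based, column / row).
#' @param width,height rectangle extent in pixels (>= 1).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(person_id, label = c("head", "body"), x0, y0, width, height) {
  label <- match.arg(label)
  dims <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (any(!is.finite(dims)) || any(dims != round(dims))) {
    stop("ROI coordinates must be integers", call. = FALSE)
  }
  if (x0 < 0 || y0 < 0 || width < 1 || height < 1) {
    stop("ROI must have nonnegative origin and positive extent", call. = FALSE)
  }
  structure(list(person_id = as.character(person_id), label = label,
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_mask")
}

roi_area <- function(mask) mask$width * mask$height

roi_rows <- function(mask) (mask$y0 + 1L):(mask$y0 + mask$height)
roi_cols <- function(mask) (mask$x0 + 1L):(mask$x0 + mask$width)

rects_overlap <- function(a, b) {
  (a$x0 < b$x0 + b$width) && (b$x0 < a$x0 + a$width) &&
    (a$y0 < b$y0 + b$height) && (b$y0 < a$y0 + a$height)
}

check_masks <- function(masks, frame_dim) {
  for (m in masks) {
    if (m$y0 + m$height > frame_dim[1L] || m$x0 + m$width > frame_dim[2L]) {
      stop(sprintf("ROI %s/%s exceeds the %dx%d frame",
                   m$person_id, m$label, frame_dim[2L], frame_dim[1L]),
           call. = FALSE)
    }
  }
  n <- length(masks)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (identical(masks[[i]]$person_id, masks[[j]]$person_id) &&
          rects_overlap(masks[[i]], masks[[j]])) {
        stop(sprintf("ROIs of person %s overlap (%s vs %s); head and body must be disjoint",
                     masks[[i]]$person_id, masks[[i]]$label, masks[[j]]$label),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Motion-energy extraction settings
#'
#' @param threshold grayscale difference threshold in 0--255 units; pixel
#'   changes must strictly exceed it to count as movement. The default 15
#'   filters sensor/lighting fluctuation while keeping genuine motion.
#' @param fps frame rate of the recording (default 25).
#' @param value what a frame difference reports: `"count"` (number of
#'   super-threshold pixels, the default, bounded by ROI area) or `"sum"`
#'   (sum of absolute grayscale differences over super-threshold pixels).
#'   Downstream synchrony is correlation-based and therefore insensitive to
#'   this choice up to monotone scale.
#' @return An object of class `me_config`.
#' @export
me_config <- function(threshold = 15, fps = 25, value = c("count", "sum")) {
  value <- match.arg(value)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255) {
    stop("'threshold' must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("'fps' must be positive", call. = FALSE)
  structure(list(threshold = threshold, fps = fps, value = value),
            class = "me_config")
}

# 2-D grayscale matrix (rows x cols, 0-255) from a matrix or an RGB(A) array,
# via the Rec.601 luma transform
as_gray_frame <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    d3 <- dim(frame)[3L]
    if (d3 >= 3L) {
      return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
    }
    return(frame[, , 1L])
  }
  stop("frame must be a matrix or an array with channels in the 3rd dimension",
       call. = FALSE)
}

#' Thresholded frame difference within one ROI
#'
#' The elementary motion-energy operation: the number of pixels inside the
#' mask whose absolute grayscale change between two consecutive frames
#' strictly exceeds the threshold (or, with `value = "sum"`, the summed
#' absolute change over those pixels).
#'
#' @param frame_prev,frame_curr grayscale frames (matrices, 0--255) of equal
#'   size.
#' @param mask a [roi_mask] lying within the frame.
#' @param config an [me_config].
#' @return A single nonnegative number.
#' @export
frame_difference <- function(frame_prev, frame_curr, mask, config = me_config()) {
  frame_prev <- as_gray_frame(frame_prev)
  frame_curr <- as_gray_frame(frame_curr)
  if (!identical(dim(frame_prev), dim(frame_curr))) {
    stop("frames differ in shape", call. = FALSE)
  }
  check_masks(list(mask), dim(frame_prev))
  d <- abs(frame_curr[roi_rows(mask), roi_cols(mask), drop = FALSE] -
             frame_prev[roi_rows(mask), roi_cols(mask), drop = FALSE])
  hit <- d > config$threshold
  if (config$value == "count") sum(hit) else sum(d[hit])
}

# normalise video input to a list of grayscale matrices
video_frames <- function(video) {
  if (is.character(video) && length(video) == 1L && dir.exists(video)) {
    files <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2L) stop("need at least 2 PNG frames in ", video, call. = FALSE)
    return(lapply(seq_along(files), function(i) {
      img <- tryCatch(png::readPNG(files[[i]]),
                      error = function(e) stop(sprintf(
                        "unreadable video frame %d (%s): %s", i, files[[i]],
                        conditionMessage(e)), call. = FALSE))
      as_gray_frame(img * 255)
    }))
  }
  if (is.array(video) && length(dim(video)) == 3L) {
    return(lapply(seq_len(dim(video)[3L]), function(i) video[, , i]))
  }
  if (is.list(video)) return(lapply(video, as_gray_frame))
  stop("'video' must be a PNG frame directory, a h x w x n array, or a list of frames",
       call. = FALSE)
}

#' Extract motion-energy series from a frame sequence
#'
#' Applies [frame_difference] to every consecutive frame pair for every ROI,
#' yielding one [motion_energy_series] per mask. A sequence of `n` frames
#' gives series of length `n - 1`. The camera is assumed static; no
#' registration is performed.
#'
#' @param video a `height x width x n_frames` array of grayscale values
#'   (0--255), a list of frames, or the path of a directory of PNG frames
#'   (lexicographic frame order).
#' @param masks list of [roi_mask]; same-person masks must be disjoint.
#' @param config an [me_config].
#' @return A named list of [motion_energy_series] (names
#'   `<person_id>_<label>`).
#' @export
extract_series <- function(video, masks, config = me_config()) {
  frames <- video_frames(video)
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  check_masks(masks, dim(frames[[1L]]))
  n <- length(frames)
  out <- lapply(masks, function(m) {
    vals <- numeric(n - 1L)
    for (i in 2L:n) {
      vals[i - 1L] <- frame_difference(frames[[i - 1L]], frames[[i]], m, config)
    }
    motion_energy_series(vals, config$fps, m$person_id, m$label,
                         roi_area = if (config$value == "count") roi_area(m) else NA_real_)
  })
  names(out) <- vapply(masks, function(m) paste0(m$person_id, "_", m$label), character(1L))
  out
}

#' Movement quantity of one series
#'
#' The fraction of frames showing any above-threshold movement: the number of
#' entries strictly greater than zero divided by the series length. Used as
#' an overall-activity covariate so that synchrony differences can be
#' disentangled from sheer movement differences.
#'
#' @param series a [motion_energy_series] or numeric vector.
#' @return A proportion in \[0, 1\].
#' @export
movement_quantity <- function(series) {
  v <- as_me_values(series)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  mean(v > 0)
}

#' Dyad-level movement quantity
#'
#' Mean of the two interactants' movement quantities for the same ROI,
#' summarising a dyad's overall activity level.
#'
#' @param series_a,series_b [motion_energy_series] with matching ROI labels.
#' @return A proportion in \[0, 1\].
#' @export
dyad_movement <- function(series_a, series_b) {
  la <- if (inherits(series_a, "motion_energy_series")) series_a$roi_label else NA
  lb <- if (inherits(series_b, "motion_energy_series")) series_b$roi_label else NA
  if (!is.na(la) && !is.na(lb) && !identical(la, lb)) {
    stop(sprintf("ROI mismatch: '%s' vs '%s'", la, lb), call. = FALSE)
  }
  (movement_quantity(series_a) + movement_quantity(series_b)) / 2
}

#' Read ROI masks from a YAML or JSON sidecar
#'
#' The sidecar holds a list of entries with fields `person`, `label`, and
#' `rect` (`[x0, y0, width, height]`, 0-based).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A list of [roi_mask].
#' @export
read_roi_masks <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(e) {
    roi_mask(e$person, e$label, e$rect[[1L]], e$rect[[2L]], e$rect[[3L]], e$rect[[4L]])
  })
}
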