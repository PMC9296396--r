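#' Motion-energy time series
#'
#' A per-frame record of movement magnitude for one person and one region of
#' interest (ROI), sampled at a fixed frame rate. Values are nonnegative; when
#' extracted from video they are counts of super-threshold changed pixels, so
#' a series derived from `n` frames has `n - 1` entries and every entry is
#' bounded by the ROI pixel area.
#'
#' @param values numeric vector of nonnegative per-frame movement values.
#' @param fps frames per second of the source recording (> 0).
#' @param person_id identifier of the person the ROI belongs to.
#' @param roi_label ROI label, conventionally `"head"`, `"body"` or `"total"`.
#' @param roi_area pixel area of the ROI, or `NA` when unknown (e.g. for
#'   synthetic series); when given, all values must be `<= roi_area`.
#'
#' @return An object of class `motion_energy_series`.
#' @export
motion_energy_series <- function(values, fps, person_id = NA_character_,
                                 roi_label = NA_character_, roi_area = NA_real_) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values))) {
    stop("'values' must be a nonempty finite numeric vector", call. = FALSE)
  }
  if (any(values < 0)) stop("motion-energy values must be nonnegative", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("'fps' must be a single positive number", call. = FALSE)
  }
  if (!is.na(roi_area) && any(values > roi_area + 1e-9)) {
    stop("motion-energy values exceed the ROI pixel area", call. = FALSE)
  }
  structure(
    list(values = values, fps = fps,
         person_id = as.character(person_id),
         roi_label = as.character(roi_label),
         roi_area = roi_area),
    class = "motion_energy_series"
  )
}

#' @export
length.motion_energy_series <- function(x) length(x$values)

#' @export
print.motion_energy_series <- function(x, ...) {
  cat(sprintf("<motion_energy_series> person=%s roi=%s  %d frames @ %g fps\n",
              x$person_id, x$roi_label, length(x$values), x$fps))
  cat(sprintf("  mean %.3f  max %.3f  nonzero %.1f%%\n",
              mean(x$values), max(x$values), 100 * mean(x$values > 0)))
  invisible(x)
}

as_me_values <- function(x) {
  if (inherits(x, "motion_energy_series")) x$values else as.numeric(x)
}

me_fps <- function(x, fps = NULL) {
  if (inherits(x, "motion_energy_series")) x$fps else fps
}

#' Dyadic recording session
#'
#' Bundles the motion-energy series of the two interactants of one recorded
#' vignette, the unit at which interpersonal synchrony is computed. Series are
#' stored in a named list with keys `personA_head`, `personA_body`,
#' `personB_head`, `personB_body` (any subset of ROIs is allowed, but both
#' persons must carry the same ROI labels).
#'
#' @param dyad_id identifier of the dyad.
#' @param group group label (e.g. `"ASD_plus"` / `"ASD_minus"`).
#' @param series named list of [motion_energy_series] objects.
#' @return An object of class `dyad_session`.
#' @export
dyad_session <- function(dyad_id, group = NA_character_, series = list()) {
  if (length(series) == 0L) stop("'series' must be a nonempty named list", call. = FALSE)
  keys <- names(series)
  ok <- grepl("^person[AB]_", keys)
  if (is.null(keys) || !all(ok)) {
    stop("series names must look like 'personA_head', 'personB_body', ...", call. = FALSE)
  }
  rois_a <- sort(sub("^personA_", "", keys[grepl("^personA_", keys)]))
  rois_b <- sort(sub("^personB_", "", keys[grepl("^personB_", keys)]))
  if (!identical(rois_a, rois_b)) {
    stop("both interactants must carry the same set of ROI labels", call. = FALSE)
  }
  structure(list(dyad_id = as.character(dyad_id), group = as.character(group),
                 series = series, rois = rois_a),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  n <- length(x$series[[1L]]$values)
  cat(sprintf("<dyad_session> %s (group %s): ROIs %s, %d frames @ %g fps\n",
              x$dyad_id, x$group, paste(x$rois, collapse = "/"), n,
              x$series[[1L]]$fps))
  invisible(x)
}

session_series <- function(session, person, roi) {
  key <- paste0("person", person, "_", roi)
  s <- session$series[[key]]
  if (is.null(s)) stop(sprintf("session %s has no series '%s'", session$dyad_id, key),
                       call. = FALSE)
  s
}

#' Write and read motion-energy series tables
#'
#' Series are exchanged as plain CSV with a `frame` column followed by one
#' column per person-and-ROI (`personA_head`, `personA_body`, `personB_head`,
#' `personB_body`, or any subset). All series in one file must share length
#' and frame rate.
#'
#' @param series named list of [motion_energy_series] (names become columns).
#' @param path file path.
#' @rdname series_csv
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a named list of [motion_energy_series].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(length(series) >= 1L, !is.null(names(series)))
  lens <- vapply(series, function(s) length(as_me_values(s)), integer(1L))
  if (length(unique(lens)) != 1L) stop("all series must have equal length", call. = FALSE)
  df <- data.frame(frame = seq_len(lens[[1L]]))
  for (nm in names(series)) df[[nm]] <- as_me_values(series[[nm]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param fps frame rate to attach to the series read back from disk.
#' @rdname series_csv
#' @export
read_series_csv <- function(path, fps) {
  df <- read.csv(path)
  cols <- setdiff(names(df), "frame")
  if (length(cols) == 0L) stop("no series columns found in ", path, call. = FALSE)
  out <- lapply(cols, function(nm) {
    roi <- sub("^person[AB]_", "", nm)
    person <- sub("^person([AB])_.*$", "\\1", nm)
    motion_energy_series(df[[nm]], fps = fps, person_id = person, roi_label = roi)
  })
  names(out) <- cols
  out
}

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}
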