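#' Generate a synthetic grayscale frame sequence
#'
#' Renders a minimal scene for exercising the extraction stage: a static
#' background with one bright square blob per ROI. A blob jumps to the next
#' of a set of disjoint positions inside its ROI on every frame its schedule
#' marks as moving, and stays put otherwise, so the fraction of scheduled
#' moves is the ground-truth movement quantity and each jump changes exactly
#' `2 * blob area` pixels (vacated plus occupied).
#'
#' @param masks list of [roi_mask] (same-person masks must be disjoint).
#' @param schedule named list keyed `"<person_id>_<label>"`; each element a
#'   logical vector of length `n_frames` whose entry `t` (for `t >= 2`) says
#'   whether that ROI's blob moves between frames `t - 1` and `t`. ROIs
#'   without a schedule stay static.
#' @param n_frames number of frames (>= 2).
#' @param frame_dim frame size as `c(height, width)` pixels.
#' @param blob_dim blob size as `c(height, width)`; default one third of the
#'   smallest ROI extent (at least 2 pixels).
#' @param seed integer seed (randomises each blob's starting position).
#' @param background,foreground grayscale levels of scene and blobs.
#' @return A `height x width x n_frames` numeric array of grayscale values.
#' @export
gen_synthetic_video <- function(masks, schedule = list(), n_frames,
                                frame_dim = c(120L, 160L), blob_dim = NULL,
                                seed = 1L, background = 20, foreground = 220) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  check_masks(masks, frame_dim)
  keys <- vapply(masks, function(m) paste0(m$person_id, "_", m$label), character(1L))
  bad <- setdiff(names(schedule), keys)
  if (length(bad)) stop("schedule refers to unknown ROIs: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(schedule)) {
    if (length(schedule[[nm]]) != n_frames) {
      stop("schedule for ", nm, " must have length n_frames", call. = FALSE)
    }
  }

  # disjoint candidate positions (top-left corners) of the blob inside a ROI,
  # spaced by the blob's own extent so consecutive positions never overlap
  blob_positions <- function(m, bd) {
    ys <- seq(m$y0, m$y0 + m$height - bd[1L], by = bd[1L])
    xs <- seq(m$x0, m$x0 + m$width - bd[2L], by = bd[2L])
    pos <- expand.grid(y = ys, x = xs)
    pos[order(pos$y, pos$x), , drop = FALSE]
  }

  with_seed(seed, {
    video <- array(background, dim = c(frame_dim[1L], frame_dim[2L], n_frames))
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      bd <- if (is.null(blob_dim)) {
        rep(max(2L, min(m$height, m$width) %/% 3L), 2L)
      } else as.integer(blob_dim)
      if (bd[1L] > m$height || bd[2L] > m$width) {
        stop("blob larger than ROI ", keys[[i]], call. = FALSE)
      }
      pos <- blob_positions(m, bd)
      sched <- schedule[[keys[[i]]]]
      if (is.null(sched)) sched <- rep(FALSE, n_frames)
      if (any(sched[-1L]) && nrow(pos) < 2L) {
        stop("ROI ", keys[[i]], " too small to move a ", bd[1L], "x", bd[2L], " blob",
             call. = FALSE)
      }
      p <- sample.int(nrow(pos), 1L)
      for (t in seq_len(n_frames)) {
        if (t >= 2L && isTRUE(sched[[t]])) p <- (p %% nrow(pos)) + 1L
        video[pos$y[p] + seq_len(bd[1L]), pos$x[p] + seq_len(bd[2L]), t] <- foreground
      }
    }
    video
  })
}

#' Write a frame sequence as a directory of PNG files
#'
#' @param video `height x width x n_frames` grayscale array (0--255).
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_png_frames <- function(video, dir) {
  stopifnot(is.array(video), length(dim(video)) == 3L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(video)[3L]
  for (t in seq_len(n)) {
    png::writePNG(video[, , t] / 255, file.path(dir, sprintf("frame_%05d.png", t)))
  }
  invisible(dir)
}
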