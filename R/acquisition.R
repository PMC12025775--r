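#' Frame sequence container
#'
#' An ordered list of interferogram frames sharing one shape, plus the frame
#' rate. Frame indices throughout the package are 0-based, matching video
#' frame numbering.
#'
#' @param frames List of `height x width x 3` arrays on the 0-255 scale.
#' @param fps Frames per second (> 0).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a non-empty list", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 0L) != 3))
    stop("every frame must be a height x width x 3 array", call. = FALSE)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all frames must share one shape", call. = FALSE)
  structure(list(frames = frames, fps = fps), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame sequence: %d frames of %dx%d at %g fps (%.2f s)\n",
              length(x$frames), d[1], d[2], x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Detect blinks in a frame sequence
#'
#' A blink is a contiguous run of frames whose mean intensity falls below
#' `(1 - drop_fraction)` times the robust baseline intensity (the median of
#' all frame means; blinks occupy a small minority of frames). Each event
#' records the first occluded frame (`start_frame`) and the first non-occluded
#' frame after the run (`end_frame`), 0-based. Runs touching the end of the
#' sequence have no post-blink frame and are dropped.
#'
#' @param seq A [frame_sequence()] of at least 3 frames.
#' @param drop_fraction Relative intensity drop defining occlusion, in (0, 1).
#'   Default 0.4.
#' @return Data frame with columns `start_frame`, `end_frame`, one row per
#'   blink, in temporal order; zero rows when no blink is found.
#' @export
detect_blinks <- function(seq, drop_fraction = 0.4) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (n < 3)
    stop("blink detection needs at least 3 frames", call. = FALSE)
  if (!is.numeric(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in (0, 1)", call. = FALSE)
  means <- vapply(seq$frames, mean, 0)
  baseline <- stats::median(means)
  occluded <- means < (1 - drop_fraction) * baseline
  runs <- rle(occluded)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & ends < n        # need a frame after the run
  data.frame(start_frame = starts[keep] - 1L,   # to 0-based
             end_frame = ends[keep])            # first clear frame, 0-based
}

#' Select the analysis frame at a fixed delay after blinks
#'
#' Returns the frame captured `delay_s` seconds after the end of the
#' `required_blinks`-th detected blink: index
#' `end_frame + round(delay_s * fps)` (ties round half up).
#'
#' @param seq A [frame_sequence()].
#' @param blinks Blink events as returned by [detect_blinks()].
#' @param delay_s Capture delay in seconds (>= 0). Default 0.5.
#' @param required_blinks Number of blinks to wait for. Default 2.
#' @return List with `frame` (the interferogram array) and `index` (0-based).
#' @export
select_analysis_frame <- function(seq, blinks, delay_s = 0.5,
                                  required_blinks = 2) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is.numeric(delay_s) || delay_s < 0)
    stop("delay_s must be >= 0", call. = FALSE)
  if (nrow(blinks) < required_blinks)
    stop(sprintf("need %d blink(s) but only %d detected",
                 required_blinks, nrow(blinks)), call. = FALSE)
  anchor <- blinks$end_frame[required_blinks]
  idx <- anchor + floor(delay_s * seq$fps + 0.5)   # round half up
  if (idx >= length(seq$frames))
    stop(sprintf("analysis frame %d lies beyond the %d-frame sequence",
                 idx, length(seq$frames)), call. = FALSE)
  list(frame = seq$frames[[idx + 1]], index = as.integer(idx))
}

#' Region-of-interest specification
#'
#' A circular cornea outline of which only the lower half is analyzed: the
#' upper corneal region is routinely obscured by lashes and lids, so pixels
#' are retained only inside the circle and strictly below the center row.
#'
#' @param center_x,center_y Circle center in 0-based pixel coordinates
#'   (row 0 at the top; rows increase downward).
#' @param radius Circle radius in pixels (> 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_x, center_y, radius) {
  stopifnot(is.numeric(center_x), is.numeric(center_y), is.numeric(radius))
  if (radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 keep = "lower_half"),
            class = "roi_spec")
}

#' Build the lower-cornea ROI mask
#'
#' The mask is true exactly for pixels inside the circle whose row index is
#' strictly greater than `center_y` (lower half; rows increase downward).
#'
#' @param shape Image dimensions `c(height, width)`.
#' @param roi An [roi_spec()].
#' @return Logical `height x width` matrix.
#' @export
build_roi <- function(shape, roi) {
  stopifnot(inherits(roi, "roi_spec"), length(shape) >= 2)
  h <- shape[1]; w <- shape[2]
  if (roi$center_x + roi$radius < 0 || roi$center_x - roi$radius > w - 1 ||
      roi$center_y + roi$radius < 0 || roi$center_y - roi$radius > h - 1)
    stop("ROI circle lies entirely outside the image", call. = FALSE)
  y <- matrix(rep(0:(h - 1), w), nrow = h)          # 0-based row index
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)   # 0-based column index
  inside <- (x - roi$center_x)^2 + (y - roi$center_y)^2 <= roi$radius^2
  inside & (y > roi$center_y)
}
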