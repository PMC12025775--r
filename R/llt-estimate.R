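#' Euclidean color distance between a pixel and a reference color
#'
#' `d = sqrt((r - R)^2 + (g - G)^2 + (b - B)^2)` on the 0-255 channel scale,
#' where (r, g, b) is an image pixel and (R, G, B) a lookup-table reference
#' color.
#'
#' @param pixel,reference Numeric vectors of length 3, channels in \[0, 255\].
#' @return The non-negative distance; 0 iff the colors are identical.
#' @export
pixel_distance <- function(pixel, reference) {
  if (length(pixel) != 3 || length(reference) != 3)
    stop("pixel and reference must have 3 channels", call. = FALSE)
  if (any(pixel < 0 | pixel > 255) || any(reference < 0 | reference > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  sqrt(sum((pixel - reference)^2))
}

#' Classify a pixel to the nearest lookup-table thickness
#'
#' Returns the thickness of the table entry at minimum Euclidean color
#' distance from the pixel; ties are broken toward the smallest thickness.
#'
#' @param pixel Numeric vector of length 3, channels in \[0, 255\].
#' @param table A [reference_table()].
#' @return The classified thickness (nm).
#' @export
classify_pixel <- function(pixel, table) {
  stopifnot(inherits(table, "reference_table"))
  if (length(pixel) != 3 || any(pixel < 0 | pixel > 255))
    stop("pixel must have 3 channels in [0, 255]", call. = FALSE)
  d2 <- colSums((t(table$colors) - pixel)^2)
  table$thickness_nm[which.min(d2)]   # which.min takes the first = smallest T
}

# Vectorized nearest-entry classification of an N x 3 pixel matrix.
# Squared distances via the |p|^2 + |c|^2 - 2 p.c expansion: all inputs are
# small integers, so every term is exact in double precision and the
# smallest-thickness tie rule of max.col(ties.method = "first") is reliable.
.classify_matrix <- function(px, table) {
  cols <- table$colors
  d2 <- outer(rowSums(px^2), rep(1, nrow(cols))) +
        outer(rep(1, nrow(px)), rowSums(cols^2)) -
        2 * px %*% t(cols)
  idx <- max.col(-d2, ties.method = "first")
  table$thickness_nm[idx]
}

#' Per-pixel classification and raw mean LLT over a region of interest
#'
#' Classifies every masked pixel of the interferogram to its nearest
#' lookup-table thickness and averages. No segmentation is applied: the
#' thickness is estimated directly from the unsegmented image.
#'
#' @param image `height x width x 3` array, channels on the 0-255 scale.
#' @param mask Logical matrix of the same height/width with >= 1 true pixel.
#' @param table A [reference_table()].
#' @return List with `raw_mean_nm` (arithmetic mean of the classified
#'   thicknesses) and `thickness_map` (matrix, NA outside the mask).
#' @export
estimate_raw_llt <- function(image, mask, table) {
  stopifnot(inherits(table, "reference_table"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("image must be a height x width x 3 array", call. = FALSE)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("mask must be a logical matrix matching the image shape", call. = FALSE)
  if (any(image < 0 | image > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (!any(mask))
    stop("ROI mask selects no pixels; adjust the ROI", call. = FALSE)
  px <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  th <- .classify_matrix(px, table)
  map <- matrix(NA_real_, d[1], d[2])
  map[mask] <- th
  list(raw_mean_nm = mean(th), thickness_map = map)
}

#' Linear LLT calibration
#'
#' The raw mean classified thickness is multiplied by `slope` and increased by
#' `intercept`: `calibrated = 0.6 * raw + 10` with the defaults.
#'
#' @param raw_mean_nm Raw mean thickness (nm, finite, >= 0).
#' @param slope,intercept Calibration constants. Defaults 0.6 and 10.
#' @return Calibrated LLT (nm).
#' @export
calibrate_llt <- function(raw_mean_nm, slope = 0.6, intercept = 10) {
  if (any(!is.finite(raw_mean_nm)) || any(raw_mean_nm < 0))
    stop("raw_mean_nm must be finite and >= 0", call. = FALSE)
  slope * raw_mean_nm + intercept
}

#' Upper/lower section analysis of the classified region
#'
#' Splits the masked region at the horizontal midline of its bounding box,
#' calibrates the mean classified thickness of each section, and reports the
#' absolute vertical difference. Rows on the exact midline go to the lower
#' section. Because the calibration is affine, the intercept cancels and the
#' vertical difference equals `slope` times the raw section difference.
#'
#' @param thickness_map Per-pixel classified thickness (matrix, NA outside the
#'   region), as returned by [estimate_raw_llt()].
#' @param mask Logical matrix marking the analyzed pixels.
#' @param slope,intercept Calibration constants passed to [calibrate_llt()].
#' @return List with `upper_section_nm`, `lower_section_nm`,
#'   `vertical_difference_nm`, `n_pixels_upper`, `n_pixels_lower`.
#' @export
section_analysis <- function(thickness_map, mask, slope = 0.6, intercept = 10) {
  if (!any(mask))
    stop("mask selects no pixels", call. = FALSE)
  rows <- which(apply(mask, 1, any))
  mid <- (min(rows) + max(rows)) / 2          # 1-based rows; midline of bbox
  row_idx <- row(mask)
  upper <- mask & (row_idx < mid)
  lower <- mask & (row_idx >= mid)
  if (!any(upper) || !any(lower))
    stop("a section contains no masked pixels; enlarge or recenter the ROI",
         call. = FALSE)
  up <- calibrate_llt(mean(thickness_map[upper]), slope, intercept)
  lo <- calibrate_llt(mean(thickness_map[lower]), slope, intercept)
  list(upper_section_nm = up, lower_section_nm = lo,
       vertical_difference_nm = abs(up - lo),
       n_pixels_upper = sum(upper), n_pixels_lower = sum(lower))
}

#' Estimate lipid layer thickness from an interferogram or frame sequence
#'
#' The core fitting function: given a single interferogram (or a video frame
#' sequence, from which the analysis frame is selected 0.5 s after the second
#' blink), it builds the lower-cornea ROI mask, classifies every masked pixel
#' to the nearest lookup-table thickness by Euclidean color distance,
#' calibrates the mean (`0.6 x raw + 10` by default), and splits the region
#' into upper and lower sections to quantify the vertical lipid distribution.
#'
#' @param input A `height x width x 3` interferogram array (0-255 scale) or a
#'   [frame_sequence()].
#' @param table A [reference_table()].
#' @param roi An [roi_spec()] defining the cornea circle.
#' @param delay_s,required_blinks,drop_fraction Acquisition parameters used
#'   when `input` is a frame sequence; see [select_analysis_frame()] and
#'   [detect_blinks()].
#' @param slope,intercept Calibration constants; see [calibrate_llt()].
#' @return An object of class `llt_estimate` with components `raw_mean_nm`,
#'   `calibrated_nm`, `upper_section_nm`, `lower_section_nm`,
#'   `vertical_difference_nm`, `n_pixels`, `n_pixels_upper`,
#'   `n_pixels_lower`, `frame_index` (0-based; NA for single images) and
#'   `thickness_map`.
#' @examples
#' tab <- build_reference_table(seq(10, 160, by = 10))
#' img <- render_interferogram(
#'   generate_thickness_field(c(64, 64), "uniform", list(value = 100)), tab)
#' fit <- estimate_llt(img, tab, roi_spec(31.5, 20, 30))
#' fit
#' @export
estimate_llt <- function(input, table, roi,
                         delay_s = 0.5, required_blinks = 2,
                         drop_fraction = 0.4,
                         slope = 0.6, intercept = 10) {
  stopifnot(inherits(table, "reference_table"), inherits(roi, "roi_spec"))
  frame_index <- NA_integer_
  if (inherits(input, "frame_sequence")) {
    blinks <- detect_blinks(input, drop_fraction)
    sel <- select_analysis_frame(input, blinks, delay_s, required_blinks)
    image <- sel$frame
    frame_index <- sel$index
  } else {
    image <- input
  }
  mask <- build_roi(dim(image)[1:2], roi)
  est <- estimate_raw_llt(image, mask, table)
  sec <- section_analysis(est$thickness_map, mask, slope, intercept)
  structure(list(raw_mean_nm = est$raw_mean_nm,
                 calibrated_nm = calibrate_llt(est$raw_mean_nm, slope, intercept),
                 upper_section_nm = sec$upper_section_nm,
                 lower_section_nm = sec$lower_section_nm,
                 vertical_difference_nm = sec$vertical_difference_nm,
                 n_pixels = sum(mask),
                 n_pixels_upper = sec$n_pixels_upper,
                 n_pixels_lower = sec$n_pixels_lower,
                 frame_index = frame_index,
                 thickness_map = est$thickness_map,
                 slope = slope, intercept = intercept,
                 call = match.call()),
            class = "llt_estimate")
}

#' @export
print.llt_estimate <- function(x, digits = 2, ...) {
  cat("Lipid layer thickness estimate\n")
  if (!is.na(x$frame_index))
    cat(sprintf("  analysis frame: %d\n", x$frame_index))
  cat(sprintf("  calibrated LLT: %.*f nm (raw mean %.*f nm over %d pixels)\n",
              digits, x$calibrated_nm, digits, x$raw_mean_nm, x$n_pixels))
  cat(sprintf("  sections: upper %.*f nm, lower %.*f nm, vertical difference %.*f nm\n",
              digits, x$upper_section_nm, digits, x$lower_section_nm,
              digits, x$vertical_difference_nm))
  invisible(x)
}

#' @export
summary.llt_estimate <- function(object, ...) {
  th <- object$thickness_map[!is.na(object$thickness_map)]
  structure(list(estimate = object,
                 thickness_quantiles = stats::quantile(th, c(0, .25, .5, .75, 1))),
            class = "summary.llt_estimate")
}

#' @export
print.summary.llt_estimate <- function(x, ...) {
  print(x$estimate)
  cat("  classified thickness quantiles (nm):\n")
  print(round(x$thickness_quantiles, 1))
  invisible(x)
}

#' @export
coef.llt_estimate <- function(object, ...) {
  c(raw_mean_nm = object$raw_mean_nm,
    calibrated_nm = object$calibrated_nm,
    upper_section_nm = object$upper_section_nm,
    lower_section_nm = object$lower_section_nm,
    vertical_difference_nm = object$vertical_difference_nm)
}

#' Plot the classified thickness map of an LLT estimate
#'
#' @param x An `llt_estimate`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.llt_estimate <- function(x, ...) {
  m <- x$thickness_map
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  main = "Classified lipid layer thickness (nm)",
                  axes = FALSE, ...)
  invisible(x)
}
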