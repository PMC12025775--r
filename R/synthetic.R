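#' Generate a ground-truth thickness field
#'
#' Produces a per-pixel true lipid thickness map (nm) used as input to the
#' forward renderer and as the reference for parameter-recovery tests.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{`uniform`}{`value` (nm).}
#'   \item{`vertical_gradient`}{`top`, `bottom` (nm); linear in row index.}
#'   \item{`two_band`}{`upper_value`, `lower_value` (nm), `split_row`
#'     (0-based; rows below `split_row` take `upper_value`).}
#'   \item{`smooth_random`}{`mean`, `amplitude` (marginal SD, nm),
#'     `corr_length` (pixels); Gaussian white noise smoothed with a separable
#'     Gaussian kernel and rescaled to the requested mean and SD.}
#' }
#'
#' Values are clipped to `grid_range` so every pixel is representable in the
#' lookup table.
#'
#' @param shape `c(height, width)` in pixels.
#' @param kind One of `"uniform"`, `"vertical_gradient"`, `"two_band"`,
#'   `"smooth_random"`.
#' @param params Named list of kind-specific parameters (above).
#' @param seed Integer seed (used by `smooth_random`); generation is a pure
#'   function of `(params, seed)`.
#' @param grid_range Admissible thickness range `c(min, max)` (nm).
#'   Default `c(10, 160)`, the default lookup grid.
#' @return A `height x width` matrix of thicknesses (nm) with attributes
#'   `kind` and `grid_range`.
#' @export
generate_thickness_field <- function(shape, kind, params = list(), seed = 1,
                                     grid_range = c(10, 160)) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  h <- shape[1]; w <- shape[2]
  field <- switch(kind,
    uniform = {
      stopifnot(!is.null(params$value))
      matrix(params$value, h, w)
    },
    vertical_gradient = {
      stopifnot(!is.null(params$top), !is.null(params$bottom))
      frac <- if (h == 1) 0 else (seq_len(h) - 1) / (h - 1)
      matrix(params$top + frac * (params$bottom - params$top), h, w)
    },
    two_band = {
      stopifnot(!is.null(params$upper_value), !is.null(params$lower_value),
                !is.null(params$split_row))
      m <- matrix(params$lower_value, h, w)
      m[seq_len(h) - 1 < params$split_row, ] <- params$upper_value
      m
    },
    smooth_random = {
      stopifnot(!is.null(params$mean), !is.null(params$amplitude))
      cl <- if (is.null(params$corr_length)) 8 else params$corr_length
      set.seed(seed)
      z <- matrix(stats::rnorm(h * w), h, w)
      z <- .gauss_smooth(z, cl)
      s <- stats::sd(as.vector(z))
      if (s == 0) s <- 1
      params$mean + params$amplitude * (z - mean(z)) / s
    },
    stop("unknown field kind: ", kind, call. = FALSE)
  )
  if (any(!is.finite(field)))
    stop("thickness field contains non-finite values", call. = FALSE)
  lo <- grid_range[1]; hi <- grid_range[2]
  if (min(field) < lo - (hi - lo) || max(field) > hi + (hi - lo))
    stop("field values lie far outside the lookup grid range", call. = FALSE)
  field <- pmin(pmax(field, lo), hi)
  attr(field, "kind") <- kind
  attr(field, "grid_range") <- grid_range
  field
}

# Separable Gaussian smoothing with edge reflection.
.gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rev(v[seq_len(min(r, n))]), v,
                v[seq.int(n, by = -1, length.out = min(r, n))])
    if (length(padded) < n + 2 * r)   # tiny inputs: recycle reflection
      padded <- rep(padded, length.out = n + 2 * r)
    out <- stats::filter(padded, k, sides = 2)
    out[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' Render a thickness field to an interferogram (forward model)
#'
#' The inverse of the classifier: each pixel takes the lookup-table color of
#' the nearest grid thickness (no interpolation, so noise-free rendering of
#' on-grid fields is exactly inverted by classification when the table's
#' colors are distinct), plus independent Gaussian channel noise, rounded and
#' clipped to \[0, 255\]. Optionally the upper image half is painted dark to
#' emulate lash/lid occlusion.
#'
#' @param field Thickness matrix (nm), e.g. from
#'   [generate_thickness_field()].
#' @param table A [reference_table()].
#' @param noise_sd Gaussian channel noise SD on the 0-255 scale (>= 0).
#' @param occlude_upper Paint rows above the image midline near-black?
#' @param seed Integer seed for the noise draw.
#' @return A `height x width x 3` interferogram array (0-255 integers).
#' @export
render_interferogram <- function(field, table, noise_sd = 0,
                                 occlude_upper = FALSE, seed = 1) {
  stopifnot(inherits(table, "reference_table"), is.matrix(field))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (min(field) < min(table$thickness_nm) ||
      max(field) > max(table$thickness_nm))
    stop("field values lie outside the lookup grid range", call. = FALSE)
  h <- nrow(field); w <- ncol(field)
  # nearest grid thickness per pixel (ties toward the smaller entry)
  grid <- table$thickness_nm
  cuts <- (grid[-length(grid)] + grid[-1]) / 2
  idx <- findInterval(field, cuts, left.open = TRUE) + 1L
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- table$colors[idx, ch]
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  if (occlude_upper) {
    top <- seq_len(floor(h / 2))
    img[top, , ] <- 8
  }
  img <- round(pmin(pmax(img, 0), 255))
  img
}

#' Generate a synthetic frame sequence with blinks
#'
#' Renders `n_frames` copies of the field's interferogram at the given frame
#' rate and overwrites the listed blink runs with near-black frames, for
#' exercising blink detection and analysis-frame selection.
#'
#' @param field Thickness matrix (nm).
#' @param table A [reference_table()].
#' @param fps Frames per second. Default 30.
#' @param blink_frames List of `c(start, end)` 0-based inclusive frame ranges
#'   rendered as blinks.
#' @param n_frames Total number of frames. Default 90.
#' @param noise_sd Channel noise SD for the open-eye frames.
#' @param seed Integer seed.
#' @return A [frame_sequence()].
#' @export
generate_frame_sequence <- function(field, table, fps = 30,
                                    blink_frames = list(), n_frames = 90,
                                    noise_sd = 0, seed = 1) {
  open_frame <- render_interferogram(field, table, noise_sd, seed = seed)
  dark <- array(5, dim(open_frame))
  frames <- rep(list(open_frame), n_frames)
  for (b in blink_frames) {
    idx <- seq.int(b[1], b[2]) + 1L
    if (any(idx < 1 | idx > n_frames))
      stop("blink range outside the sequence", call. = FALSE)
    for (i in idx) frames[[i]] <- dark
  }
  frame_sequence(frames, fps)
}
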