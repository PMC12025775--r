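#' Load a run configuration from JSON or YAML
#'
#' Reads the shared configuration binding the pipeline stages together and
#' applies the protocol defaults for absent keys: capture delay 0.5 s after 2
#' blinks, blink drop fraction 0.4, calibration slope 0.6 and intercept 10,
#' Student independent-test variant, alpha 0.05. Every key is validated before
#' any stage runs and unknown keys are an error.
#'
#' Recognised keys (flat or nested): `lookup.path`,
#' `lookup.generate.{t_min,t_max,step,n_lipid,n_water,gamma}`,
#' `roi.{center_x,center_y,radius}`,
#' `acquisition.{delay_s,required_blinks,drop_fraction}`,
#' `calibration.{slope,intercept}`, `stats.{variant,alpha}`, `seed`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  }
  if (is.null(raw)) raw <- list()

  defaults <- list(
    lookup = list(path = NULL,
                  generate = list(t_min = 10, t_max = 160, step = 1,
                                  n_lipid = 1.48, n_water = 1.336,
                                  gamma = TRUE)),
    roi = list(center_x = NULL, center_y = NULL, radius = NULL),
    acquisition = list(delay_s = 0.5, required_blinks = 2, drop_fraction = 0.4),
    calibration = list(slope = 0.6, intercept = 10),
    stats = list(variant = "student", alpha = 0.05),
    seed = 1
  )
  unknown <- character()
  merge <- function(def, user, prefix = "") {
    for (k in names(user)) {
      key <- paste0(prefix, k)
      if (!k %in% names(def)) {
        unknown <<- c(unknown, key)
      } else if (is.list(def[[k]]) && is.list(user[[k]])) {
        def[[k]] <- merge(def[[k]], user[[k]], paste0(key, "."))
      } else {
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  cfg <- merge(defaults, raw)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  chk <- function(ok, key, constraint)
    if (!isTRUE(ok)) stop("config key ", key, ": ", constraint, call. = FALSE)
  chk(cfg$acquisition$delay_s >= 0, "acquisition.delay_s", "must be >= 0")
  chk(cfg$acquisition$required_blinks >= 1, "acquisition.required_blinks",
      "must be >= 1")
  chk(cfg$acquisition$drop_fraction > 0 && cfg$acquisition$drop_fraction < 1,
      "acquisition.drop_fraction", "must lie in (0, 1)")
  chk(is.finite(cfg$calibration$slope), "calibration.slope", "must be finite")
  chk(is.finite(cfg$calibration$intercept), "calibration.intercept",
      "must be finite")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1, "stats.alpha",
      "must lie in (0, 1)")
  chk(cfg$stats$variant %in% c("student", "welch"), "stats.variant",
      "must be \"student\" or \"welch\"")
  chk(cfg$seed == round(cfg$seed), "seed", "must be an integer")
  if (!is.null(cfg$lookup$path))
    chk(file.exists(cfg$lookup$path), "lookup.path", "file does not exist")
  if (!is.null(cfg$roi$radius))
    chk(cfg$roi$radius > 0, "roi.radius", "must be > 0")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  acquisition: delay %g s after %d blink(s), drop fraction %g\n",
              x$acquisition$delay_s, x$acquisition$required_blinks,
              x$acquisition$drop_fraction))
  cat(sprintf("  calibration: %g x raw + %g\n",
              x$calibration$slope, x$calibration$intercept))
  cat(sprintf("  stats: %s, alpha %g; seed %d\n",
              x$stats$variant, x$stats$alpha, as.integer(x$seed)))
  invisible(x)
}

#' Read an 8-bit RGB interferogram image
#'
#' Accepts 8-bit-per-channel RGB PNG or TIFF and returns a
#' `height x width x 3` array on the 0-255 integer scale. Grayscale images
#' and higher bit depths are rejected with a conversion hint.
#'
#' @param path Image path.
#' @return Interferogram array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, " (use 8-bit RGB PNG or TIFF)",
         call. = FALSE)
  }
  if (length(dim(img)) < 3 || dim(img)[3] < 3)
    stop("grayscale image: convert to 8-bit RGB before analysis", call. = FALSE)
  img <- img[, , 1:3, drop = FALSE] * 255   # drop alpha if present
  if (max(abs(img - round(img))) > 1e-6)
    stop("image is not 8-bit per channel: convert to 8-bit RGB", call. = FALSE)
  round(img)
}

#' Write an interferogram to PNG
#'
#' @param image `height x width x 3` array on the 0-255 scale.
#' @param path Output path (`.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write per-eye LLT estimates to CSV
#'
#' Fixed column order `eye_id, raw_mean_nm, calibrated_nm, upper_nm,
#' lower_nm, vertical_difference_nm, n_pixels`; deterministic formatting.
#'
#' @param estimates Named list of `llt_estimate` objects (names = eye ids) or
#'   a single estimate.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(estimates, path) {
  if (inherits(estimates, "llt_estimate")) estimates <- list(eye = estimates)
  stopifnot(all(vapply(estimates, inherits, TRUE, "llt_estimate")))
  ids <- names(estimates)
  if (is.null(ids)) ids <- sprintf("eye_%03d", seq_along(estimates))
  df <- data.frame(
    eye_id = ids,
    raw_mean_nm = vapply(estimates, `[[`, 0, "raw_mean_nm"),
    calibrated_nm = vapply(estimates, `[[`, 0, "calibrated_nm"),
    upper_nm = vapply(estimates, `[[`, 0, "upper_section_nm"),
    lower_nm = vapply(estimates, `[[`, 0, "lower_section_nm"),
    vertical_difference_nm = vapply(estimates, `[[`, 0, "vertical_difference_nm"),
    n_pixels = vapply(estimates, `[[`, 0L, "n_pixels"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' Expects columns `eye_id, group, parameter, pre, post` as written by
#' [write_cohort()].
#'
#' @param path Cohort CSV path.
#' @return An `eye_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "parameter", "pre", "post")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("eye_id", "group", "parameter")) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad) > 0)
      stop("cohort CSV row ", bad[1], ": missing ", col, call. = FALSE)
  }
  for (col in c("pre", "post")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0)
      stop("cohort CSV row ", bad[1], ": non-numeric ", col, call. = FALSE)
  }
  class(df) <- c("eye_cohort", "data.frame")
  df
}

#' Write a cohort to long-format CSV
#'
#' @param cohort An `eye_cohort` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(
    cohort[, c("eye_id", "group", "parameter", "pre", "post")], path,
    row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
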