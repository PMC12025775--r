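#' Construct a reference table object
#'
#' A reference table maps an ordered grid of lipid-film thicknesses (nm) to one
#' expected interference color per thickness, on the 8-bit 0-255 channel scale.
#' It is the lookup table the nearest-color classifier references.
#'
#' @param thickness_nm Strictly increasing, non-negative thicknesses (nm),
#'   length >= 2.
#' @param colors Integer matrix with one row per thickness and columns
#'   `red`, `green`, `blue`, values in \[0, 255\].
#' @param source `"generated"` or `"loaded"`.
#' @return An object of class `reference_table`.
#' @seealso [build_reference_table()], [load_reference_table()]
#' @export
reference_table <- function(thickness_nm, colors, source = "generated") {
  thickness_nm <- as.numeric(thickness_nm)
  colors <- as.matrix(colors)
  if (length(thickness_nm) < 2)
    stop("a reference table needs at least 2 entries", call. = FALSE)
  if (any(!is.finite(thickness_nm)) || any(thickness_nm < 0))
    stop("thicknesses must be finite and non-negative", call. = FALSE)
  if (any(diff(thickness_nm) <= 0))
    stop("thicknesses must be strictly increasing", call. = FALSE)
  if (ncol(colors) != 3 || nrow(colors) != length(thickness_nm))
    stop("colors must be a matrix with one (red, green, blue) row per thickness",
         call. = FALSE)
  if (any(!is.finite(colors)) || any(colors < 0) || any(colors > 255) ||
      any(colors != round(colors)))
    stop("channel values must be integers in [0, 255]", call. = FALSE)
  if (!source %in% c("generated", "loaded"))
    stop("source must be \"generated\" or \"loaded\"", call. = FALSE)
  storage.mode(colors) <- "integer"
  colnames(colors) <- c("red", "green", "blue")
  structure(list(thickness_nm = thickness_nm, colors = colors, source = source),
            class = "reference_table")
}

#' Build a thickness-to-color lookup table from thin-film optics
#'
#' For each thickness the two-beam reflectance spectrum of a lipid film on
#' water is computed ([thin_film_reflectance()]), normalised by the maximum
#' attainable two-beam reflectance so the brightest fringe fills the display
#' range, and converted to an 8-bit RGB color under the configured illuminant.
#' At zero thickness the interference term is constant across wavelengths, so
#' the color is achromatic under the equal-energy illuminant.
#'
#' @param thickness_grid Strictly increasing, non-negative thicknesses (nm).
#'   The default 10-160 nm at 1 nm brackets clinically reported LLT values
#'   (roughly 70-86 nm) with margin.
#' @param optics An [optics_config()].
#' @return A `reference_table` with `source = "generated"`.
#' @examples
#' tab <- build_reference_table(seq(10, 160, by = 10))
#' tab
#' @export
build_reference_table <- function(thickness_grid = seq(10, 160, by = 1),
                                  optics = optics_config()) {
  if (length(thickness_grid) == 0)
    stop("thickness_grid must be non-empty", call. = FALSE)
  if (any(thickness_grid < 0) || any(diff(thickness_grid) <= 0))
    stop("thickness_grid must be strictly increasing and non-negative",
         call. = FALSE)
  stopifnot(inherits(optics, "optics_config"))
  wl <- optics$wavelength_grid_nm
  nl <- optics$lipid_refractive_index
  ns <- optics$substrate_refractive_index
  r1 <- (1 - nl) / (1 + nl)
  r2 <- (nl - ns) / (nl + ns)
  gain <- (abs(r1) + abs(r2))^2           # max two-beam reflectance
  spectra <- t(vapply(thickness_grid, function(T) {
    thin_film_reflectance(T, wl, nl, ns) / gain
  }, numeric(length(wl))))
  reference_table(thickness_grid, spectra_to_rgb255(spectra, optics),
                  source = "generated")
}

#' Load a reference table from CSV
#'
#' Expects a header `thickness_nm,red,green,blue` and one row per grid point.
#' Rows out of thickness order are re-sorted with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `reference_table` with `source = "loaded"`.
#' @export
load_reference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("thickness_nm", "red", "green", "blue")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("lookup CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0)
      stop("lookup CSV row ", bad[1], ": non-numeric or missing ", col,
           call. = FALSE)
  }
  bad <- which(df$red < 0 | df$red > 255 | df$green < 0 | df$green > 255 |
               df$blue < 0 | df$blue > 255)
  if (length(bad) > 0)
    stop("lookup CSV row ", bad[1], ": channel value outside [0, 255]",
         call. = FALSE)
  dup <- which(duplicated(df$thickness_nm))
  if (length(dup) > 0)
    stop("lookup CSV row ", dup[1], ": duplicate thickness ",
         df$thickness_nm[dup[1]], call. = FALSE)
  if (is.unsorted(df$thickness_nm)) {
    warning("lookup CSV rows were not in thickness order; re-sorting",
            call. = FALSE)
    df <- df[order(df$thickness_nm), , drop = FALSE]
  }
  reference_table(df$thickness_nm,
                  as.matrix(df[, c("red", "green", "blue")]),
                  source = "loaded")
}

#' Write a reference table to CSV
#'
#' Writes the `thickness_nm,red,green,blue` format read by
#' [load_reference_table()]; the round trip is the identity on valid tables.
#'
#' @param table A `reference_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference_table <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  df <- data.frame(thickness_nm = table$thickness_nm,
                   red = table$colors[, "red"],
                   green = table$colors[, "green"],
                   blue = table$colors[, "blue"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference table (%s): %d entries, %g-%g nm\n",
              x$source, length(x$thickness_nm),
              min(x$thickness_nm), max(x$thickness_nm)))
  n_distinct <- nrow(unique(x$colors))
  cat(sprintf("  distinct colors: %d of %d\n", n_distinct, nrow(x$colors)))
  invisible(x)
}

#' @export
format.reference_table <- function(x, ...) {
  sprintf("<reference_table: %d entries>", length(x$thickness_nm))
}
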