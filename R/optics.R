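#' Optical model configuration for lookup-table generation
#'
#' Parameters of the two-beam thin-film interference model used by
#' [build_reference_table()]: a lipid film of refractive index
#' `lipid_refractive_index` on an aqueous substrate of index
#' `substrate_refractive_index`, illuminated at normal incidence and viewed in
#' reflection. The reflectance spectrum is sampled on `wavelength_grid_nm` and
#' integrated against the CIE 1931 color-matching functions under the named
#' illuminant.
#'
#' @param lipid_refractive_index Refractive index of the lipid film
#'   (dimensionless, > 1). Default 1.48, a typical meibum value.
#' @param substrate_refractive_index Refractive index of the aqueous tear layer
#'   beneath the film (dimensionless, > 1). Default 1.336 (water).
#' @param wavelength_grid_nm Strictly increasing visible wavelengths (nm) in
#'   \[380, 780\] on which spectra are sampled. Default 380-780 nm step 5 nm.
#' @param illuminant Spectral power tag; only `"E"` (equal energy) is
#'   implemented.
#' @param gamma_encode Apply the sRGB display transfer function before
#'   quantising to 8 bits? Default `TRUE`, matching 8-bit image exports.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(lipid_refractive_index = 1.48,
                          substrate_refractive_index = 1.336,
                          wavelength_grid_nm = seq(380, 780, by = 5),
                          illuminant = "E",
                          gamma_encode = TRUE) {
  stopifnot(is.numeric(lipid_refractive_index), length(lipid_refractive_index) == 1,
            is.numeric(substrate_refractive_index), length(substrate_refractive_index) == 1,
            is.numeric(wavelength_grid_nm), length(wavelength_grid_nm) >= 1,
            is.logical(gamma_encode), length(gamma_encode) == 1)
  if (lipid_refractive_index <= 1 || substrate_refractive_index <= 1)
    stop("refractive indices must be > 1", call. = FALSE)
  if (any(diff(wavelength_grid_nm) <= 0))
    stop("wavelength_grid_nm must be strictly increasing", call. = FALSE)
  if (min(wavelength_grid_nm) < 380 || max(wavelength_grid_nm) > 780)
    stop("wavelength_grid_nm must lie within [380, 780] nm", call. = FALSE)
  if (!identical(illuminant, "E"))
    stop("only the equal-energy illuminant \"E\" is implemented", call. = FALSE)
  structure(list(lipid_refractive_index = lipid_refractive_index,
                 substrate_refractive_index = substrate_refractive_index,
                 wavelength_grid_nm = as.numeric(wavelength_grid_nm),
                 illuminant = illuminant,
                 gamma_encode = gamma_encode),
            class = "optics_config")
}

# Piecewise-Gaussian lobe: sigma1 left of the mean, sigma2 right.
.cmf_lobe <- function(wl, mu, s1, s2) {
  s <- ifelse(wl < mu, s1, s2)
  exp(-0.5 * ((wl - mu) / s)^2)
}

#' CIE 1931 2-degree color-matching functions (analytic fit)
#'
#' Multi-lobe piecewise-Gaussian fit of the CIE 1931 standard observer
#' (Wyman, Sloan & Shirley 2013), accurate to well below the 8-bit channel
#' quantisation used downstream.
#'
#' @param wavelength_nm Wavelengths (nm).
#' @return Matrix with one row per wavelength, columns `x`, `y`, `z`.
#' @keywords internal
cie_cmf <- function(wavelength_nm) {
  wl <- wavelength_nm
  x <- 1.056 * .cmf_lobe(wl, 599.8, 37.9, 31.0) +
       0.362 * .cmf_lobe(wl, 442.0, 16.0, 26.7) -
       0.065 * .cmf_lobe(wl, 501.1, 20.4, 26.2)
  y <- 0.821 * .cmf_lobe(wl, 568.8, 46.9, 40.5) +
       0.286 * .cmf_lobe(wl, 530.9, 16.3, 31.1)
  z <- 1.217 * .cmf_lobe(wl, 437.0, 11.8, 36.0) +
       0.681 * .cmf_lobe(wl, 459.0, 26.0, 13.8)
  cbind(x = x, y = y, z = z)
}

#' Two-beam thin-film reflectance spectrum
#'
#' Normal-incidence reflectance of a lipid film of thickness `thickness_nm` on
#' an aqueous substrate, in the two-beam approximation:
#' `R(lambda) = r1^2 + r2^2 + 2 r1 r2 cos(4 pi n_lipid T / lambda)`,
#' with `r1`, `r2` the Fresnel amplitude coefficients at the air-lipid and
#' lipid-water interfaces.
#'
#' @param thickness_nm Film thickness (nm, >= 0).
#' @param wavelength_nm Wavelengths (nm).
#' @param n_lipid,n_substrate Refractive indices (> 1).
#' @return Reflectance values in \[0, 1\], one per wavelength.
#' @export
thin_film_reflectance <- function(thickness_nm, wavelength_nm,
                                  n_lipid = 1.48, n_substrate = 1.336) {
  if (n_lipid <= 1 || n_substrate <= 1)
    stop("refractive indices must be > 1", call. = FALSE)
  r1 <- (1 - n_lipid) / (1 + n_lipid)
  r2 <- (n_lipid - n_substrate) / (n_lipid + n_substrate)
  r1^2 + r2^2 + 2 * r1 * r2 * cos(4 * pi * n_lipid * thickness_nm / wavelength_nm)
}

# sRGB display transfer function on linear values in [0, 1].
srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

# XYZ -> linear sRGB primaries.
.xyz_to_rgb <- matrix(c( 3.2406, -1.5372, -0.4986,
                        -0.9689,  1.8758,  0.0415,
                         0.0557, -0.2040,  1.0570),
                      nrow = 3, byrow = TRUE)

#' Convert reflectance spectra to 8-bit RGB under an optics configuration
#'
#' Integrates each spectrum against the CIE 1931 color-matching functions and
#' the equal-energy illuminant, converts to sRGB primaries, white-balances to
#' the illuminant (so a wavelength-flat spectrum maps to an achromatic color),
#' clips to gamut, optionally gamma-encodes, and quantises to 0-255 integers.
#'
#' @param spectra Matrix of reflectances, one row per spectrum, one column per
#'   wavelength of `optics$wavelength_grid_nm`; values in \[0, 1\].
#' @param optics An [optics_config()].
#' @return Integer matrix, one row per spectrum, columns `red`, `green`, `blue`.
#' @keywords internal
spectra_to_rgb255 <- function(spectra, optics) {
  wl <- optics$wavelength_grid_nm
  spectra <- matrix(spectra, ncol = length(wl))
  cmf <- cie_cmf(wl)                      # equal-energy illuminant: S(lambda) = 1
  xyz <- spectra %*% cmf
  rgb_lin <- xyz %*% t(.xyz_to_rgb)
  white <- as.numeric(rep(1, length(wl)) %*% cmf %*% t(.xyz_to_rgb))
  rgb_lin <- sweep(rgb_lin, 2, white, "/") # illuminant white balance
  rgb_lin <- pmin(pmax(rgb_lin, 0), 1)
  if (optics$gamma_encode) rgb_lin <- srgb_encode(rgb_lin)
  out <- matrix(as.integer(round(rgb_lin * 255)), nrow = nrow(rgb_lin))
  colnames(out) <- c("red", "green", "blue")
  out
}
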