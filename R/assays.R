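# Spectrophotometric quantification: single-wavelength Beer-Lambert total
# anthocyanin, Folin-Ciocalteu total phenolics via a gallic-acid standard
# curve, and conversion of extract concentrations to per-100 g contents.

#' Beer-Lambert constants for the anthocyanin assay
#'
#' Defaults quantify total anthocyanin as cyanidin-3-glycoside equivalents
#' from a single 535 nm absorbance reading.
#'
#' @param molar_mass Molar mass, g/mol (default 449.2, cyanidin-3-glycoside).
#' @param molar_absorptivity Molar absorptivity, L/(mol cm) (default 26900).
#' @param path_length Cuvette path length, cm (default 1).
#' @param wavelength_nm Measurement wavelength, metadata (default 535).
#' @return An object of class `"assay_constants"`.
#' @export
assay_constants <- function(molar_mass = 449.2, molar_absorptivity = 26900,
                            path_length = 1, wavelength_nm = 535) {
  if (molar_mass <= 0 || molar_absorptivity <= 0 || path_length <= 0) {
    stop("invalid assay constants: all must be positive", call. = FALSE)
  }
  structure(list(molar_mass = molar_mass,
                 molar_absorptivity = molar_absorptivity,
                 path_length = path_length, wavelength_nm = wavelength_nm),
            class = "assay_constants")
}

#' Anthocyanin concentration from absorbance
#'
#' Beer-Lambert quantification: \eqn{C\,[g/L] = Abs \cdot MM / (\epsilon b)},
#' returned in mg/L and multiplied by the dilution factor of the read aliquot.
#'
#' @param absorbance Absorbance at 535 nm (>= 0; readings above 1.2 are
#'   outside the reliable photometric range and trigger a warning).
#' @param constants An [assay_constants()].
#' @param dilution_factor Dilution of the read aliquot relative to the extract
#'   (>= 1).
#' @return Concentration in the undiluted extract, mg/L.
#' @examples
#' anthocyanin_concentration(1.0)  # 449.2 / 26900 * 1000 = 16.699 mg/L
#' @export
anthocyanin_concentration <- function(absorbance, constants = assay_constants(),
                                      dilution_factor = 1) {
  stopifnot(inherits(constants, "assay_constants"))
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  if (any(absorbance > 1.2)) {
    warning("absorbance above 1.2: outside the reliable photometric range",
            call. = FALSE)
  }
  g_per_L <- absorbance * constants$molar_mass /
    (constants$molar_absorptivity * constants$path_length)
  g_per_L * 1000 * dilution_factor
}

#' Fit a linear standard curve
#'
#' Simple linear regression of absorbance on standard concentration, as used
#' for gallic-acid calibration of the Folin-Ciocalteu phenolics assay.
#'
#' @param concentrations Standard concentrations, mg/L (>= 3 points, >= 2
#'   distinct values).
#' @param absorbances Measured absorbances, same length.
#' @param analyte Analyte label (default `"gallic acid"`).
#' @return An object of class `"standard_curve"`: `slope` (absorbance per
#'   mg/L), `intercept`, `r_squared`, `analyte`.
#' @export
fit_standard_curve <- function(concentrations, absorbances,
                               analyte = "gallic acid") {
  if (length(concentrations) != length(absorbances) ||
      length(concentrations) < 3L || length(unique(concentrations)) < 2L) {
    stop("insufficient standards: need >= 3 points at >= 2 concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(absorbances ~ concentrations)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r_squared_of(absorbances, stats::fitted(fit)),
                 analyte = analyte),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve (%s): Abs = %.5g * C + %.5g, R2 = %.4f\n",
              x$analyte, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Phenolic concentration from absorbance via a standard curve
#'
#' Inverts the calibration line: \eqn{C = (Abs - a_0) / a_1}, multiplied by
#' the dilution factor. Negative results (absorbance below the blank) are
#' floored at zero with a warning.
#'
#' @param absorbance Absorbance at 760 nm.
#' @param curve A [fit_standard_curve()] result.
#' @param dilution_factor Dilution of the read aliquot (>= 1).
#' @return Concentration in mg gallic-acid equivalents per L.
#' @export
tpc_concentration <- function(absorbance, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("invalid curve: zero slope", call. = FALSE)
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  conc <- (absorbance - curve$intercept) / curve$slope * dilution_factor
  if (any(conc < 0)) {
    warning("negative concentration after blank correction; floored at 0",
            call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Extraction batch conditions
#'
#' @param sample_mass_g Ground plant material, g.
#' @param extract_volume_mL Standardized extract volume, mL.
#' @param dilution_factor Assay dilution (>= 1).
#' @param solvent,pH,temperature_C,duration_min Process metadata.
#' @return An object of class `"extraction_conditions"`.
#' @export
extraction_conditions <- function(sample_mass_g = 5, extract_volume_mL = 75,
                                  dilution_factor = 1,
                                  solvent = "70% ethanol (v/v), pH 2",
                                  pH = 2, temperature_C = NA_real_,
                                  duration_min = NA_real_) {
  if (sample_mass_g <= 0 || extract_volume_mL <= 0 || dilution_factor < 1) {
    stop("invalid extraction conditions", call. = FALSE)
  }
  structure(list(sample_mass_g = sample_mass_g,
                 extract_volume_mL = extract_volume_mL,
                 dilution_factor = dilution_factor, solvent = solvent,
                 pH = pH, temperature_C = temperature_C,
                 duration_min = duration_min),
            class = "extraction_conditions")
}

#' Extract concentration to per-100 g sample content
#'
#' \eqn{content = C \cdot (V / 1000) / m \cdot 100} — mg of analyte recovered
#' in the extract per 100 g of plant material as used (no moisture
#' correction).
#'
#' @param concentration_mg_L Analyte concentration in the extract, mg/L.
#' @param conditions An [extraction_conditions()].
#' @return Content in mg/100 g.
#' @examples
#' extract_content(16.699, extraction_conditions(5, 75))  # 25.048 mg/100 g
#' @export
extract_content <- function(concentration_mg_L, conditions = extraction_conditions()) {
  stopifnot(inherits(conditions, "extraction_conditions"))
  concentration_mg_L * (conditions$extract_volume_mL / 1000) /
    conditions$sample_mass_g * 100
}
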