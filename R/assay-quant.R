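#' Molar extinction coefficients used by the spectrophotometric assays
#'
#' Read-only table of the extinction coefficients used throughout the package:
#' NADPH at 340 nm (6220), the TNB anion released in the DTNB thiol assay at
#' 412 nm (14,100; one TNB counted per free thiol), triiodide formed in the
#' iodide peroxide assay at 358 nm (29,700), the horseradish-peroxidase
#' compound I difference coefficient at 403 nm (54,000, a difference spectrum),
#' and the tryptophan-derived cis/trans hydroperoxides at 295 nm (2750 / 2460).
#' All values in M^-1 cm^-1.
#'
#' @return A data.frame with columns `species_label`, `wavelength_nm`,
#'   `epsilon`, `is_delta`.
#' @export
#' @examples
#' extinction_coefficients()
extinction_coefficients <- function() {
  data.frame(
    species_label = c("NADPH", "TNB", "triiodide", "HRP_compound_I",
                      "cis-WOOH", "trans-WOOH"),
    wavelength_nm = c(340, 412, 358, 403, 295, 295),
    epsilon       = c(6220, 14100, 29700, 54000, 2750, 2460),
    is_delta      = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# look up epsilon by label; error on unknown species
lookup_epsilon <- function(species_label) {
  tab <- extinction_coefficients()
  i <- match(species_label, tab$species_label)
  if (is.na(i)) {
    stop("unknown species label '", species_label, "'; known: ",
         paste(tab$species_label, collapse = ", "))
  }
  tab$epsilon[i]
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' Converts a blank-corrected absorbance reading into a molar concentration,
#' `conc = (A - blank) / (epsilon * path) * dilution`.
#'
#' @param absorbance Measured absorbance (dimensionless).
#' @param epsilon Extinction coefficient in M^-1 cm^-1, or a species label
#'   present in [extinction_coefficients()].
#' @param blank Blank absorbance subtracted before conversion (default 0).
#' @param path_cm Optical path length in cm (default 1).
#' @param dilution Dilution factor of the sample into the assay (>= 1), by
#'   which the cuvette concentration is multiplied to recover the sample
#'   concentration.
#' @return Concentration in mol/L. Vectorized over `absorbance` and `blank`.
#' @export
#' @examples
#' conc_from_absorbance(0.622, epsilon = "NADPH")   # 1e-4 M
#' conc_from_absorbance(0.141, epsilon = "TNB", dilution = 30)
conc_from_absorbance <- function(absorbance, epsilon, blank = 0,
                                 path_cm = 1, dilution = 1) {
  if (is.character(epsilon)) epsilon <- lookup_epsilon(epsilon)
  stopifnot(epsilon > 0)
  if (any(path_cm <= 0)) stop("path length must be positive")
  if (any(dilution < 1)) stop("dilution factor must be >= 1")
  corrected <- absorbance - blank
  if (any(corrected < 0)) {
    stop("blank-corrected absorbance is negative: invalid reading")
  }
  corrected / (epsilon * path_cm) * dilution
}

#' Thiols per protein molecule
#'
#' Ratio of free-thiol concentration (e.g. from the DTNB assay) to protein
#' concentration. Used to gate pre-reduced protein preparations: the
#' quality windows (2-3 thiols for wild-type Prx2, 1-2 for C51S Prx2, 3-4 for
#' Prx4) are closed intervals on the real-valued ratio, no rounding.
#'
#' @param thiol_conc Free-thiol concentration, mol/L (>= 0).
#' @param protein_conc Protein concentration, mol/L (> 0).
#' @return Dimensionless ratio >= 0.
#' @export
thiols_per_protein <- function(thiol_conc, protein_conc) {
  if (any(protein_conc <= 0)) stop("protein concentration must be positive")
  if (any(thiol_conc < 0)) stop("thiol concentration must be non-negative")
  thiol_conc / protein_conc
}

#' Check a thiol-per-protein ratio against a preparation window
#'
#' @param ratio Real-valued thiols-per-protein ratio.
#' @param window Numeric length-2 closed interval, e.g. `c(2, 3)` for
#'   wild-type Prx2.
#' @return Logical.
#' @export
in_thiol_window <- function(ratio, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  ratio >= window[1] & ratio <= window[2]
}

#' Tissue concentration from analyte content per protein mass
#'
#' Converts an analyte content measured per mg of protein into an average
#' cellular concentration, assuming a given protein yield per g tissue, the
#' fraction of tissue mass that is intracellular volume, and a tissue density
#' of ~1 g/mL:
#' `conc_uM = content * protein_mass_per_tissue_mass / (cell_volume_fraction *
#' tissue_density)`.
#'
#' The default `protein_mass_per_tissue_mass = 1000` mg/g (i.e. treating the
#' per-mg content as per mg tissue) is the assumption that reproduces the
#' published arterial glutathione estimate of ~540 uM from a content of 0.4
#' nmol/mg with a 74 percent cell-volume fraction; it is exposed as an
#' explicit parameter because the protein-to-tissue conversion is otherwise
#' underdetermined.
#'
#' @param analyte_per_mass Analyte content in nmol per mg (>= 0).
#' @param cell_volume_fraction Fraction of tissue mass contributed by cells,
#'   in (0, 1]; default 0.74 (endothelial plus smooth-muscle share of
#'   resistance arteries).
#' @param tissue_density Tissue density in g/mL (default 1).
#' @param protein_mass_per_tissue_mass Protein mass per tissue mass in mg/g
#'   (default 1000).
#' @return Concentration in umol/L.
#' @export
#' @examples
#' tissue_concentration(0.4)   # ~540 uM
tissue_concentration <- function(analyte_per_mass,
                                 cell_volume_fraction = 0.74,
                                 tissue_density = 1,
                                 protein_mass_per_tissue_mass = 1000) {
  if (any(analyte_per_mass < 0)) stop("analyte content must be non-negative")
  if (any(cell_volume_fraction <= 0 | cell_volume_fraction > 1)) {
    stop("cell_volume_fraction must be in (0, 1]")
  }
  if (any(tissue_density <= 0)) stop("tissue density must be positive")
  if (any(protein_mass_per_tissue_mass <= 0)) {
    stop("protein_mass_per_tissue_mass must be positive")
  }
  analyte_per_mass * protein_mass_per_tissue_mass /
    (cell_volume_fraction * tissue_density)
}

#' Amount from an isotope-dilution calibration line
#'
#' Inverts a calibration line of analyte/internal-standard area ratio against
#' loaded amount: `amount = (area_ratio - intercept) / slope`. Amounts below
#' the assay's lower limit of detection are flagged `below_lod` (the
#' glutathione LC-MS/MS assay has LODs of 0.0125 pmol for GSH-NEM and 0.005
#' pmol for GSSG); negative inverted amounts are flagged `below_blank`.
#'
#' @param area_ratio Observed analyte-to-internal-standard peak-area ratio.
#' @param slope Calibration slope, signal per pmol (non-zero).
#' @param intercept Calibration intercept (default 0).
#' @param lod Lower limit of detection in the amount unit, or NA to skip the
#'   check.
#' @return data.frame with columns `amount`, `below_lod`, `below_blank`,
#'   vectorized over `area_ratio`.
#' @export
isotope_dilution_amount <- function(area_ratio, slope, intercept = 0,
                                    lod = NA_real_) {
  if (slope == 0) stop("calibration slope must be non-zero")
  amount <- (area_ratio - intercept) / slope
  data.frame(
    amount = amount,
    below_lod = if (is.na(lod)) rep(FALSE, length(amount)) else amount < lod,
    below_blank = amount < 0)
}
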