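#' Catalogue of principal Raman bands of cortical tissue
#'
#' The 17 principal Raman bands observed in normal cortex and focal cortical
#' dysplasia (FCD) type II cells, with their tentative biomolecular
#' assignments and the group in which each band is more intense (`FCD` or
#' `normal` for the disease-vs-control contrast; `IIa` or `IIb` where the
#' band separates the two FCD subtypes). These positions define the expected
#' feature space of the classifier and the band table of the synthetic
#' generator.
#'
#' @return data.frame with columns `position` (cm^-1), `vibration_mode`,
#'   `molecule`, `higher_in`, and logical `sig_fcd_vs_normal` /
#'   `sig_iia_vs_iib` flags marking bands with significant group differences.
#' @export
#' @examples
#' cat17 <- band_catalogue()
#' nrow(cat17)                       # 17
#' band_lookup(1002)$molecule        # phenylalanine ring-breathing band
band_catalogue <- function() {
  data.frame(
    position = c(758, 827, 852, 933, 1002, 1031, 1101, 1124, 1201, 1263,
                 1302, 1337, 1447, 1554, 1593, 1602, 1657),
    vibration_mode = c(
      "nu_s indole ring breathing",
      "nu_2 PO2- stretch",
      "tyrosine ring breathing and proline",
      "nu(C-C) skeletal of collagen backbone",
      "nu ring breathing",
      "delta(C-H) and bending mode",
      "amide III",
      "nu(C-C) skeletal of acyl backbone in lipid (trans conformation)",
      "amide III",
      "ring breathing modes of the DNA/RNA bases; =C-H bend (protein)",
      "delta(CH2) twisting, wagging, and phospholipid",
      "ring breathing modes in the DNA bases",
      "CH2 deformation (protein vibration)",
      "nu(CN) and (NH) amide I",
      "C=C vibration",
      "delta(C=C)",
      "amide I and fatty acids"),
    molecule = c(
      "Tryptophan",
      "Nucleic acid",
      "Protein (collagen)",
      "Protein (collagen)",
      "Phenylalanine and protein",
      "Phenylalanine and protein",
      "Proteins",
      "Lipid",
      "Proteins",
      "DNA/RNA",
      "Lipid and protein combination",
      "DNA",
      "A marker for protein concentration",
      "Protein",
      "Retinoid and enzymes",
      "Phenylalanine and protein",
      "Triglycerides"),
    higher_in = c("FCD", "FCD", "FCD", "FCD", "normal", "normal", "IIb",
                  "IIb", "IIb", "FCD", "normal", "FCD", "normal", "FCD",
                  "IIb", "FCD", "FCD"),
    sig_fcd_vs_normal = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                          FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE, FALSE),
    sig_iia_vs_iib = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                       TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                       TRUE),
    stringsAsFactors = FALSE
  )
}

#' Look up catalogue bands near a position
#'
#' @param position Query position in cm^-1.
#' @param tolerance Half-width of the match window in cm^-1 (default 0.5,
#'   i.e. essentially exact lookup).
#' @return The matching catalogue rows; zero rows when no band is within
#'   `tolerance`.
#' @export
band_lookup <- function(position, tolerance = 0.5) {
  cat17 <- band_catalogue()
  cat17[abs(cat17$position - position) <= tolerance, , drop = FALSE]
}

# Band-contrast directions observed between group mean spectra:
# +1 means the first-named group has the larger mean band height.
# Used by the synthetic generator's class profiles.
contrast_fcd_vs_normal <- function() {
  d <- stats::setNames(numeric(17), as.character(band_catalogue()$position))
  d[as.character(c(758, 827, 852, 933, 1263, 1337, 1554, 1602, 1657))] <- 1
  d[as.character(c(1002, 1031, 1302, 1447))] <- -1
  d
}

contrast_iib_vs_iia <- function() {
  d <- stats::setNames(numeric(17), as.character(band_catalogue()$position))
  d[as.character(c(852, 1031, 1101, 1124, 1201, 1263, 1302, 1447,
                   1554, 1593))] <- 1
  d[as.character(1002)] <- -1
  d
}
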