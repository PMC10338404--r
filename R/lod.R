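#' Detection-limit model for PTMs in 1H-13C HSQC spectra
#'
#' The smallest modification concentration that still produces detectable
#' cross-peaks in a standard 5 mm tube experiment is an empirical input
#' (default 55 umol/L for typical overnight measurements on cryoprobe
#' instruments). The minimal detectable modification fraction then scales
#' inversely with the protein concentration, and the absolute detectable
#' amount with the sample volume.
#'
#' @param lod_concentration Empirical LOD concentration in umol/L
#'   (default 55).
#' @param sample_volume Sample volume in uL (default 500).
#' @return An `lod_model` list.
#' @export
lod_model <- function(lod_concentration = 55, sample_volume = 500) {
  if (lod_concentration <= 0 || sample_volume <= 0)
    stopf("lod_concentration and sample_volume must be > 0")
  structure(list(lod_concentration = lod_concentration,
                 sample_volume = sample_volume),
            class = "lod_model")
}

#' Minimal detectable modification fraction at a protein concentration
#'
#' `100 * min(1, lod_concentration / protein_conc)` percent: the higher
#' the protein concentration, the lower the modification percentage per
#' molecule that can still be seen; at or below the LOD concentration the
#' fraction is capped at 100%. The display value is rounded half-up to the
#' nearest integer percent; the exact value is retained.
#'
#' @param protein_conc Protein concentration in umol/L (> 0).
#' @param model An [lod_model()].
#' @return List with `percent` (exact) and `percent_display` (integer).
#' @examples
#' min_detectable_fraction(220)$percent_display  # 25
#' min_detectable_fraction(900)$percent_display  # 6 (from 6.1)
#' @export
min_detectable_fraction <- function(protein_conc, model = lod_model()) {
  if (!is.finite(protein_conc) || protein_conc <= 0)
    stopf("protein concentration must be > 0")
  pct <- 100 * min(1, model$lod_concentration / protein_conc)
  list(percent = pct, percent_display = round_half_up(pct))
}

#' Absolute amount corresponding to a concentration and sample volume
#'
#' `conc [umol/L] x volume [uL] x 1e-3` nanomoles; display value rounded
#' half-up to the nearest nmol (55 umol/L in 500 uL is 27.5 nmol exact,
#' 28 nmol displayed).
#'
#' @param conc Concentration in umol/L (> 0).
#' @param volume Sample volume in uL (> 0).
#' @return List with `nmol` (exact) and `nmol_display` (integer).
#' @export
absolute_amount <- function(conc, volume) {
  if (!is.finite(conc) || conc <= 0 || !is.finite(volume) || volume <= 0)
    stopf("concentration and volume must be > 0")
  nmol <- conc * volume * 1e-3
  list(nmol = nmol, nmol_display = round_half_up(nmol))
}
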