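#' Load the Amadori-product chemical-shift fingerprint library
#'
#' Returns the DSS-referenced cross-peak fingerprint of the cyclic forms of
#' fructoselysine (the Amadori product of glucose and a lysine side chain)
#' as observed in denatured proteins. The dominant beta-pyranose form
#' carries experimentally determined positions; its C5-H5, C6-H6 and C6-H6'
#' correlations are flagged `diagnostic` because they do not superimpose
#' with protein or glycan signals and are the specific markers for
#' glucose-induced glycation. The minor forms (both furanoses and the
#' alpha-pyranose) have synthetic placeholder positions, at least 1 ppm
#' (13C) away from the diagnostic markers; only their equilibrium
#' populations (0.70/0.13/0.13/0.04) are meaningful.
#'
#' C1-H1 is retained but flagged `exchange_affected`: in D2O its protons
#' exchange with solvent deuterium, attenuating and shifting the signal, so
#' it is excluded from quantification by default. C2 is quaternary after
#' cyclization and carries no proton (`hsqc_visible = FALSE`).
#'
#' @param file Path to a library CSV. Default: the versioned file shipped
#'   with the package.
#' @return A `shift_library`: a data.frame with columns `form`, `label`,
#'   `c13`, `h1`, `multiplicity`, `protons_in_signal`, `diagnostic`,
#'   `exchange_affected`, `hsqc_visible`, `population`, plus attributes
#'   `reference_standard` ("DSS") and `source_column` ("BSA").
#' @examples
#' lib <- amadori_library()
#' lookup_correlation(lib, "beta-pyranose", "C5-H5")
#' @export
amadori_library <- function(file = NULL) {
  file <- file %||% system.file("extdata", "amadori_library.csv",
                                package = "amadoriNMR", mustWork = TRUE)
  raw <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  lib <- data.frame(
    form = raw$form,
    label = raw$label,
    c13 = raw$c13_ppm,
    h1 = raw$h1_ppm,
    multiplicity = raw$multiplicity,
    protons_in_signal = raw$protons_in_signal,
    diagnostic = raw$diagnostic,
    exchange_affected = raw$exchange_affected,
    hsqc_visible = raw$hsqc_visible,
    population = raw$population,
    stringsAsFactors = FALSE
  )
  new_shift_library(lib, reference_standard = "DSS", source_column = "BSA")
}

#' Construct and validate a shift library
#'
#' @param correlations data.frame with the columns documented in
#'   [amadori_library()].
#' @param reference_standard Chemical-shift zero-point standard the values
#'   are referenced to; internal convention is DSS.
#' @param source_column Provenance tag of the main-form values.
#' @return A validated `shift_library`.
#' @export
new_shift_library <- function(correlations, reference_standard = "DSS",
                              source_column = "custom") {
  lib <- correlations
  needed <- c("form", "label", "c13", "h1", "multiplicity",
              "protons_in_signal", "diagnostic", "exchange_affected",
              "hsqc_visible", "population")
  missing_cols <- setdiff(needed, names(lib))
  if (length(missing_cols))
    stopf("shift library lacks columns: %s", paste(missing_cols, collapse = ", "))

  vis <- lib[lib$hsqc_visible, ]
  if (any(vis$c13 < 0 | vis$c13 > 220))
    stopf("13C shifts must lie in [0, 220] ppm")
  if (any(vis$h1 < 0 | vis$h1 > 13))
    stopf("1H shifts must lie in [0, 13] ppm")
  if (!all(vis$protons_in_signal %in% c(1L, 2L)))
    stopf("protons_in_signal must be 1 or 2 for HSQC-visible correlations")
  if (any(vis$diagnostic & !vis$multiplicity %in% c("CH", "CH2")))
    stopf("diagnostic correlations must be CH or CH2")

  pops <- tapply(lib$population, lib$form, unique)
  if (any(lengths(pops) != 1))
    stopf("each form must carry a single population value")
  pops <- vapply(pops, identity, numeric(1))
  if (any(pops < 0) || sum(pops) > 1 + 1e-9)
    stopf("form populations must be non-negative and sum to <= 1")
  if ("beta-pyranose" %in% names(pops) &&
      pops[["beta-pyranose"]] < max(pops) - 1e-12)
    stopf("beta-pyranose must be the most populated form")

  structure(lib,
            class = c("shift_library", "data.frame"),
            reference_standard = reference_standard,
            source_column = source_column)
}

#' Look up one correlation of one Amadori form
#'
#' @param library A `shift_library`.
#' @param form Form name, e.g. `"beta-pyranose"`.
#' @param label Correlation label, e.g. `"C6-H6'"`.
#' @return One-row data.frame with the correlation's fields.
#' @export
lookup_correlation <- function(library, form, label) {
  hit <- library[library$form == form & library$label == label, , drop = FALSE]
  if (nrow(hit) == 0)
    stopf("no correlation '%s' in form '%s'", label, form)
  as.data.frame(hit)
}

#' Diagnostic marker correlations of a form
#'
#' The markers whose match is required for a positive glycation call:
#' for the beta-pyranose form these are C5-H5, C6-H6 and C6-H6'.
#'
#' @inheritParams lookup_correlation
#' @return data.frame of diagnostic, HSQC-visible correlations.
#' @export
diagnostic_correlations <- function(library, form = "beta-pyranose") {
  as.data.frame(library[library$form == form & library$diagnostic &
                          library$hsqc_visible, , drop = FALSE])
}

# Fixed additive offsets of each supported zero-point standard relative to
# DSS, derived from reference-standard conversion footnotes: TMS-referenced
# 13C values need +2.5 ppm and 1,4-dioxane-referenced values +1.8 ppm to be
# put on the DSS scale.
.ref_offsets_to_dss <- c(DSS = 0, TMS = 2.5, dioxane = 1.8)

#' Convert a 13C chemical shift between referencing standards
#'
#' Chemical-shift values in the literature are reported against different
#' zero-point standards. This applies the fixed additive offsets that bring
#' TMS-referenced (+2.5 ppm) and 1,4-dioxane-referenced (+1.8 ppm) 13C
#' values onto the DSS scale; conversions between any two standards are
#' composed from these.
#'
#' @param shift Shift value(s) in ppm.
#' @param from,to Referencing standards, each one of `"DSS"`, `"TMS"`,
#'   `"dioxane"`.
#' @return Shift in ppm on the `to` standard.
#' @examples
#' convert_reference(53.1, "TMS", "DSS")   # 55.6
#' convert_reference(70.6, "dioxane", "DSS") # 72.4
#' @export
convert_reference <- function(shift, from, to) {
  for (std in c(from, to)) {
    if (!std %in% names(.ref_offsets_to_dss))
      stopf("unknown referencing standard '%s' (use DSS, TMS or dioxane)", std)
  }
  shift + .ref_offsets_to_dss[[from]] - .ref_offsets_to_dss[[to]]
}

#' Load the random-coil chemical-shift table
#'
#' Residue-type random-coil 1H/13C correlations of the 20 proteinogenic
#' amino acids as observed in urea-denatured proteins, DSS-referenced,
#' taken from standard literature compilations. Two special rows
#' (`pre_pro = TRUE`) hold the proline-perturbed Ca-Ha anchor positions of
#' Ser (56.6/4.71 ppm) and Thr (60.1/4.60 ppm) immediately preceding a
#' proline; these often give isolated single-residue cross-peaks that serve
#' as CH reference integrals for quantification.
#'
#' @param file Path to a table CSV. Default: the versioned file shipped
#'   with the package.
#' @return A `random_coil_table`: data.frame with columns `residue`,
#'   `label`, `c13`, `h1`, `multiplicity`, `protons_in_signal`, `pre_pro`.
#' @export
random_coil_table <- function(file = NULL) {
  file <- file %||% system.file("extdata", "random_coil_shifts.csv",
                                package = "amadoriNMR", mustWork = TRUE)
  raw <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  tab <- data.frame(
    residue = raw$residue,
    label = raw$label,
    c13 = raw$c13_ppm,
    h1 = raw$h1_ppm,
    multiplicity = raw$multiplicity,
    protons_in_signal = raw$protons_in_signal,
    pre_pro = raw$pre_pro,
    stringsAsFactors = FALSE
  )
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  have_ca <- unique(tab$residue[grepl("Ca-Ha", tab$label) & !tab$pre_pro])
  if (!all(aa %in% have_ca))
    stopf("random-coil table lacks Ca-Ha entries for: %s",
          paste(setdiff(aa, have_ca), collapse = ", "))
  structure(tab, class = c("random_coil_table", "data.frame"))
}
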