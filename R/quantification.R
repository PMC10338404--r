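#' Select reference signals for stoichiometry quantification
#'
#' Ranks candidate protein reference cross-peaks for per-proton volume
#' normalization. A good reference is an isolated, well-integrable
#' random-coil signal with a known residue count: either a residue-type
#' signal (e.g. the Arg Cd-Hd of all arginines, or the Gln Cg-Hg) or the
#' rare single-residue signal of a Ser/Thr preceding a proline, whose Ca-Ha
#' is pushed to a unique anchor position. Isolation is scored as the
#' minimum tolerance-normalized distance to every other predicted protein
#' or Amadori cross-peak.
#'
#' @param sequence One-letter protein sequence.
#' @param coil Random-coil table ([random_coil_table()]).
#' @param library Amadori fingerprint, used only to penalize candidates
#'   near Amadori positions.
#' @param tol_c13,tol_h1 Normalization scales for the isolation score.
#' @return A `reference_signals` data.frame: `label`, `residue`, `c13`,
#'   `h1`, `multiplicity`, `protons_in_signal`, `n` (occurrences in the
#'   sequence), `preferred`, `isolation`, `volume` (NA until measured),
#'   sorted preferred-first then most-isolated-first. Attribute
#'   `disabled_classes` lists multiplicity classes with no candidate.
#' @export
select_reference_signals <- function(sequence, coil = random_coil_table(),
                                     library = amadori_library(),
                                     tol_c13 = 0.4, tol_h1 = 0.04) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0) stopf("sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  n_aa <- length(aa)
  pre_pro <- which(aa %in% c("S", "T") &
                     c(aa[-1], "") == "P" & seq_len(n_aa) < n_aa)
  anchor_counts <- table(factor(aa[pre_pro], levels = c("S", "T")))
  counts <- table(factor(aa, levels = unique(coil$residue)))

  rows <- list()
  for (i in seq_len(nrow(coil))) {
    rc <- coil[i, ]
    n <- as.integer(counts[rc$residue])
    if (is.na(n) || n == 0) next
    if (rc$pre_pro) {
      n <- as.integer(anchor_counts[rc$residue])
      if (is.na(n) || n == 0) next
    } else if (grepl("Ca-Ha", rc$label) && rc$residue %in% c("S", "T")) {
      n <- n - as.integer(anchor_counts[rc$residue])
      if (n == 0) next
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = rc$label, residue = rc$residue, c13 = rc$c13, h1 = rc$h1,
      multiplicity = rc$multiplicity, protons_in_signal = rc$protons_in_signal,
      n = n, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no reference candidates for this sequence")
  cand <- do.call(rbind, rows)

  lib_vis <- library[library$hsqc_visible, ]
  all_c13 <- c(cand$c13, lib_vis$c13)
  all_h1 <- c(cand$h1, lib_vis$h1)
  cand$isolation <- vapply(seq_len(nrow(cand)), function(i) {
    d <- sqrt(((cand$c13[i] - all_c13) / tol_c13)^2 +
                ((cand$h1[i] - all_h1) / tol_h1)^2)
    min(d[-i])
  }, numeric(1))

  preferred_labels <- c("Ser(-Pro) Ca-Ha", "Thr(-Pro) Ca-Ha", "Gln Cg-Hg",
                        "Glu Cg-Hg", "Arg Cd-Hd", "Phe Ca-Ha", "Ile Cb-Hb",
                        "Gly Ca-Ha")
  cand$preferred <- cand$label %in% preferred_labels
  cand$volume <- NA_real_
  cand <- cand[order(-cand$preferred, -cand$isolation, cand$label), ]
  rownames(cand) <- NULL

  disabled <- setdiff(c("CH", "CH2"), unique(cand$multiplicity))
  if (length(disabled))
    warnf("no %s reference candidate in this sequence; %s quantification disabled",
          paste(disabled, collapse = "/"), paste(disabled, collapse = "/"))
  structure(cand, class = c("reference_signals", "data.frame"),
            disabled_classes = disabled)
}

#' Measure reference volumes from a peak list
#'
#' Fills the `volume` column of a `reference_signals` table by matching
#' each reference position to the nearest peak inside the tolerance box
#' (each peak used at most once, greedy by normalized distance).
#'
#' @param references A `reference_signals` table.
#' @param peaklist An integrated [peak_list()] (`value_type = "volume"`).
#' @param tol_c13,tol_h1 Matching tolerances (ppm).
#' @return The `reference_signals` table with `volume` filled where a peak
#'   was found.
#' @export
measure_reference_volumes <- function(references, peaklist,
                                      tol_c13 = 0.4, tol_h1 = 0.04) {
  if (attr(peaklist, "value_type") != "volume")
    stopf("peak list carries heights, not volumes; integrate first")
  nr <- nrow(references); np <- nrow(peaklist)
  if (np == 0) return(references)
  pairs <- expand.grid(ri = seq_len(nr), pi = seq_len(np))
  dC <- peaklist$c13[pairs$pi] - references$c13[pairs$ri]
  dH <- peaklist$h1[pairs$pi] - references$h1[pairs$ri]
  keep <- abs(dC) <= tol_c13 & abs(dH) <= tol_h1
  cand <- data.frame(ri = pairs$ri[keep], pi = pairs$pi[keep],
                     dist = sqrt((dC[keep] / tol_c13)^2 + (dH[keep] / tol_h1)^2))
  cand <- cand[order(cand$dist, cand$pi), , drop = FALSE]
  used <- rep(FALSE, np); done <- rep(FALSE, nr)
  for (r in seq_len(nrow(cand))) {
    ri <- cand$ri[r]; pi <- cand$pi[r]
    if (!done[ri] && !used[pi]) {
      references$volume[ri] <- abs(peaklist$volume[pi])
      done[ri] <- TRUE; used[pi] <- TRUE
    }
  }
  references
}

#' Per-proton normalized volume
#'
#' The volume corresponding to a single proton: the measured reference
#' integral divided by the occurrence `n` of the residue type in the
#' sequence and, when a CH2 group gives one unresolved signal, by the
#' factor `p = 2`.
#'
#' @param v_ref Measured reference volume (> 0).
#' @param n Residue count in the sequence (>= 1).
#' @param p Protons contributing to the single signal (1 or 2).
#' @return `v_ref / (n * p)`.
#' @examples
#' normalized_volume(46, 23, 2)  # 1: 23 arginines, unresolved CH2
#' @export
normalized_volume <- function(v_ref, n, p) {
  if (!is.finite(v_ref) || v_ref <= 0) stopf("reference volume must be > 0")
  if (n < 1) stopf("residue count must be >= 1")
  if (!p %in% c(1, 2)) stopf("protons_in_signal must be 1 or 2")
  v_ref / (n * p)
}

#' Estimate glycation stoichiometry from matched marker volumes
#'
#' Implements the per-proton volume-comparison rule: each usable Amadori
#' marker volume is divided by the per-proton normalized volume of a
#' protein reference of the same multiplicity class - CH markers only
#' against CH references, CH2 markers only against CH2 references, never
#' across (HSQC response differs between classes under the compromise
#' INEPT delay, so integrals are only comparable within a class). Each
#' per-marker ratio `g_i` estimates glycations per molecule; the aggregate
#' `G` is their unweighted mean, and `100 * G` expresses the result as
#' percent of molecules glycated (meaningful when `G <= 1`).
#'
#' Markers flagged as overlapping, the solvent-exchange-affected C1-H1,
#' and the congested Lys Ce-He are excluded by default. When a resolved
#' CH2-carbon pair (H6/H6') is used, each resolved line carries
#' `protons_in_signal = 1`; the divide-by-2 rule applies only to a single
#' unresolved CH2 signal.
#'
#' Marker volumes scale with the equilibrium population of the matched
#' form (about 0.70 for the beta-pyranose). The default
#' `form_population = 1` reproduces the plain ratio convention (reported
#' stoichiometries quoted directly from beta-pyranose volumes); pass the
#' actual population to convert marker volumes into total Amadori
#' stoichiometry across all forms.
#'
#' @param match_report A `match_report` from [match_amadori()] /
#'   [detect_glycation()].
#' @param references A `reference_signals` table with measured volumes
#'   ([measure_reference_volumes()]).
#' @param form Which Amadori form's markers to quantify (default
#'   beta-pyranose).
#' @param form_population Equilibrium fraction of `form` used to scale
#'   marker estimates to total stoichiometry (default 1 = no scaling).
#' @param include_exchange_affected,include_lys Override the default
#'   exclusions.
#' @param only_c6 Use only the C6-H6/C6-H6' markers (for crowded spectra
#'   where only those are isolated).
#' @param force Quantify even when the match report did not call presence.
#' @return A `quantification_report`: list with `per_marker` (label,
#'   class, volume, estimate `g`), `g` (aggregate glycations per
#'   molecule), `percent_molecules` (`100 * g`), `references_used`,
#'   `form_population`, `excluded` and `warnings`.
#' @export
quantify_glycation <- function(match_report, references,
                               form = "beta-pyranose",
                               form_population = 1,
                               include_exchange_affected = FALSE,
                               include_lys = FALSE,
                               only_c6 = FALSE,
                               force = FALSE) {
  stopifnot(inherits(match_report, "match_report"))
  if (!isTRUE(attr(match_report, "presence")) && !force)
    stopf("match report did not call glycation presence; use force = TRUE to quantify anyway")
  if (form_population <= 0 || form_population > 1)
    stopf("form_population must be in (0, 1]")

  rep_df <- as.data.frame(match_report)
  m <- rep_df[rep_df$form == form & rep_df$matched, , drop = FALSE]
  warnings <- character(0)
  excluded <- character(0)
  drop <- rep(FALSE, nrow(m))
  if (!include_exchange_affected && any(m$exchange_affected)) {
    excluded <- c(excluded, sprintf("%s (solvent exchange)",
                                    m$label[m$exchange_affected]))
    drop <- drop | m$exchange_affected
  }
  if (!include_lys) {
    is_lys <- grepl("^Lys", m$label)
    if (any(is_lys)) {
      excluded <- c(excluded, sprintf("%s (congested region)", m$label[is_lys]))
      drop <- drop | is_lys
    }
  }
  ov <- !is.na(m$overlap) & m$overlap
  if (any(ov)) {
    excluded <- c(excluded, sprintf("%s (overlapping signal)", m$label[ov]))
    drop <- drop | ov
  }
  m <- m[!drop, , drop = FALSE]
  if (only_c6) m <- m[grepl("^C6", m$label), , drop = FALSE]
  if (nrow(m) == 0) stopf("no usable %s marker volumes to quantify", form)
  if (any(is.na(m$volume)))
    stopf("matched markers carry no volumes; integrate the spectrum first")

  refs <- references[!is.na(references$volume) & references$volume > 0, ,
                     drop = FALSE]
  norm_ref <- list()
  ref_used <- list()
  for (cls in c("CH", "CH2")) {
    rc <- refs[refs$multiplicity == cls, , drop = FALSE]
    if (nrow(rc) > 0) {
      norm_ref[[cls]] <- normalized_volume(rc$volume[1], rc$n[1],
                                           rc$protons_in_signal[1])
      ref_used[[cls]] <- rc[1, c("label", "n", "protons_in_signal", "volume")]
    }
  }

  usable <- m$multiplicity %in% names(norm_ref)
  if (!any(usable)) {
    stopf("no measured reference of class %s available for the %s markers",
          paste(setdiff(unique(m$multiplicity), names(norm_ref)),
                collapse = "/"), form)
  }
  if (any(!usable)) {
    msg <- sprintf("no reference for class %s; markers dropped: %s",
                   paste(setdiff(unique(m$multiplicity[!usable]),
                                 names(norm_ref)), collapse = "/"),
                   paste(m$label[!usable], collapse = ", "))
    warnf("%s", msg)
    warnings <- c(warnings, msg)
    m <- m[usable, , drop = FALSE]
  }

  g_i <- vapply(seq_len(nrow(m)), function(i) {
    abs(m$volume[i]) /
      (norm_ref[[m$multiplicity[i]]] * m$protons_in_signal[i] * form_population)
  }, numeric(1))

  per_marker <- data.frame(label = m$label, class = m$multiplicity,
                           volume = abs(m$volume), g = g_i,
                           stringsAsFactors = FALSE)
  g <- mean(g_i)
  structure(list(per_marker = per_marker,
                 g = g,
                 percent_molecules = 100 * g,
                 references_used = ref_used,
                 form = form,
                 form_population = form_population,
                 excluded = excluded,
                 warnings = warnings),
            class = "quantification_report")
}

#' @export
print.quantification_report <- function(x, ...) {
  cat(sprintf("<quantification_report> %s markers\n", x$form))
  print(x$per_marker, digits = 3)
  cat(sprintf("glycations per molecule: %.2f (marker range %.2f-%.2f)\n",
              x$g, min(x$per_marker$g), max(x$per_marker$g)))
  if (x$g <= 1)
    cat(sprintf("%% of molecules glycated: %.0f%%\n", x$percent_molecules))
  for (e in x$excluded) cat(" excluded:", e, "\n")
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' Relative equilibrium abundances of the Amadori forms
#'
#' Estimates the equilibrium fractions of the cyclic Amadori forms from
#' matched cross-peak volumes. Comparability across forms is enforced by
#' restricting each form to the correlation labels (with identical
#' multiplicity and protons-per-signal) matched in every form, averaging
#' their per-proton volumes, and normalizing the per-form means to sum
#' to 1.
#'
#' @param match_report A `match_report` covering all library forms.
#' @return Named numeric vector of fractions summing to 1 over the matched
#'   forms. When only one form is matched, returns 1 for it with a
#'   dominance-only warning.
#' @export
relative_form_abundances <- function(match_report) {
  stopifnot(inherits(match_report, "match_report"))
  m <- as.data.frame(match_report)
  m <- m[m$matched & !is.na(m$volume), , drop = FALSE]
  if (nrow(m) == 0) stopf("no matched correlations with volumes")
  forms <- unique(m$form)
  if (length(forms) == 1) {
    warnf("only one form matched; reporting dominance only")
    return(setNames(1, forms))
  }
  m$key <- paste(m$label, m$multiplicity, m$protons_in_signal)
  common <- Reduce(intersect, split(m$key, m$form))
  if (length(common) == 0)
    stopf("matched forms share no comparable correlation (same label, multiplicity and protons)")
  m <- m[m$key %in% common, , drop = FALSE]
  per_form <- tapply(abs(m$volume) / m$protons_in_signal, m$form, mean)
  fr <- per_form / sum(per_form)
  setNames(as.numeric(fr), names(fr))
}
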