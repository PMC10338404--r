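#' Simulation configuration for synthetic HSQC spectra
#'
#' Collects and validates everything [simulate_hsqc()] needs. Defaults
#' emulate a multiplicity-edited 1H-13C HSQC of a urea-denatured protein:
#' random-coil cross-peaks from the sequence composition, Amadori-product
#' cross-peaks at the library positions with the equilibrium populations of
#' fructoselysine (beta-pyranose 0.70, both furanoses 0.13 each,
#' alpha-pyranose 0.04; open forms < 1% are neglected), axis-aligned 2D
#' Gaussian lineshapes, additive white noise, and deuterium-exchange
#' attenuation of C1-H1.
#'
#' Per-unit-proton volume is identical for protein and Amadori peaks within
#' one multiplicity class; the relative HSQC response of CH2 vs CH under
#' the compromise INEPT delay is not known, so `ch2_response` is an
#' explicit free parameter, not an estimate of it.
#'
#' @param sequence One-letter protein sequence.
#' @param glycations_per_molecule Expected Amadori stoichiometry G (>= 0).
#' @param form_populations Named fractions per Amadori form; non-negative,
#'   sum <= 1.
#' @param sigma_c13,sigma_h1 Gaussian lineshape sigmas (ppm).
#' @param noise_sigma Additive white-noise sigma (intensity units; 0 for a
#'   noiseless spectrum).
#' @param h1_exchange_attenuation Multiplier in \[0,1\] applied to the
#'   exchange-affected C1-H1 volume (default 0.8).
#' @param ch2_response Per-proton response of CH2 (and the CH2-carbon H6
#'   pair) relative to CH (default 0.85).
#' @param grid List with `c13_min`, `c13_max`, `c13_step`, `h1_min`,
#'   `h1_max`, `h1_step` (ppm). Default covers 13C 40-105 at 0.05 ppm/pt
#'   and 1H 2.5-5.5 at 0.005 ppm/pt.
#' @param seed Integer seed; drives the noise realization only (positions
#'   and volumes are deterministic functions of the other fields).
#' @param decoy_peaks Optional data.frame (`c13`, `h1`, `volume`, `sign`,
#'   `multiplicity`) of extra non-Amadori peaks (e.g. glycan decoys) for
#'   specificity tests.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(sequence,
                              glycations_per_molecule = 0,
                              form_populations = c("beta-pyranose" = 0.70,
                                                   "beta-furanose" = 0.13,
                                                   "alpha-furanose" = 0.13,
                                                   "alpha-pyranose" = 0.04),
                              sigma_c13 = 0.05,
                              sigma_h1 = 0.005,
                              noise_sigma = 0,
                              h1_exchange_attenuation = 0.8,
                              ch2_response = 0.85,
                              grid = list(c13_min = 40, c13_max = 105,
                                          c13_step = 0.05,
                                          h1_min = 2.5, h1_max = 5.5,
                                          h1_step = 0.005),
                              seed = 1L,
                              decoy_peaks = NULL) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0) stopf("sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  valid <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  bad <- which(!aa %in% valid)
  if (length(bad))
    stopf("unknown residue letter(s) at position(s): %s",
          paste(bad, collapse = ", "))
  if (glycations_per_molecule < 0) stopf("glycations_per_molecule must be >= 0")
  if (any(form_populations < 0) || sum(form_populations) > 1 + 1e-9)
    stopf("form populations must be non-negative and sum to <= 1")
  if (sigma_c13 <= 0 || sigma_h1 <= 0) stopf("lineshape sigmas must be > 0")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (h1_exchange_attenuation < 0 || h1_exchange_attenuation > 1)
    stopf("h1_exchange_attenuation must be in [0, 1]")
  if (ch2_response <= 0) stopf("ch2_response must be > 0")
  for (k in c("c13_min", "c13_max", "c13_step", "h1_min", "h1_max", "h1_step"))
    if (is.null(grid[[k]])) stopf("grid lacks '%s'", k)
  if (grid$c13_step <= 0 || grid$h1_step <= 0) stopf("grid steps must be > 0")

  structure(list(sequence = sequence,
                 glycations_per_molecule = glycations_per_molecule,
                 form_populations = form_populations,
                 sigma_c13 = sigma_c13, sigma_h1 = sigma_h1,
                 noise_sigma = noise_sigma,
                 h1_exchange_attenuation = h1_exchange_attenuation,
                 ch2_response = ch2_response,
                 grid = grid, seed = as.integer(seed),
                 decoy_peaks = decoy_peaks),
            class = "simulation_config")
}

# per-proton response scale of a multiplicity class
.class_scale <- function(multiplicity, config) {
  ifelse(multiplicity == "CH2", config$ch2_response, 1.0)
}

# Deterministic true peak table for a config: protein random-coil peaks
# (counts from sequence composition, Ser/Thr before Pro moved to their
# anchor positions) plus Amadori peaks (G x population x protons x class
# scale, C1-H1 attenuated by solvent exchange), then physical merging of
# near-degenerate peaks (< 0.5 sigma apart on both axes).
.predict_true_peaks <- function(config, library, coil) {
  aa <- strsplit(config$sequence, "")[[1]]
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
      n <- n - as.integer(anchor_counts[rc$residue])  # moved to anchor
      if (n == 0) next
    }
    rows[[length(rows) + 1]] <- data.frame(
      owner = rc$label, owner_type = "residue", form = NA_character_,
      label = rc$label, c13 = rc$c13, h1 = rc$h1,
      multiplicity = rc$multiplicity, protons = rc$protons_in_signal,
      volume = n * rc$protons_in_signal * .class_scale(rc$multiplicity, config),
      stringsAsFactors = FALSE)
  }

  g <- config$glycations_per_molecule
  if (g > 0) {
    vis <- library[library$hsqc_visible, ]
    for (i in seq_len(nrow(vis))) {
      cr <- vis[i, ]
      pop <- config$form_populations[cr$form]
      if (is.na(pop) || pop == 0) next
      v <- g * as.numeric(pop) * cr$protons_in_signal *
        .class_scale(cr$multiplicity, config)
      if (cr$exchange_affected) v <- v * config$h1_exchange_attenuation
      rows[[length(rows) + 1]] <- data.frame(
        owner = paste(cr$form, cr$label), owner_type = "amadori",
        form = cr$form, label = cr$label, c13 = cr$c13, h1 = cr$h1,
        multiplicity = cr$multiplicity, protons = cr$protons_in_signal,
        volume = v, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$decoy_peaks)) {
    dp <- config$decoy_peaks
    for (i in seq_len(nrow(dp))) {
      rows[[length(rows) + 1]] <- data.frame(
        owner = sprintf("decoy %d", i), owner_type = "decoy",
        form = NA_character_, label = sprintf("decoy %d", i),
        c13 = dp$c13[i], h1 = dp$h1[i],
        multiplicity = dp$multiplicity[i] %||% "CH",
        protons = 1L, volume = dp$volume[i], stringsAsFactors = FALSE)
    }
  }
  pk <- do.call(rbind, rows)
  pk$sign <- ifelse(pk$multiplicity == "CH2", -1, 1)

  # physical superposition: distinct owners closer than 0.5 sigma on both
  # axes add into one observable peak; record the merge
  n <- nrow(pk)
  cluster <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (abs(pk$c13[i] - pk$c13[j]) < 0.5 * config$sigma_c13 &&
        abs(pk$h1[i] - pk$h1[j]) < 0.5 * config$sigma_h1)
      cluster[cluster == cluster[j]] <- cluster[i]
  }
  merged <- lapply(unique(cluster), function(cl) {
    sub <- pk[cluster == cl, , drop = FALSE]
    if (nrow(sub) == 1) { sub$overlap <- FALSE; return(sub) }
    signed_v <- sum(sub$volume * sub$sign)
    w <- abs(sub$volume) / sum(abs(sub$volume))
    data.frame(owner = paste(sub$owner, collapse = " + "),
               owner_type = paste(sort(unique(sub$owner_type)), collapse = "+"),
               form = sub$form[which.max(sub$volume)],
               label = paste(sub$label, collapse = " + "),
               c13 = sum(w * sub$c13), h1 = sum(w * sub$h1),
               multiplicity = if (length(unique(sub$multiplicity)) == 1)
                 sub$multiplicity[1] else "mixed",
               protons = sum(sub$protons),
               volume = abs(signed_v), sign = sign(signed_v),
               overlap = TRUE, stringsAsFactors = FALSE)
  })
  pk <- do.call(rbind, merged)

  # crowding (peaks with a neighbor within 3 sigma on both axes) makes a
  # peak a poor target for isolated per-peak assertions and quantification
  n <- nrow(pk)
  crowded <- rep(FALSE, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (abs(pk$c13[i] - pk$c13[j]) < 3 * config$sigma_c13 &&
        abs(pk$h1[i] - pk$h1[j]) < 3 * config$sigma_h1)
      crowded[i] <- crowded[j] <- TRUE
  }
  pk$crowded <- crowded
  rownames(pk) <- NULL
  pk
}

#' Simulate a multiplicity-edited 1H-13C HSQC spectrum with known truth
#'
#' Renders the deterministic true peak table of `config` (random-coil
#' protein peaks plus Amadori-product peaks) as signed axis-aligned 2D
#' Gaussians on the configured ppm grid and adds white Gaussian noise. The
#' amplitude of each peak is `volume / (2 pi sigma_c13 sigma_h1)` so the
#' numeric integral of the noiseless spectrum reproduces the ground-truth
#' volumes. CH (and CH3) peaks are positive, CH2 peaks negative.
#'
#' @param config A [simulation_config()].
#' @param library Amadori fingerprint ([amadori_library()]).
#' @param coil Random-coil table ([random_coil_table()]).
#' @return List with `spectrum` (an `hsqc_spectrum`) and `ground_truth`
#'   (a `synthetic_ground_truth`: true peak table with `overlap`,
#'   `crowded` and `on_grid` flags, the true stoichiometry `g`, the seed,
#'   and the config).
#' @export
simulate_hsqc <- function(config, library = amadori_library(),
                          coil = random_coil_table()) {
  stopifnot(inherits(config, "simulation_config"))
  pk <- .predict_true_peaks(config, library, coil)
  gr <- config$grid
  c13_axis <- seq(gr$c13_min, gr$c13_max, by = gr$c13_step)
  h1_axis <- seq(gr$h1_min, gr$h1_max, by = gr$h1_step)
  intensity <- matrix(0, nrow = length(c13_axis), ncol = length(h1_axis))

  margin_c <- 6 * config$sigma_c13
  margin_h <- 6 * config$sigma_h1
  pk$on_grid <- pk$c13 >= gr$c13_min & pk$c13 <= gr$c13_max &
    pk$h1 >= gr$h1_min & pk$h1 <= gr$h1_max

  for (i in which(pk$on_grid)) {
    amp <- pk$sign[i] * pk$volume[i] /
      (2 * pi * config$sigma_c13 * config$sigma_h1)
    ci <- which(c13_axis >= pk$c13[i] - margin_c &
                  c13_axis <= pk$c13[i] + margin_c)
    hi <- which(h1_axis >= pk$h1[i] - margin_h &
                  h1_axis <= pk$h1[i] + margin_h)
    if (!length(ci) || !length(hi)) next
    gc <- exp(-0.5 * ((c13_axis[ci] - pk$c13[i]) / config$sigma_c13)^2)
    gh <- exp(-0.5 * ((h1_axis[hi] - pk$h1[i]) / config$sigma_h1)^2)
    intensity[ci, hi] <- intensity[ci, hi] + amp * outer(gc, gh)
  }

  if (config$noise_sigma > 0) {
    set.seed(config$seed)
    intensity <- intensity +
      rnorm(length(intensity), sd = config$noise_sigma)
  }

  spectrum <- gridded_spectrum(intensity, c13_axis, h1_axis,
                               multiplicity_edited = TRUE,
                               noise_sigma_estimate = config$noise_sigma)
  ground_truth <- structure(list(peaks = pk,
                                 g = config$glycations_per_molecule,
                                 seed = config$seed,
                                 config = config),
                            class = "synthetic_ground_truth")
  list(spectrum = spectrum, ground_truth = ground_truth)
}

#' Noiseless peak list from simulation ground truth
#'
#' Converts the generator's true peak table into a [peak_list()], so
#' detection and quantification can be exercised without the gridded
#' pick-and-fit path.
#'
#' @param ground_truth A `synthetic_ground_truth` from [simulate_hsqc()].
#' @return A [peak_list()] carrying signed volumes, multiplicity classes
#'   and true assignments; the `overlap` and `crowded` flags are kept as
#'   extra columns.
#' @export
truth_peaklist <- function(ground_truth) {
  stopifnot(inherits(ground_truth, "synthetic_ground_truth"))
  pk <- ground_truth$peaks
  peaks <- data.frame(
    c13 = pk$c13, h1 = pk$h1,
    volume = pk$volume, height = NA_real_, sign = pk$sign,
    multiplicity_class = ifelse(pk$multiplicity == "CH2", "CH2-like",
                                ifelse(pk$multiplicity %in% c("CH", "CH3"),
                                       "CH-like", NA_character_)),
    fit_quality = 0, assignment = pk$owner,
    overlap = pk$overlap, crowded = pk$crowded,
    stringsAsFactors = FALSE)
  peak_list(peaks, multiplicity_edited = TRUE,
            provenance = sprintf("synthetic seed %d", ground_truth$seed),
            value_type = "volume")
}

#' Write simulation ground truth as CSV
#'
#' @param ground_truth A `synthetic_ground_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write.csv(ground_truth$peaks, path, row.names = FALSE)
  invisible(path)
}
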