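test_that("reference selection mirrors the sequence-driven rules", {
  # one Ser-Pro motif and 23 arginines: the anchor is the CH reference,
  # the pooled Arg Cd-Hd the CH2 reference
  seqs <- paste0("ASPK", strrep("R", 23), "GQF")
  refs <- select_reference_signals(seqs)
  sp <- refs[refs$label == "Ser(-Pro) Ca-Ha", ]
  expect_equal(sp$n, 1)
  expect_identical(sp$multiplicity, "CH")
  arg <- refs[refs$label == "Arg Cd-Hd", ]
  expect_equal(arg$n, 23)
  expect_equal(arg$protons_in_signal, 2)
  expect_identical(arg$multiplicity, "CH2")

  # four phenylalanines
  refs_f <- select_reference_signals("FFFF")
  expect_equal(refs_f$n[refs_f$label == "Phe Ca-Ha"], 4)

  # poly-Ala: no CH2 candidate at all -> warned and disabled
  expect_warning(refs_a <- select_reference_signals("AAAA"), "disabled")
  expect_identical(attr(refs_a, "disabled_classes"), "CH2")
})

test_that("per-proton normalization divides by count and the CH2 factor", {
  expect_equal(normalized_volume(46, 23, 2), 1)
  expect_equal(normalized_volume(4, 4, 1), 1)
  expect_equal(normalized_volume(1, 1, 1), 1)
  expect_error(normalized_volume(0, 1, 1), "> 0")
  expect_error(normalized_volume(1, 1, 3), "1 or 2")
})

make_report <- function(volumes, lib = amadori_library()) {
  vis <- as.data.frame(lib[lib$hsqc_visible & lib$form == "beta-pyranose", ])
  vis <- vis[vis$label %in% names(volumes), ]
  pl <- peak_list(data.frame(
    c13 = vis$c13, h1 = vis$h1,
    volume = as.numeric(volumes[vis$label]),
    sign = ifelse(vis$multiplicity == "CH2", -1, 1)),
    multiplicity_edited = TRUE)
  match_amadori(pl, lib)
}

make_refs <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(label = r$label, residue = "X", c13 = 50,
               h1 = 3.0, multiplicity = r$multiplicity,
               protons_in_signal = r$p, n = r$n, isolation = 10,
               preferred = TRUE, volume = r$volume,
               stringsAsFactors = FALSE)))
  structure(df, class = c("reference_signals", "data.frame"),
            disabled_classes = character(0))
}

test_that("marker-over-reference ratios reproduce the worked stoichiometry", {
  rep <- make_report(c("C5-H5" = 8.0, "C4-H4" = 7.5,
                       "C6-H6" = 8.0, "C6-H6'" = 8.0))
  refs <- make_refs(list(label = "CHref", multiplicity = "CH", p = 1, n = 1,
                         volume = 1.0))
  expect_warning(q <- quantify_glycation(rep, refs), "no reference for class CH2")
  expect_equal(sort(q$per_marker$g), c(7.5, 8.0))
  expect_equal(q$g, 7.75)
})

test_that("resolved single-proton CH2 markers quantify fractional glycation", {
  rep <- make_report(c("C5-H5" = 0.33, "C6-H6" = 0.33, "C6-H6'" = 0.33))
  refs <- make_refs(list(label = "CH2ref", multiplicity = "CH2", p = 2, n = 1,
                         volume = 2.0))
  q <- quantify_glycation(rep, refs, only_c6 = TRUE)
  expect_equal(q$per_marker$g, c(0.33, 0.33))
  expect_equal(q$g, 0.33)
  expect_equal(q$percent_molecules, 33)
})

test_that("stoichiometry estimates are invariant under global volume scaling", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- runif(4, 0.5, 8)
    names(v) <- c("C5-H5", "C4-H4", "C6-H6", "C6-H6'")
    ref_v <- runif(1, 0.5, 3)
    mk <- function(scale) {
      rep <- make_report(v * scale)
      refs <- make_refs(
        list(label = "CHref", multiplicity = "CH", p = 1, n = 2,
             volume = ref_v * 2 * scale),
        list(label = "CH2ref", multiplicity = "CH2", p = 2, n = 3,
             volume = ref_v * 6 * scale))
      quantify_glycation(rep, refs)
    }
    q1 <- mk(1); q2 <- mk(runif(1, 10, 1000))
    expect_equal(q1$per_marker$g, q2$per_marker$g)
    expect_equal(q1$g, q2$g)
  }
})

test_that("CH markers never divide by CH2 references or vice versa", {
  for (seed in 1:10) {
    set.seed(seed)
    v <- runif(4, 0.5, 8)
    names(v) <- c("C5-H5", "C4-H4", "C6-H6", "C6-H6'")
    # deliberately very different per-proton reference volumes per class
    ch_norm <- runif(1, 0.5, 2)
    ch2_norm <- ch_norm * runif(1, 5, 20)
    rep <- make_report(v)
    refs <- make_refs(
      list(label = "CHref", multiplicity = "CH", p = 1, n = 3,
           volume = ch_norm * 3),
      list(label = "CH2ref", multiplicity = "CH2", p = 2, n = 2,
           volume = ch2_norm * 4))
    q <- quantify_glycation(rep, refs)
    expected <- ifelse(q$per_marker$class == "CH", v[q$per_marker$label] / ch_norm,
                       v[q$per_marker$label] / ch2_norm)
    expect_equal(q$per_marker$g, unname(expected))
  }
})

test_that("quantification refuses absent presence unless forced", {
  rep <- make_report(c("C5-H5" = 1.0))  # C6 markers missing -> no presence
  refs <- make_refs(list(label = "CHref", multiplicity = "CH", p = 1, n = 1,
                         volume = 1.0))
  expect_error(quantify_glycation(rep, refs), "presence")
  q <- quantify_glycation(rep, refs, force = TRUE)
  expect_equal(q$g, 1.0)
})

test_that("full pipeline recovers the true stoichiometry", {
  # noiseless: every G within 10%
  for (g_true in c(0.25, 0.5, 1, 2, 4, 8)) {
    cfg <- simulation_config(toy_sequence, glycations_per_molecule = g_true,
                             grid = small_grid)
    sim <- simulate_hsqc(cfg)
    rep <- detect_glycation(sim$spectrum)
    expect_true(attr(rep, "presence"))
    refs <- select_reference_signals(toy_sequence)
    refs <- measure_reference_volumes(refs, attr(rep, "peaklist"))
    q <- quantify_glycation(rep, refs, form_population = 0.70)
    expect_lt(abs(q$g - g_true) / g_true, 0.10)
  }

  # noisy at SNR >= 10 on the diagnostic markers: within 25% across seeds
  g_true <- 2
  amp_c6 <- g_true * 0.70 * 0.85 / (2 * pi * 0.05 * 0.005)  # weakest marker
  noise <- amp_c6 / 10
  errs <- vapply(1:20, function(seed) {
    cfg <- simulation_config(toy_sequence, glycations_per_molecule = g_true,
                             noise_sigma = noise, seed = seed,
                             grid = small_grid)
    sim <- simulate_hsqc(cfg)
    # noise spikes above threshold occasionally fail to fit; the summation
    # fallback warning is expected here
    rep <- suppressWarnings(detect_glycation(sim$spectrum))
    refs <- select_reference_signals(toy_sequence)
    refs <- measure_reference_volumes(refs, attr(rep, "peaklist"))
    q <- quantify_glycation(rep, refs, form_population = 0.70, force = TRUE)
    abs(q$g - g_true) / g_true
  }, numeric(1))
  expect_lt(max(errs), 0.25)
})

test_that("relative form abundances recover the equilibrium mixture", {
  cfg <- simulation_config("GAFK", glycations_per_molecule = 4)
  sim <- simulate_hsqc(cfg)
  rep <- detect_glycation(sim$spectrum)
  fr <- relative_form_abundances(rep)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["beta-pyranose"]), 0.70, tolerance = 0.01)
  expect_equal(unname(fr["beta-furanose"]), 0.13, tolerance = 0.01)
  expect_equal(unname(fr["alpha-pyranose"]), 0.04, tolerance = 0.01)

  # two forms with equal volumes split 50/50
  lib <- amadori_library()
  two <- as.data.frame(lib[lib$hsqc_visible & lib$label == "C5-H5" &
                             lib$form %in% c("beta-pyranose", "beta-furanose"), ])
  pl <- peak_list(data.frame(c13 = two$c13, h1 = two$h1, volume = 3, sign = 1),
                  multiplicity_edited = TRUE)
  fr2 <- relative_form_abundances(match_amadori(pl, lib))
  expect_equal(unname(fr2), c(0.5, 0.5))

  # single form matched: dominance only
  one <- two[two$form == "beta-pyranose", ]
  pl1 <- peak_list(data.frame(c13 = one$c13, h1 = one$h1, volume = 3, sign = 1),
                   multiplicity_edited = TRUE)
  expect_warning(fr1 <- relative_form_abundances(match_amadori(pl1, lib)),
                 "dominance")
  expect_equal(unname(fr1), 1)
})
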