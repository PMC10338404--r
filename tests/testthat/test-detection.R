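make_gauss_spectrum <- function(peaks, sigma_c = 0.05, sigma_h = 0.005,
                                noise = 0, seed = 1,
                                c13_axis = seq(60, 80, by = 0.05),
                                h1_axis = seq(3.4, 4.4, by = 0.005)) {
  I <- matrix(0, length(c13_axis), length(h1_axis))
  for (i in seq_len(nrow(peaks))) {
    gc <- exp(-0.5 * ((c13_axis - peaks$c13[i]) / sigma_c)^2)
    gh <- exp(-0.5 * ((h1_axis - peaks$h1[i]) / sigma_h)^2)
    I <- I + peaks$amp[i] * outer(gc, gh)
  }
  if (noise > 0) {
    set.seed(seed)
    I <- I + rnorm(length(I), sd = noise)
  }
  gridded_spectrum(I, c13_axis, h1_axis, multiplicity_edited = TRUE)
}

test_that("picking finds isolated apexes and resolves close pairs", {
  s <- make_gauss_spectrum(data.frame(c13 = 70, h1 = 3.9, amp = 10), noise = 1)
  pk <- pick_peaks(s, threshold_k = 5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$c13, 70, tolerance = 0.05)
  expect_equal(pk$h1, 3.9, tolerance = 0.005)
  expect_equal(pk$multiplicity_class, "CH-like")

  # two Gaussians 4 sigma apart on the 13C axis give two extrema
  s2 <- make_gauss_spectrum(data.frame(c13 = c(70, 70.2), h1 = c(3.9, 3.9),
                                       amp = c(10, 10)))
  pk2 <- pick_peaks(s2, noise_sigma = 1)
  expect_equal(nrow(pk2), 2)
})

test_that("pure noise at k = 5 yields essentially no false positives", {
  set.seed(123)
  ax_c <- seq(40, by = 0.05, length.out = 320)
  ax_h <- seq(3, by = 0.005, length.out = 320)
  s <- gridded_spectrum(matrix(rnorm(320 * 320), 320, 320), ax_c, ax_h)
  pk <- pick_peaks(s, threshold_k = 5, noise_sigma = 1)
  # ~1e5 interior points; the 5-sigma Gaussian tail bound predicts << 1
  expect_lte(nrow(pk), 1)
})

test_that("Gaussian fit recovers the closed-form volume", {
  s <- make_gauss_spectrum(data.frame(c13 = 70, h1 = 3.9, amp = 1))
  pk <- pick_peaks(s, noise_sigma = 0.01)
  fit <- fit_and_integrate(s, pk)
  v_exact <- 2 * pi * 1 * 0.05 * 0.005
  expect_equal(fit$volume, v_exact, tolerance = 0.01)
  expect_equal(fit$c13, 70, tolerance = 0.05)

  # with noise at SNR 20 the volume stays within 5%
  s_n <- make_gauss_spectrum(data.frame(c13 = 70, h1 = 3.9, amp = 20),
                             noise = 1, seed = 5)
  fit_n <- fit_and_integrate(s_n, pick_peaks(s_n, threshold_k = 5))
  expect_equal(fit_n$volume, 20 * v_exact, tolerance = 0.05)
})

test_that("overlapping peaks are fit jointly and conserve total volume", {
  v_single <- 2 * pi * 10 * 0.05 * 0.005

  # two identical peaks at the same position superimpose into one signal
  # of twice the volume
  s0 <- make_gauss_spectrum(data.frame(c13 = c(70, 70), h1 = c(3.9, 3.9),
                                       amp = c(10, 10)))
  fit0 <- fit_and_integrate(s0, pick_peaks(s0, noise_sigma = 0.01))
  expect_equal(sum(fit0$volume), 2 * v_single, tolerance = 0.02)

  # 3 sigma apart on 13C: apexes distinct but windows overlap -> joint fit
  s <- make_gauss_spectrum(data.frame(c13 = c(70, 70.15), h1 = c(3.9, 3.9),
                                      amp = c(10, 10)))
  pk <- pick_peaks(s, noise_sigma = 0.01)
  expect_equal(nrow(pk), 2)
  fit <- fit_and_integrate(s, pk)
  expect_equal(sum(fit$volume), 2 * v_single, tolerance = 0.02)
})

test_that("fingerprint matching follows the three-marker presence rule", {
  lib <- amadori_library()
  vis <- as.data.frame(lib[lib$hsqc_visible & lib$form == "beta-pyranose", ])
  exact <- peak_list(data.frame(c13 = vis$c13, h1 = vis$h1, volume = 1,
                                sign = ifelse(vis$multiplicity == "CH2", -1, 1)),
                     multiplicity_edited = TRUE)
  rep <- match_amadori(exact, lib)
  expect_true(attr(rep, "presence"))
  expect_equal(attr(rep, "diagnostic_hits"), 3)

  # empty peak list
  empty <- peak_list(data.frame(c13 = numeric(0), h1 = numeric(0)))
  rep0 <- match_amadori(empty, lib)
  expect_false(attr(rep0, "presence"))
  expect_equal(attr(rep0, "diagnostic_hits"), 0)

  # displacing both C6 entries by twice the tolerance kills the call even
  # though C5-H5 is present
  shifted <- vis
  shifted$c13[grepl("^C6", shifted$label)] <-
    shifted$c13[grepl("^C6", shifted$label)] + 0.8
  pl <- peak_list(data.frame(c13 = shifted$c13, h1 = shifted$h1, volume = 1,
                             sign = ifelse(shifted$multiplicity == "CH2", -1, 1)),
                  multiplicity_edited = TRUE)
  rep2 <- match_amadori(pl, lib)
  expect_false(attr(rep2, "presence"))
  d <- as.data.frame(rep2)
  expect_true(d$matched[d$label == "C5-H5" & d$form == "beta-pyranose"])

  # a wrong-sign peak at a diagnostic position is rejected
  flipped <- peak_list(data.frame(c13 = vis$c13, h1 = vis$h1, volume = 1,
                                  sign = 1),  # all positive incl. CH2 markers
                       multiplicity_edited = TRUE)
  rep3 <- match_amadori(flipped, lib)
  expect_false(attr(rep3, "presence"))
})

test_that("matched set shrinks monotonically as tolerances tighten", {
  lib <- amadori_library()
  vis <- as.data.frame(lib[lib$hsqc_visible, ])
  for (seed in 1:5) {
    set.seed(seed)
    pl <- peak_list(data.frame(
      c13 = vis$c13 + rnorm(nrow(vis), sd = 0.15),
      h1 = vis$h1 + rnorm(nrow(vis), sd = 0.015),
      volume = 1,
      sign = ifelse(vis$multiplicity == "CH2", -1, 1)),
      multiplicity_edited = TRUE)
    matched_at <- function(tol_scale) {
      r <- match_amadori(pl, lib, tol_c13 = 0.4 * tol_scale,
                         tol_h1 = 0.04 * tol_scale)
      paste(r$form, r$label)[r$matched]
    }
    sets <- lapply(c(0.5, 1, 2), matched_at)
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("matching is invariant under global intensity scaling", {
  cfg <- simulation_config(toy_sequence, glycations_per_molecule = 1,
                           grid = small_grid)
  sim <- simulate_hsqc(cfg)
  rep1 <- detect_glycation(sim$spectrum)
  scaled <- sim$spectrum
  scaled$intensity <- scaled$intensity * 1000
  rep2 <- detect_glycation(scaled)
  expect_identical(rep1$matched, rep2$matched)
  expect_identical(attr(rep1, "presence"), attr(rep2, "presence"))
})

test_that("greedy assignment equals exhaustive optimum on small instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n_lib <- sample(2:6, 1)
    lib <- tiny_library(c13 = runif(n_lib, 60, 75),
                        h1 = runif(n_lib, 3.4, 4.4))
    # one candidate near each entry plus decoys, so conflicts do occur
    near <- data.frame(c13 = lib$c13 + rnorm(n_lib, sd = 0.1),
                       h1 = lib$h1 + rnorm(n_lib, sd = 0.01))
    decoy <- data.frame(c13 = runif(2, 60, 75), h1 = runif(2, 3.4, 4.4))
    pl <- peak_list(rbind(near, decoy))
    rep <- match_amadori(pl, lib, tol_c13 = 0.4, tol_h1 = 0.04)
    oracle <- brute_force_match(pl, as.data.frame(lib), 0.4, 0.04)
    lib_order <- match(paste(rep$form, rep$label),
                       paste(lib$form, lib$label))
    greedy_pi <- ifelse(rep$matched,
                        match(paste(rep$c13_obs, rep$h1_obs),
                              paste(pl$c13, pl$h1)), NA_integer_)
    expect_identical(greedy_pi, oracle[lib_order])
  }
})

test_that("fitted marker positions reproduce library positions on synthetic spectra", {
  cfg <- simulation_config(toy_sequence, glycations_per_molecule = 1,
                           grid = small_grid)
  sim <- simulate_hsqc(cfg)
  rep <- detect_glycation(sim$spectrum)
  d <- as.data.frame(rep)
  d <- d[d$form == "beta-pyranose" & d$matched, ]
  expect_true(all(abs(d$d_c13) <= small_grid$c13_step))
  expect_true(all(abs(d$d_h1) <= small_grid$h1_step))
})

test_that("decoy peaks far from the diagnostics do not trigger presence", {
  decoys <- data.frame(c13 = c(70.2, 68.0, 65.3, 73.0),
                       h1 = c(4.01, 3.99, 3.76, 3.75),
                       volume = 5, sign = 1, multiplicity = "CH")
  cfg <- simulation_config(toy_sequence, glycations_per_molecule = 0,
                           decoy_peaks = decoys, grid = small_grid)
  sim <- simulate_hsqc(cfg)
  # every decoy is >= 1 ppm (13C) from every diagnostic marker
  lib <- amadori_library()
  diag <- diagnostic_correlations(lib)
  for (x in decoys$c13) expect_gte(min(abs(x - diag$c13)), 1)
  rep <- detect_glycation(sim$spectrum)
  expect_false(attr(rep, "presence"))

  # and an unglycated spectrum alone is negative too
  cfg0 <- simulation_config(toy_sequence, glycations_per_molecule = 0,
                            grid = small_grid)
  rep0 <- detect_glycation(simulate_hsqc(cfg0)$spectrum)
  expect_false(attr(rep0, "presence"))
})
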