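---
title: "Detecting and quantifying protein glycation from 2D HSQC spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying protein glycation from 2D HSQC spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amadoriNMR)
```

## The problem

Glycation is the spontaneous, non-enzymatic reaction of a reducing sugar
with a protein primary amine — mostly the Nε of lysine side chains —
followed by the Amadori rearrangement to a stable ketoamine adduct
(fructoselysine, for glucose). It is a critical quality attribute of
protein therapeutics and a marker of aging and metabolic disease. Mass
spectrometry detects the +162 Da mass shift but cannot distinguish
isobaric modifications; NMR can, because the Amadori product has a unique
chemical-shift fingerprint.

Under denaturing conditions (7 M urea in D2O) a protein's 1H-13C HSQC
collapses onto the random-coil cross-peaks of the 20 residue types, and
any covalent modification adds its own, well-separated correlations. The
cyclic Amadori product exists in an equilibrium of four ring forms; the
beta-pyranose dominates at about 70%, the two furanoses contribute about
13% each, the alpha-pyranose about 4%, and the open forms are below 1%.
The package's fingerprint library stores the experimentally observed
beta-pyranose correlations (C3-H3 72.4/3.75, C4-H4 72.1/3.89, C5-H5
71.8/4.00, C6-H6 66.7/3.99, C6-H6' 66.7/3.76, Lys Cε-Hε 50.9/3.06, all
ppm vs DSS). Three of them — C5-H5, C6-H6, C6-H6' — fall in spectral
regions free of protein and glycan signals and are therefore the
diagnostic markers: presence of glycation is called if and only if all
three are matched with the correct multiplicity sign.

## The detection model

Gridded spectra are processed in three steps.

1. **Peak picking**: local extrema of |I| on a 3×3 neighborhood above
   `k·sigma_noise` (default `k = 5`). The noise sigma comes from a
   truncated robust estimator: the median absolute intensity of points
   below the 90th percentile of |I|, divided by `qnorm(0.725)` — the
   exact consistency constant for that truncation under Gaussian noise
   (the usual 1.4826 MAD factor would be ~11% biased here).
2. **Lineshape integration**: each peak is fit as an axis-aligned 2D
   Gaussian plus a local constant baseline on a ±4-sigma window; windows
   that overlap on both axes are fit jointly as a Gaussian sum. The
   volume is the closed form `2π·A·σC·σH`. A non-convergent fit falls
   back to baseline-corrected window summation and is flagged.
3. **Fingerprint matching**: each library correlation takes the nearest
   peak inside a ±0.4 ppm (13C) / ±0.04 ppm (1H) tolerance box, greedily
   by the tolerance-normalized Euclidean distance, one peak per entry,
   with sign-inconsistent candidates rejected in multiplicity-edited
   spectra. The tolerance default spans the spread of the fingerprint
   across proteins (e.g. C4 72.0–72.6 ppm) with margin; no published
   tolerance exists, so it is an engineering choice exposed in the API.
   Ties break by distance, then peak order, making results reproducible.

Greedy matching can in principle differ from the globally optimal
assignment, but on fingerprint-like instances (distinct library entries,
at most one nearby candidate per entry plus decoys) it coincides with the
exhaustive optimum; the test suite checks this against a brute-force
enumerator on small random instances.

## The quantification model

HSQC intensity is only comparable within a multiplicity class: the
compromise INEPT delay makes CH, CH2 and CH3 responses differ, but within
a class integrals are nearly quantitative. The stoichiometry procedure is
therefore:

* pick protein **reference signals** with a known residue count — a
  pooled residue-type signal (Arg Cδ-Hδ, Gln/Glu Cγ-Hγ, Gly Cα-Hα, Phe
  Cα-Hα, …) or the single-residue Cα-Hα anchor of a Ser (56.6/4.71) or
  Thr (60.1/4.60) immediately preceding a proline;
* normalize to a **per-proton volume**: divide the reference integral by
  the residue count `n` and, for an unresolved CH2 giving one signal, by
  2 (a resolved H6/H6' pair instead counts one proton per line);
* divide each usable marker volume by the per-proton reference volume of
  the *same* class — CH with CH, CH2 with CH2, never across.

Each ratio estimates glycations per molecule; the aggregate is their
unweighted mean (published work reports ranges like "7–9" without
defining an aggregator; the mean is transparent, and per-marker values
are always reported so the range stays visible). C1-H1 is excluded by
default because its protons exchange with solvent deuterium in D2O, and
Lys Cε-Hε because its region is congested; both exclusions can be
overridden.

One design choice deserves emphasis: marker volumes are proportional to
the *population of the matched ring form*, about 0.70 for the
beta-pyranose. The conventional report quotes the ratio as measured
(`form_population = 1`), which is what published stoichiometries do;
passing `form_population = 0.70` converts beta-pyranose marker volumes
into total Amadori stoichiometry summed over all forms. The synthetic
round-trip tests use the latter, since the generator's ground truth is
total stoichiometry.

## The synthetic-data generator

`simulate_hsqc()` renders the model the analysis assumes: one cross-peak
per random-coil correlation of each residue type (volume proportional to
count × protons per signal), Ser/Thr preceding a proline moved to their
anchor positions, and Amadori peaks at the library positions with volume
proportional to `G × population × protons`, C1-H1 attenuated by a
deuterium-exchange factor (default 0.8). Lineshapes are axis-aligned 2D
Gaussians (matching the Gaussian-fit integration and giving a closed-form
volume oracle), signs follow multiplicity editing, and white Gaussian
noise is added; the single integer seed drives only the noise. Defaults:
sigmas 0.05 ppm (13C) / 0.005 ppm (1H), grid 13C 40–105 ppm at 0.05
ppm/pt × 1H 2.5–5.5 ppm at 0.005 ppm/pt (~1300 × 600 points, the region
of interest at desk scale; the repeated-simulation tests use a reduced
40–78 × 2.8–4.9 ppm window for speed). The relative CH2/CH response
under the compromise INEPT delay is not published, so `ch2_response`
(default 0.85) is an explicit free parameter; none of the within-class
arithmetic depends on its value. Peaks of distinct owners closer than
0.5 sigma on both axes are summed into one observable signal and flagged
as overlapped; peaks with a neighbor within 3 sigma are flagged crowded.

What the generator does **not** emulate: J-coupling multiplets, t1-noise
ridges, solvent streaks, glycan backgrounds (an explicit decoy-peak list
can be injected for specificity tests), chemical-shift dispersion within
a residue type, and differential relaxation. Passing round-trip tests
therefore demonstrates correctness of the pipeline's arithmetic and
matching logic under the stated model, not robustness to every artifact
of real spectra.

The minor-form positions shipped with the library are synthetic
placeholders (the published minor-form assignments are not printed in the
main text of the underlying literature); they are guaranteed at least
1 ppm (13C) away from the diagnostic markers, and presence calls never
rest on them. Only their populations are literature values. The
random-coil table beyond the two printed X-Pro anchors ships standard
literature values; CH3 correlations are omitted as they fall outside the
default window and cannot serve as references here.

## Detection limit

The limit of detection is taken as an empirical input: about 55 µmol/L
of modification for a 5 mm tube and typical overnight cryoprobe
measurements (27.5 nmol — displayed 28 — in 500 µL). The smallest
detectable modified fraction at protein concentration `c` is
`100 · min(1, LOD/c)` percent, e.g. 25% at 220 µmol/L and 6% (displayed,
from 6.1) at 0.9 mM. Display values round half-up; exact values are kept
in machine-readable output. The LOD concentration is a parameter, not a
constant: independent estimates (e.g. 66 µmol/L from a 10% limit at
660 µmol/L) can be plugged in, and the published 0.7%-at-3.85 mM figure
is mutually inconsistent with 55 µmol/L (it implies ~28 µmol/L), which
is why the model does not hard-code it.

## Worked example

```{r example}
seqs <- "MKSPAFGQETRKGFNAA"   # toy protein with one Ser-Pro anchor motif
cfg <- simulation_config(seqs, glycations_per_molecule = 2)
sim <- simulate_hsqc(cfg)
report <- detect_glycation(sim$spectrum)
attr(report, "presence")

refs <- select_reference_signals(seqs)
refs <- measure_reference_volumes(refs, attr(report, "peaklist"))
quantify_glycation(report, refs, form_population = 0.70)
```

The recovered stoichiometry equals the simulated two glycations per
molecule because the spectrum is noiseless; with noise at a marker
signal-to-noise ratio of 10 the estimate stays within 25% across seeds
(see the test suite).

## Numerical notes and limitations

* Positions and volumes of the generator are deterministic; only noise is
  seeded. Fits are initialized at the picked apex with the configured
  initial widths and optimized by Levenberg–Marquardt on log-sigma
  parameters (keeping widths positive); `maxiter = 200`.
* Degenerate inputs: an all-zero spectrum has noise 0 and yields an empty
  peak list; an empty peak list yields `presence = FALSE`; quantification
  refuses to run without a presence call unless forced, and errors when a
  needed multiplicity class has no measured reference.
* Form-abundance estimation restricts each form to the correlation labels
  matched in *every* form (same multiplicity and protons per signal)
  before averaging, so missing correlations do not bias the fractions.
* The pipeline does no absolute-concentration calibration, no correction
  for differential T1 or 1J(CH), no de novo assignment of unknown
  modifications, and no coverage of sugars other than glucose or of
  advanced glycation end products.
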