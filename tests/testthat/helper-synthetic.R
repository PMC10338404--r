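# Shared fixtures for the test suite. Everything is generated in code.

# toy sequence with one Ser-Pro anchor motif and the common reference types
toy_sequence <- "MKSPAFGQETRKGFNAA"

# reduced ppm window that still contains every beta-pyranose marker and the
# usable reference signals; keeps repeated noisy simulations fast
small_grid <- list(c13_min = 40, c13_max = 78, c13_step = 0.05,
                   h1_min = 2.8, h1_max = 4.9, h1_step = 0.005)

# numeric integral of a spectrum over a ppm box (Riemann sum oracle)
integrate_box <- function(spectrum, c13_range, h1_range) {
  ci <- spectrum$c13_axis >= c13_range[1] & spectrum$c13_axis <= c13_range[2]
  hi <- spectrum$h1_axis >= h1_range[1] & spectrum$h1_axis <= h1_range[2]
  dc <- diff(spectrum$c13_axis)[1]
  dh <- diff(spectrum$h1_axis)[1]
  sum(spectrum$intensity[ci, hi]) * dc * dh
}

# brute-force optimal fingerprint assignment: enumerates all one-to-one
# assignments of library entries to in-tolerance peaks and returns the one
# with maximum cardinality, then minimum total normalized distance
brute_force_match <- function(peaks, lib, tol_c13, tol_h1) {
  nl <- nrow(lib)
  cands <- lapply(seq_len(nl), function(li) {
    d_c <- peaks$c13 - lib$c13[li]
    d_h <- peaks$h1 - lib$h1[li]
    ok <- which(abs(d_c) <= tol_c13 & abs(d_h) <= tol_h1)
    list(pi = ok, dist = sqrt((d_c[ok] / tol_c13)^2 + (d_h[ok] / tol_h1)^2))
  })
  best <- list(card = -1, total = Inf, assign = rep(NA_integer_, nl))
  recurse <- function(li, used, assign, total, card) {
    if (li > nl) {
      if (card > best$card ||
          (card == best$card && total < best$total - 1e-12)) {
        best <<- list(card = card, total = total, assign = assign)
      }
      return(invisible())
    }
    recurse(li + 1, used, assign, total, card)  # leave li unmatched
    opts <- cands[[li]]
    for (k in seq_along(opts$pi)) {
      p <- opts$pi[k]
      if (!p %in% used) {
        assign2 <- assign; assign2[li] <- p
        recurse(li + 1, c(used, p), assign2, total + opts$dist[k], card + 1)
      }
    }
  }
  recurse(1, integer(0), rep(NA_integer_, nl), 0, 0)
  best$assign
}

# minimal shift-library data.frame for matcher unit tests
tiny_library <- function(c13, h1, multiplicity = rep("CH", length(c13)),
                         diagnostic = rep(FALSE, length(c13))) {
  new_shift_library(data.frame(
    form = "beta-pyranose",
    label = sprintf("X%d", seq_along(c13)),
    c13 = c13, h1 = h1, multiplicity = multiplicity,
    protons_in_signal = 1L, diagnostic = diagnostic,
    exchange_affected = FALSE, hsqc_visible = TRUE, population = 0.7,
    stringsAsFactors = FALSE))
}
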