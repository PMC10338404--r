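#' Construct a peak list
#'
#' A peak list is a data.frame of 2D cross-peaks with one row per peak and
#' columns `c13`, `h1` (ppm), `volume` (signed intensity units, or NA),
#' `height`, `sign` (+1, -1 or NA when unknown), `multiplicity_class`
#' ("CH-like", "CH2-like" or NA), `fit_quality` and `assignment`. Rows are
#' kept sorted by (c13, h1) so output is deterministic.
#'
#' @param peaks data.frame with at least `c13` and `h1`.
#' @param multiplicity_edited Was the spectrum multiplicity-edited (CH
#'   positive, CH2 negative)?
#' @param provenance Free-text origin (file path or generator seed).
#' @param value_type `"volume"` if `volume` holds integrals, `"height"` if
#'   only apex heights are available. Quantification refuses heights.
#' @return A `peak_list`.
#' @export
peak_list <- function(peaks, multiplicity_edited = FALSE,
                      provenance = "constructed", value_type = "volume") {
  if (!all(c("c13", "h1") %in% names(peaks)))
    stopf("peaks need 'c13' and 'h1' columns")
  n <- nrow(peaks)
  defaults <- list(volume = NA_real_, height = NA_real_, sign = NA_real_,
                   multiplicity_class = NA_character_,
                   fit_quality = NA_real_, assignment = NA_character_)
  for (col in names(defaults))
    if (is.null(peaks[[col]])) peaks[[col]] <- rep(defaults[[col]], n)
  if (!is.finite(sum(abs(peaks$c13))) || !is.finite(sum(abs(peaks$h1))))
    stopf("peak positions must be finite")
  if (multiplicity_edited) {
    known <- !is.na(peaks$sign) & !is.na(peaks$multiplicity_class)
    bad <- known & ((peaks$sign > 0 & peaks$multiplicity_class == "CH2-like") |
                    (peaks$sign < 0 & peaks$multiplicity_class == "CH-like"))
    if (any(bad))
      stopf("multiplicity-edited convention violated (CH positive, CH2 negative) for %d peak(s)",
            sum(bad))
  }
  ord <- order(peaks$c13, peaks$h1)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks,
            class = c("peak_list", "data.frame"),
            multiplicity_edited = multiplicity_edited,
            provenance = provenance,
            value_type = value_type)
}

#' Read a 2D peak list from disk
#'
#' Two dialects are supported. `"sparky"` parses the whitespace-separated
#' Sparky peak-list export `assignment w1 w2 [height-or-volume]`, with
#' w1 = 13C and w2 = 1H by default (heteronuclear convention); a
#' plausibility check rejects files whose w2 column leaves the 0-13 ppm
#' proton window, which catches silently transposed axes. `"csv"` reads a
#' comma-separated file with header columns `c13_ppm,h1_ppm,volume` and
#' optionally `sign`.
#'
#' @param path File to read.
#' @param dialect `"sparky"` or `"csv"`.
#' @param axis_order `"c13-h1"` (default) or `"h1-c13"` for Sparky files
#'   whose w1 is the proton dimension.
#' @param multiplicity_edited Stored on the returned list.
#' @param value_type Whether the intensity column holds volumes or heights.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, dialect = c("sparky", "csv"),
                          axis_order = c("c13-h1", "h1-c13"),
                          multiplicity_edited = FALSE,
                          value_type = "volume") {
  dialect <- match.arg(dialect)
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("c13_ppm", "h1_ppm", "volume") %in% names(df)))
      stopf("CSV peak list needs header columns c13_ppm,h1_ppm,volume")
    peaks <- data.frame(c13 = df$c13_ppm, h1 = df$h1_ppm, volume = df$volume)
    if (!is.null(df$sign)) peaks$sign <- df$sign
    peaks$sign <- peaks$sign %||% sign(peaks$volume)
    return(peak_list(peaks, multiplicity_edited = multiplicity_edited,
                     provenance = path, value_type = value_type))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*(Assignment|#)", lines)
  rows <- which(keep)
  if (length(rows) == 0)
    return(peak_list(data.frame(c13 = numeric(0), h1 = numeric(0)),
                     multiplicity_edited = multiplicity_edited,
                     provenance = path, value_type = value_type))
  parse_row <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3)
      stopf("line %d: expected 'assignment w1 w2 [value]', got '%s'", i, lines[i])
    w <- suppressWarnings(as.numeric(tok[2:3]))
    if (any(is.na(w)))
      stopf("line %d: non-numeric shift in '%s'", i, lines[i])
    val <- if (length(tok) >= 4) suppressWarnings(as.numeric(tok[4])) else NA_real_
    c(w1 = w[1], w2 = w[2], value = val)
  }
  m <- t(vapply(rows, parse_row, c(w1 = 0, w2 = 0, value = 0)))
  if (axis_order == "c13-h1") {
    c13 <- m[, "w1"]; h1 <- m[, "w2"]
  } else {
    c13 <- m[, "w2"]; h1 <- m[, "w1"]
  }
  if (any(h1 < 0 | h1 > 13))
    stopf(paste("proton shifts outside the 0-13 ppm window; the w1/w2 axis",
                "order is probably transposed - re-read with axis_order =",
                if (axis_order == "c13-h1") "'h1-c13'" else "'c13-h1'"))
  peaks <- data.frame(c13 = c13, h1 = h1, volume = m[, "value"],
                      sign = sign(m[, "value"]))
  peaks$sign[is.na(peaks$volume)] <- NA_real_
  peak_list(peaks, multiplicity_edited = multiplicity_edited,
            provenance = path, value_type = value_type)
}

#' Write a peak list as CSV
#'
#' Columns `c13_ppm,h1_ppm,volume,sign`; the inverse of the CSV dialect of
#' [read_peaklist()].
#'
#' @param peaklist A [peak_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaklist, path) {
  out <- data.frame(c13_ppm = peaklist$c13, h1_ppm = peaklist$h1,
                    volume = peaklist$volume, sign = peaklist$sign)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%s, %smultiplicity-edited)\n",
              nrow(x), attr(x, "value_type"),
              if (attr(x, "multiplicity_edited")) "" else "not "))
  print(as.data.frame(x), ...)
  invisible(x)
}
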