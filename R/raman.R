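# Raman microspectroscopy: baseline correction and cytochrome redox metrics.
#
# Single-cell Raman spectra carry bands for lipids (1440 cm^-1, C-C), proteins
# (1660 cm^-1, amide I) and reduced cytochromes (750 and 1126 cm^-1 under
# 532 nm excitation; a broad 1550-1580 cm^-1 heme band under 633 nm).
# Fluorescence background is removed by subtracting a natural cubic spline
# through manually placed off-peak knots; ratio metrics are then read from the
# corrected spectrum.

#' Construct a Raman spectrum object
#'
#' @param shifts Numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `shifts`, all finite.
#' @param laser_nm Excitation wavelength, one of 532 or 633.
#' @param cell_id Optional cell label.
#' @param cell_class Optional cell class, `"astrocyte"` or `"neuron"`.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shifts, intensities, laser_nm = 532,
                           cell_id = NA_character_, cell_class = NA_character_) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities))
    stop("shifts and intensities must have equal length")
  if (any(!is.finite(shifts)) || any(diff(shifts) <= 0))
    stop("shifts must be finite and strictly increasing")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  if (!laser_nm %in% c(532, 633))
    stop("laser_nm must be 532 or 633")
  structure(
    list(shifts = shifts, intensities = intensities, laser_nm = laser_nm,
         cell_id = cell_id, cell_class = cell_class),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1, %d nm excitation\n",
              length(x$shifts), min(x$shifts), max(x$shifts), x$laser_nm))
  invisible(x)
}

#' Baseline specification for spline background subtraction
#'
#' Knot x-positions are chosen once, off the informative peaks, and reused for
#' every spectrum of a study; knot heights are re-estimated per spectrum as the
#' mean intensity over a (2*halfwidth + 1)-point neighborhood of the grid point
#' nearest each knot.
#'
#' @param knot_positions Strictly increasing wavenumbers (cm^-1); at least 4
#'   are required for a cubic spline.
#' @param neighborhood_halfwidth Points on either side of the nearest grid
#'   index averaged into the knot height (default 2, a 5-point window).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(knot_positions,
                          neighborhood_halfwidth = 2L) {
  knot_positions <- as.numeric(knot_positions)
  if (length(knot_positions) < 4)
    stop("at least 4 knots are required for a cubic spline baseline")
  if (any(diff(knot_positions) <= 0))
    stop("knot_positions must be strictly increasing")
  if (neighborhood_halfwidth < 0)
    stop("neighborhood_halfwidth must be >= 0")
  structure(
    list(knot_positions = knot_positions,
         neighborhood_halfwidth = as.integer(neighborhood_halfwidth)),
    class = "baseline_spec"
  )
}

#' Default baseline knots
#'
#' Knots placed in quiet regions of the 600-1800 cm^-1 fingerprint range,
#' avoiding the 750, 1126, 1440, 1550-1580 and 1655-1665 cm^-1 bands.
#'
#' @return A `baseline_spec`.
#' @export
default_baseline <- function() {
  baseline_spec(c(610, 700, 810, 900, 990, 1070, 1180, 1290, 1380,
                  1510, 1620, 1720, 1790))
}

#' Subtract a cubic-spline baseline from a spectrum
#'
#' Knot heights are the mean intensity over the neighborhood of each knot's
#' nearest grid index; a natural cubic spline through (knot position, height)
#' is evaluated on the full grid and subtracted. Outside the outermost knots
#' the spline is extended linearly with the end slopes.
#'
#' @param spectrum A [raman_spectrum()].
#' @param baseline A [baseline_spec()]; default [default_baseline()].
#' @param method Spline type: `"natural"` (default; zero second derivative at
#'   the end knots) or `"fmm"` (end cubics fitted through the outer four
#'   knots, exact for polynomial backgrounds up to degree 3).
#' @return A `raman_spectrum` with corrected intensities.
#' @export
subtract_baseline <- function(spectrum, baseline = default_baseline(),
                              method = c("natural", "fmm")) {
  method <- match.arg(method)
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(baseline, "baseline_spec"))
  sh <- spectrum$shifts
  if (any(baseline$knot_positions < min(sh)) ||
      any(baseline$knot_positions > max(sh)))
    stop("baseline knot outside the spectral range")
  heights <- knot_heights(sh, spectrum$intensities,
                          baseline$knot_positions,
                          baseline$neighborhood_halfwidth)
  f <- stats::splinefun(baseline$knot_positions, heights, method = method)
  corrected <- spectrum$intensities - f(sh)
  out <- spectrum
  out$intensities <- corrected
  out
}

# Per-spectrum knot heights: mean over the (2h+1)-point window around the grid
# index nearest each knot position, truncated at the spectrum ends.
knot_heights <- function(shifts, intensities, knot_positions, halfwidth) {
  n <- length(shifts)
  vapply(knot_positions, function(x0) {
    i <- which.min(abs(shifts - x0))
    idx <- max(1L, i - halfwidth):min(n, i + halfwidth)
    mean(intensities[idx])
  }, numeric(1))
}

#' Peak intensity near a nominal band position
#'
#' Returns the maximum corrected intensity within `center +/- window`; the
#' window absorbs small calibration shifts of the band maximum.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param center Nominal peak position (cm^-1).
#' @param window Half-width of the search window (cm^-1), default 5.
#' @return Peak intensity (scalar).
#' @export
peak_intensity <- function(spectrum, center, window = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  sel <- spectrum$shifts >= center - window & spectrum$shifts <= center + window
  if (!any(sel))
    stop(sprintf("no grid points within %g cm^-1 of %g cm^-1", window, center))
  max(spectrum$intensities[sel])
}

#' Sum of intensities over a closed wavenumber band
#'
#' Sums corrected intensities at native grid points with
#' `lo <= shift <= hi`; no re-interpolation is performed.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param lo,hi Band limits (cm^-1), `lo < hi`.
#' @return Band intensity sum (scalar).
#' @export
band_intensity_sum <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (lo >= hi) stop("lo must be < hi")
  sel <- spectrum$shifts >= lo & spectrum$shifts <= hi
  if (!any(sel))
    stop(sprintf("no grid points in [%g, %g] cm^-1", lo, hi))
  sum(spectrum$intensities[sel])
}

# Read a named peak after baseline subtraction, warning on a negative value
# (negative corrected intensities are kept, not clipped).
.named_peak <- function(corrected, center, window) {
  v <- peak_intensity(corrected, center, window)
  if (v < 0)
    warning(sprintf("corrected intensity at %g cm^-1 peak is negative", center))
  v
}

# Light running-mean smoothing before the window-max peak read; the max of
# many noisy samples is biased upward, and a (2h+1)-point mean attenuates a
# Gaussian band of width >= 8 cm^-1 by well under 1%.
.smooth_spectrum <- function(spectrum, halfwidth) {
  if (halfwidth <= 0) return(spectrum)
  k <- 2L * halfwidth + 1L
  n <- length(spectrum$intensities)
  acc <- numeric(n)
  for (off in -halfwidth:halfwidth)
    acc <- acc + spectrum$intensities[pmin(pmax(seq_len(n) + off, 1L), n)]
  out <- spectrum
  out$intensities <- acc / k
  out
}

#' Redox and composition metrics from a 532 nm spectrum
#'
#' After baseline subtraction, reads peaks at 750 (reduced c-type cytochromes),
#' 1126 (reduced b-type cytochromes), 1440 (lipid C-C) and 1660 cm^-1 (protein
#' amide I) and forms:
#' * `protein_to_lipid` = I1660 / I1440,
#' * `red_cyt_cb_per_protein` = I750 / I1660,
#' * `c_to_b` = I750 / I1126.
#'
#' @param spectrum A [raman_spectrum()] with `laser_nm == 532`.
#' @param baseline A [baseline_spec()].
#' @param window Peak search half-width (cm^-1).
#' @param smooth_halfwidth Running-mean half-width (grid points) applied
#'   before the window-max peak read (default 1, a 3-point mean); 0 reads
#'   raw corrected intensities.
#' @return A list of class `redox_metrics_532` with the three ratios and the
#'   four peak intensities.
#' @export
metrics_532 <- function(spectrum, baseline = default_baseline(), window = 5,
                        smooth_halfwidth = 1) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (spectrum$laser_nm != 532)
    stop("metrics_532 requires a 532 nm spectrum")
  cor <- .smooth_spectrum(subtract_baseline(spectrum, baseline),
                          smooth_halfwidth)
  i750 <- .named_peak(cor, 750, window)
  i1126 <- .named_peak(cor, 1126, window)
  i1440 <- .named_peak(cor, 1440, window)
  i1660 <- .named_peak(cor, 1660, window)
  if (i1440 <= 0) stop("undefined ratio: 1440 cm^-1 (lipid) peak <= 0")
  if (i1660 <= 0) stop("undefined ratio: 1660 cm^-1 (protein) peak <= 0")
  if (i1126 <= 0) stop("undefined ratio: 1126 cm^-1 (cyt b) peak <= 0")
  structure(
    list(protein_to_lipid = i1660 / i1440,
         red_cyt_cb_per_protein = i750 / i1660,
         c_to_b = i750 / i1126,
         peaks = c(`750` = i750, `1126` = i1126,
                   `1440` = i1440, `1660` = i1660)),
    class = "redox_metrics_532"
  )
}

#' Reduced a-type cytochrome metric from a 633 nm spectrum
#'
#' After baseline subtraction, forms the ratio of the intensity sum over the
#' 1550-1580 cm^-1 heme band (reduced a-type cytochromes) to the sum over
#' 1655-1665 cm^-1 (protein amide I shoulder).
#'
#' @inheritParams metrics_532
#' @return A list of class `redox_metrics_633` with `red_cyt_a_ratio` and the
#'   two band sums.
#' @export
metrics_633 <- function(spectrum, baseline = default_baseline()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (spectrum$laser_nm != 633)
    stop("metrics_633 requires a 633 nm spectrum")
  cor <- subtract_baseline(spectrum, baseline)
  num <- band_intensity_sum(cor, 1550, 1580)
  den <- band_intensity_sum(cor, 1655, 1665)
  if (den <= 0) stop("undefined ratio: 1655-1665 cm^-1 band sum <= 0")
  structure(
    list(red_cyt_a_ratio = num / den,
         band_1550_1580 = num, band_1655_1665 = den),
    class = "redox_metrics_633"
  )
}

#' Read a two-column spectrum file
#'
#' Accepts CSV or whitespace/tab-separated files with columns
#' (shift in cm^-1, intensity); a non-numeric header line is skipped.
#'
#' @param path File path.
#' @param laser_nm,cell_id,cell_class Metadata passed to [raman_spectrum()].
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, laser_nm = 532,
                          cell_id = NA_character_, cell_class = NA_character_) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(toks[1:2]))))
  d <- utils::read.table(path, sep = sep, header = header,
                         comment.char = "#", strip.white = TRUE)
  raman_spectrum(d[[1]], d[[2]], laser_nm = laser_nm,
                 cell_id = cell_id, cell_class = cell_class)
}

#' Batch Raman metrics over a manifest
#'
#' The manifest names one spectrum file per cell with its metadata; metrics
#' appropriate for each cell's laser line are computed with a fixed knot set.
#'
#' @param manifest A data.frame (or CSV path) with columns `file`, `cell_id`,
#'   `cell_class`, `laser_nm` and optionally `group`.
#' @param baseline A [baseline_spec()] shared by all spectra.
#' @param dir Directory that `file` entries are relative to.
#' @return A data.frame with one row per cell and columns for every metric
#'   (NA where a metric does not apply to the laser line).
#' @export
raman_batch <- function(manifest, baseline = default_baseline(), dir = ".") {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    sp <- read_spectrum(file.path(dir, m$file), laser_nm = m$laser_nm,
                        cell_id = m$cell_id, cell_class = m$cell_class)
    out <- data.frame(cell_id = m$cell_id, cell_class = m$cell_class,
                      laser_nm = m$laser_nm,
                      group = if ("group" %in% names(m)) m$group else NA,
                      protein_to_lipid = NA_real_,
                      red_cyt_cb_per_protein = NA_real_,
                      c_to_b = NA_real_, red_cyt_a_ratio = NA_real_,
                      stringsAsFactors = FALSE)
    if (m$laser_nm == 532) {
      r <- metrics_532(sp, baseline)
      out$protein_to_lipid <- r$protein_to_lipid
      out$red_cyt_cb_per_protein <- r$red_cyt_cb_per_protein
      out$c_to_b <- r$c_to_b
    } else {
      r <- metrics_633(sp, baseline)
      out$red_cyt_a_ratio <- r$red_cyt_a_ratio
    }
    out
  })
  do.call(rbind, rows)
}
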