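# Corrected emission spectra: containers, file I/O, band integration, and the
# total-to-magnetic-dipole intensity ratio that feeds the radiative-lifetime
# calculation.

#' Construct an emission spectrum
#'
#' Container for a corrected emission spectrum sampled on a strictly
#' increasing wavelength grid. Intensities are in arbitrary units per nm, so
#' band integrals carry units of intensity x nm.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of non-negative intensities (a.u./nm),
#'   same length as `wavelengths`.
#' @param refractive_index Optional refractive index of the medium the
#'   spectrum was recorded in (dimensionless, >= 1). Stored for downstream
#'   radiative-lifetime calculations.
#' @param label Free-text sample label.
#'
#' @return An object of class `"emission_spectrum"`: a list with elements
#'   `wavelengths`, `intensities`, `refractive_index`, `label`.
#' @export
#' @examples
#' s <- emission_spectrum(c(592, 593, 594), c(0, 1, 0), label = "toy")
#' integrate_band(s, band_window("F1", 585, 603))
emission_spectrum <- function(wavelengths, intensities, refractive_index = NULL,
                              label = "") {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L) {
    stop("spectrum needs at least 2 points", call. = FALSE)
  }
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have the same length", call. = FALSE)
  }
  if (anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  bad <- which(intensities < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative intensity at row %d (wavelength %g nm)",
                 bad[1L], wavelengths[bad[1L]]), call. = FALSE)
  }
  if (!is.null(refractive_index)) {
    refractive_index <- as.numeric(refractive_index)
    if (length(refractive_index) != 1L || !is.finite(refractive_index) ||
        refractive_index <= 0) {
      stop("refractive_index must be a single positive number", call. = FALSE)
    }
  }
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         refractive_index = refractive_index, label = as.character(label)),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d points, %.1f-%.1f nm\n", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$refractive_index)) {
    cat(sprintf("  medium refractive index: %.4f\n", x$refractive_index))
  }
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses delimited text (comma or whitespace separated) with wavelength in
#' nm in column 1 and intensity in column 2. Lines starting with `#` are
#' comments. Rows are sorted by wavelength before validation.
#'
#' @param source Path to a file, a connection, or a character vector of lines.
#' @inheritParams emission_spectrum
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(source, refractive_index = NULL, label = "") {
  m <- read_two_column(source, what = "spectrum")
  ord <- order(m[, 1L])
  m <- m[ord, , drop = FALSE]
  emission_spectrum(m[, 1L], m[, 2L], refractive_index = refractive_index,
                    label = label)
}

# Shared two-column numeric text reader ('#' comments, comma or whitespace).
read_two_column <- function(source, what = "file") {
  lines <- if (is.character(source) && length(source) == 1L &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("source must be a file path, connection, or character vector",
         call. = FALSE)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop(sprintf("no data rows in %s input", what), call. = FALSE)
  }
  parts <- strsplit(gsub(",", " ", lines, fixed = TRUE), "[[:space:]]+")
  n_col <- lengths(parts)
  if (any(n_col < 2L)) {
    stop(sprintf("row %d of %s input has fewer than 2 columns",
                 which(n_col < 2L)[1L], what), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value at row %d of %s input", bad[1L], what),
         call. = FALSE)
  }
  cbind(x, y)
}

#' Define an integration window for a 5D0 -> 7FJ band
#'
#' @param transition One of `"F0"`, `"F1"`, `"F2"`, `"F3"`, `"F4"`, naming the
#'   terminal 7F_J level of the transition.
#' @param lo,hi Window edges in nm, `lo < hi`.
#' @return A `"band_window"` object.
#' @export
band_window <- function(transition, lo, hi) {
  transition <- match.arg(transition, c("F0", "F1", "F2", "F3", "F4"))
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("band window requires lo < hi", call. = FALSE)
  }
  structure(list(transition = transition, lo = lo, hi = hi),
            class = "band_window")
}

#' Default Eu(III) emission band windows
#'
#' Windows partitioning 574-720 nm around the five 5D0 -> 7F_J emission lines
#' of Eu(3+) (F0 ~579, F1 ~593, F2 ~614, F3 ~654, F4 ~701 nm). The F1 window
#' isolates the magnetic-dipole transition used as the internal intensity
#' standard. Override any window for instruments or matrices with shifted
#' Stark structure.
#'
#' @return A named list of [band_window()] objects.
#' @export
default_band_windows <- function() {
  list(
    F0 = band_window("F0", 574, 585),
    F1 = band_window("F1", 585, 603),
    F2 = band_window("F2", 603, 640),
    F3 = band_window("F3", 640, 672),
    F4 = band_window("F4", 672, 720)
  )
}

#' Integrate a spectrum over a band window
#'
#' Trapezoidal integral of intensity over `[lo, hi]` on the native grid, with
#' linear interpolation at window edges that fall between grid points (the
#' clipped trapezoid). Returns 0 when the window does not overlap the
#' spectrum support. No resampling is performed, so the rule is exact for
#' piecewise-linear spectra and band areas are additive over disjoint windows
#' sharing a grid.
#'
#' @param spectrum An [emission_spectrum()].
#' @param window A [band_window()].
#' @return Band area (intensity x nm).
#' @export
integrate_band <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(window, "band_window"))
  w <- spectrum$wavelengths
  y <- spectrum$intensities
  lo <- max(window$lo, w[1L])
  hi <- min(window$hi, w[length(w)])
  if (lo >= hi) return(0)
  inside <- w > lo & w < hi
  xs <- c(lo, w[inside], hi)
  ys <- c(stats::approx(w, y, xout = lo)$y,
          y[inside],
          stats::approx(w, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}

#' Integrate all emission bands and form the intensity ratio
#'
#' Computes per-transition band areas, the total integrated intensity
#' `I_tot` (sum over the supplied windows), and the magnetic-dipole intensity
#' `I_MD` (the F1 area). Their ratio `I_tot / I_MD` is the spectroscopic
#' input to the radiative-lifetime relation: because the 5D0 -> 7F1 magnetic
#' dipole transition has an environment-independent vacuum emission rate, it
#' calibrates the whole spectrum in absolute rate units.
#'
#' @inheritParams integrate_band
#' @param windows Named list of [band_window()] objects; must include `F1`.
#'   Windows must be pairwise disjoint. Defaults to [default_band_windows()].
#' @return A `"band_table"` object: list with `areas` (named numeric),
#'   `I_tot`, `I_MD`, and `ratio_tot_md`.
#' @export
band_areas <- function(spectrum, windows = default_band_windows()) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (inherits(windows, "band_window")) windows <- list(windows)
  trans <- vapply(windows, function(w) w$transition, "")
  names(windows) <- trans
  if (anyDuplicated(trans)) {
    stop("duplicate transition in window set", call. = FALSE)
  }
  if (!"F1" %in% trans) {
    stop("window set must include the F1 (magnetic dipole) window",
         call. = FALSE)
  }
  edges <- t(vapply(windows, function(w) c(w$lo, w$hi), numeric(2L)))
  ord <- order(edges[, 1L])
  if (any(edges[ord, 1L][-1L] < edges[ord, 2L][-nrow(edges)])) {
    stop("band windows must be pairwise disjoint", call. = FALSE)
  }
  areas <- vapply(windows, function(w) integrate_band(spectrum, w), 0)
  I_tot <- sum(areas)
  I_MD <- areas[["F1"]]
  if (I_MD <= 0) {
    stop("magnetic dipole (F1) band area is zero; I_tot/I_MD is undefined",
         call. = FALSE)
  }
  structure(
    list(areas = areas, I_tot = I_tot, I_MD = I_MD,
         ratio_tot_md = I_tot / I_MD),
    class = "band_table"
  )
}

#' @export
print.band_table <- function(x, ...) {
  cat("<band_table>\n")
  for (nm in names(x$areas)) {
    cat(sprintf("  %s: %.6g\n", nm, x$areas[[nm]]))
  }
  cat(sprintf("  I_tot = %.6g, I_MD = %.6g, I_tot/I_MD = %.4f\n",
              x$I_tot, x$I_MD, x$ratio_tot_md))
  invisible(x)
}

#' Convert diffuse reflectance to absorbed fraction
#'
#' For powder samples in an integrating sphere the fraction of excitation
#' light absorbed is `1 - R`, with `R` the measured reflectance.
#'
#' @param reflectance Reflectance fraction in `[0, 1]`.
#' @return Absorbed fraction `1 - reflectance`.
#' @export
absorption_from_reflectance <- function(reflectance) {
  reflectance <- as.numeric(reflectance)
  if (any(!is.finite(reflectance)) || any(reflectance < 0) ||
      any(reflectance > 1)) {
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  }
  1 - reflectance
}
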