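# Lateral-flow strip densitometry: lightness profiles along the
# chromatographic flow axis, test/control line detection, and the
# biotin-blocking titration endpoint ("signal permanence") analysis.

#' Construct a lateral-flow strip image
#'
#' @param pixels Numeric matrix of grayscale values in `[0, 1]`.
#' @param pixel_size Edge length of a pixel in mm.
#' @param flow_axis `"col"` (default) if columns index positions along the
#'   chromatographic flow direction (rows span the strip width), `"row"`
#'   otherwise.
#' @return A `"strip_image"` object.
#' @export
strip_image <- function(pixels, pixel_size, flow_axis = c("col", "row")) {
  flow_axis <- match.arg(flow_axis)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0) ||
      any(pixels > 1)) {
    stop("pixel values must be finite and in [0, 1]", call. = FALSE)
  }
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a positive number (mm/pixel)", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 flow_axis = flow_axis),
            class = "strip_image")
}

#' Read a strip image from a PNG or TIFF file
#'
#' 8/16-bit gray or RGB images are accepted; RGB is converted to grayscale
#' with the Rec. 601 luma weights (0.299 R + 0.587 G + 0.114 B). Requires the
#' `png` or `tiff` package for the respective format.
#'
#' @param path Path to a `.png` or `.tif(f)` file.
#' @inheritParams strip_image
#' @return A [strip_image()].
#' @export
read_strip_image <- function(path, pixel_size, flow_axis = c("col", "row")) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    arr <- if (nch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]
    }
  }
  strip_image(arr, pixel_size = pixel_size, flow_axis = flow_axis)
}

#' Construct a strip lightness profile
#'
#' @param positions Increasing positions along the flow direction, mm.
#' @param lightness Mean grayscale values in `[0, 1]`, same length.
#' @return A `"strip_profile"` object.
#' @export
strip_profile <- function(positions, lightness) {
  positions <- as.numeric(positions)
  lightness <- as.numeric(lightness)
  if (length(positions) != length(lightness) || length(positions) < 1L) {
    stop("positions and lightness must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (anyNA(lightness) || any(!is.finite(lightness)) || any(lightness < 0) ||
      any(lightness > 1)) {
    stop("lightness must be finite and in [0, 1]", call. = FALSE)
  }
  structure(list(positions = positions, lightness = lightness),
            class = "strip_profile")
}

#' Lightness profile along the flow axis
#'
#' Averages the image across the strip width at each position along the
#' chromatographic flow direction; positions are pixel centers in mm
#' (increasing from the sample pad toward the test line).
#'
#' @param image A [strip_image()].
#' @return A [strip_profile()].
#' @export
lightness_profile <- function(image) {
  stopifnot(inherits(image, "strip_image"))
  vals <- if (image$flow_axis == "col") {
    colMeans(image$pixels)
  } else {
    rowMeans(image$pixels)
  }
  positions <- (seq_along(vals) - 0.5) * image$pixel_size
  strip_profile(positions, vals)
}

#' Detect test/control lines in a lightness profile
#'
#' Subtracts a rolling-median baseline (robust to debris and drift), then
#' reports local maxima whose height exceeds `min_snr` times the robust
#' noise level (MAD of the baseline residual). Peak area is the trapezoidal
#' integral of the baseline-subtracted signal over the contiguous support
#' where it stays above 5% of the peak height.
#'
#' @param profile A [strip_profile()].
#' @param min_snr Minimum peak signal-to-noise ratio; default 3.
#' @param baseline_window_mm Width of the rolling-median baseline window in
#'   mm; should be several times the expected line width. Default 10.
#' @param min_width_px Minimum number of contiguous samples above the SNR
#'   threshold for a region to count as a line; default 3. Rejects
#'   single-sample noise excursions, which a pure SNR cut would pass.
#' @return A data.frame of class `"line_peaks"` with columns `position`
#'   (mm), `height` (lightness above local baseline), `area` (lightness x
#'   mm), `snr`; sorted by position. Zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_lines <- function(profile, min_snr = 3, baseline_window_mm = 10,
                         min_width_px = 3L) {
  stopifnot(inherits(profile, "strip_profile"))
  y <- profile$lightness
  x <- profile$positions
  n <- length(y)
  if (n < 5L) stop("profile too short for line detection", call. = FALSE)

  dx <- stats::median(diff(x))
  k <- max(3L, round(baseline_window_mm / dx))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  baseline <- stats::runmed(y, k, endrule = "median")
  resid <- y - baseline
  noise <- stats::mad(resid)
  if (noise == 0) noise <- .Machine$double.eps^0.5

  # one peak per contiguous region above the SNR threshold
  above <- resid > 0 & resid / noise >= min_snr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width_px
  peaks <- mapply(function(l0, r0) {
    i <- (l0:r0)[which.max(resid[l0:r0])]
    h <- resid[i]
    thr <- 0.05 * h
    l <- i; while (l > 1L && resid[l - 1L] > thr) l <- l - 1L
    r <- i; while (r < n && resid[r + 1L] > thr) r <- r + 1L
    area <- if (r > l) pracma::trapz(x[l:r], resid[l:r]) else 0
    data.frame(position = x[i], height = h, area = area, snr = h / noise)
  }, starts[keep], ends[keep], SIMPLIFY = FALSE)
  out <- if (length(peaks) > 0L) {
    do.call(rbind, peaks)
  } else {
    data.frame(position = numeric(0), height = numeric(0),
               area = numeric(0), snr = numeric(0))
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("line_peaks", "data.frame")
  out
}

#' Construct a biotin-blocking titration series
#'
#' Test-line signal as a function of the biotin dose pre-incubated with the
#' bead conjugate: free biotin blocks the (Neutr)avidin binding sites, so
#' the signal declines until all sites are occupied and then stays constant.
#'
#' @param doses Added biotin per bead (molecule counts), non-negative and
#'   increasing.
#' @param signals Test-line signal (lightness units), same length.
#' @param noise_floor Estimated per-point measurement noise (lightness
#'   units); deviations within this band are treated as "constant" when
#'   judging signal permanence.
#' @return A `"titration_series"` object.
#' @export
titration_series <- function(doses, signals, noise_floor = 0) {
  doses <- as.numeric(doses)
  signals <- as.numeric(signals)
  if (length(doses) != length(signals) || length(doses) < 2L) {
    stop("doses and signals must be equal-length (>= 2)", call. = FALSE)
  }
  if (any(doses < 0) || any(diff(doses) <= 0)) {
    stop("doses must be non-negative and increasing", call. = FALSE)
  }
  if (anyNA(signals) || any(!is.finite(signals))) {
    stop("signals must be finite", call. = FALSE)
  }
  noise_floor <- as.numeric(noise_floor)
  if (length(noise_floor) != 1L || !is.finite(noise_floor) ||
      noise_floor < 0) {
    stop("noise_floor must be a single non-negative number", call. = FALSE)
  }
  structure(list(doses = doses, signals = signals,
                 noise_floor = noise_floor),
            class = "titration_series")
}

#' Titration endpoint: the onset of signal permanence
#'
#' Fits a two-segment model -- a declining linear segment followed by a
#' constant plateau -- by least squares over all candidate split points (the
#' split point is shared by both segments) and returns the dose at the best
#' split: the smallest dose after which the signal is permanently constant.
#' The plateau must be genuine: every plateau point has to lie within
#' `max(noise_floor, tol)` of the plateau mean, otherwise the series has not
#' reached signal permanence and an error is raised.
#'
#' @param series A [titration_series()].
#' @param tol Absolute tolerance added under the plateau test for noiseless
#'   series; default `1e-9 * max(|signal|)`.
#' @return Endpoint dose (same units as `series$doses`).
#' @export
titration_endpoint <- function(series, tol = NULL) {
  stopifnot(inherits(series, "titration_series"))
  d <- series$doses
  s <- series$signals
  n <- length(d)
  if (n < 4L) stop("need at least 4 doses", call. = FALSE)
  if (is.null(tol)) tol <- 1e-9 * max(abs(s), 1)

  # candidate split j: decline on 1..j, plateau on j..n (>= 2 points each)
  cand <- 2L:(n - 1L)
  rss <- vapply(cand, function(j) {
    fit <- stats::lm.fit(cbind(1, d[1:j]), s[1:j])
    plateau <- mean(s[j:n])
    sum(fit$residuals^2) + sum((s[j:n] - plateau)^2)
  }, 0)
  j <- cand[which.min(rss)]

  plateau <- mean(s[j:n])
  band <- max(series$noise_floor, tol)
  if (any(abs(s[j:n] - plateau) > band)) {
    stop("no signal permanence: no terminal plateau within the noise floor",
         call. = FALSE)
  }
  slope <- stats::coef(stats::lm(s[1:j] ~ d[1:j]))[[2L]]
  if (is.finite(slope) && slope >= 0 && s[1L] <= plateau + band) {
    # nothing declined; a flat series has no blocking endpoint
    stop("no signal permanence: series shows no declining segment",
         call. = FALSE)
  }
  d[j]
}

#' Protein count from a titration series
#'
#' Divides the blocking endpoint dose by the number of biotin binding sites
#' per protein (4 for (Neutr)avidin) to obtain the number of surface
#' proteins per bead.
#'
#' @inheritParams titration_endpoint
#' @param sites_per_protein Biotin sites per protein; default 4.
#' @return Proteins per bead.
#' @export
titration_to_proteins <- function(series, sites_per_protein = 4L) {
  proteins_from_biotin_endpoint(titration_endpoint(series),
                                sites_per_protein)
}
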