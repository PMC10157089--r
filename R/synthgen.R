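# Seeded synthetic-data generators. Every generator returns its analytic
# ground truth alongside the sample, so parameter-recovery tests for the
# analysis modules need no instrument data.

# Run expr with a local RNG state: seeded if seed is given, untouched
# otherwise (callers manage their own RNG).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic Eu(III) line emission spectrum
#'
#' Sum of Gaussian bands at the 5D0 -> 7F_J line positions with prescribed
#' integrated areas, plus optional seeded Gaussian noise (clamped at zero so
#' intensities stay valid). The analytic band areas are returned as ground
#' truth; with the default centers and widths each band sits well inside its
#' [default_band_windows()] window, so pipeline-recovered areas match the
#' truth to better than 1e-4 relative on a 0.2 nm grid.
#'
#' @param areas Named numeric vector of band areas (intensity x nm) for
#'   `F0`..`F4`; `F1` must be positive. The default areas give
#'   `I_tot / I_MD` = 27.46, a typical value for a strongly hypersensitive
#'   Eu(III) beta-diketonate.
#' @param centers Band centers in nm (F0..F4); defaults 579, 593, 614, 654,
#'   701.
#' @param widths Gaussian sigma in nm, recycled across bands; default 2.
#' @param grid `c(start, stop, step)` in nm for the wavelength axis;
#'   default `c(570, 720, 0.2)`. Must cover every band center +/- 4 sigma.
#' @param noise_sd Additive Gaussian noise s.d. as a fraction of the peak
#'   intensity; default 0.
#' @param stark_shoulder If `TRUE`, 20% of the F2 area is moved into a
#'   second Gaussian component at 617.5 nm, mimicking the Stark shoulder
#'   seen for thienyl-substituted complexes.
#' @param seed Integer seed for the noise; `NULL` leaves the RNG alone.
#' @param label Sample label for the spectrum.
#' @return List with `spectrum` (an [emission_spectrum()]) and `truth` (a
#'   `"band_table"` holding the analytic areas and ratio).
#' @export
#' @examples
#' gs <- gen_emission_spectrum()
#' band_areas(gs$spectrum)$ratio_tot_md  # ~27.46
gen_emission_spectrum <- function(areas = c(F0 = 0.2, F1 = 1.0, F2 = 24.0,
                                            F3 = 0.5, F4 = 1.76),
                                  centers = c(F0 = 579, F1 = 593, F2 = 614,
                                              F3 = 654, F4 = 701),
                                  widths = 2,
                                  grid = c(570, 720, 0.2),
                                  noise_sd = 0,
                                  stark_shoulder = FALSE,
                                  seed = NULL,
                                  label = "synthetic Eu(III) emission") {
  trans <- names(areas)
  if (is.null(trans)) {
    stop("areas must be named by transition (F0..F4)", call. = FALSE)
  }
  if (!"F1" %in% trans || areas[["F1"]] <= 0) {
    stop("F1 (magnetic dipole) area must be positive", call. = FALSE)
  }
  if (any(areas < 0)) stop("band areas must be >= 0", call. = FALSE)
  centers <- centers[trans]
  if (anyNA(centers)) stop("missing band center for a listed area",
                           call. = FALSE)
  widths <- rep_len(widths, length(areas))
  if (grid[3L] <= 0) stop("grid step must be positive", call. = FALSE)
  if (any(centers - 4 * widths < grid[1L]) ||
      any(centers + 4 * widths > grid[2L])) {
    stop("grid must cover every band center +/- 4 sigma", call. = FALSE)
  }
  wl <- seq(grid[1L], grid[2L], by = grid[3L])
  comps <- mapply(function(a, c0, s) a * stats::dnorm(wl, c0, s),
                  areas, centers, widths)
  if (stark_shoulder && "F2" %in% trans) {
    i2 <- match("F2", trans)
    comps[, i2] <- 0.8 * areas[["F2"]] *
      stats::dnorm(wl, centers[["F2"]], widths[i2]) +
      0.2 * areas[["F2"]] * stats::dnorm(wl, 617.5, widths[i2])
  }
  intensity <- rowSums(comps)
  if (noise_sd > 0) {
    intensity <- with_local_seed(seed, {
      intensity + stats::rnorm(length(wl), 0, noise_sd * max(intensity))
    })
    intensity <- pmax(intensity, 0)
  }
  truth <- structure(
    list(areas = areas, I_tot = sum(areas), I_MD = areas[["F1"]],
         ratio_tot_md = sum(areas) / areas[["F1"]]),
    class = "band_table"
  )
  list(spectrum = emission_spectrum(wl, intensity, label = label),
       truth = truth)
}

#' Generate a mono-exponential decay trace
#'
#' Samples `A * exp(-t / tau) + b` on a regular time grid with optional
#' seeded noise: additive Gaussian (s.d. a fraction of the peak) or Poisson
#' counting noise. The signal is clamped at zero to keep the trace valid.
#'
#' @param tau Decay time, microseconds, > 0.
#' @param amplitude Amplitude `A` at t = 0; default 1000.
#' @param baseline Constant offset `b`; default 0.
#' @param noise_sd Gaussian noise s.d. as a fraction of the peak signal;
#'   default 0. Ignored when `poisson = TRUE`.
#' @param window `c(start, stop)` time window in microseconds.
#' @param step Sampling step in microseconds.
#' @param poisson If `TRUE`, draw each sample from a Poisson distribution
#'   with the model value as mean (signal interpreted as counts).
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#' @param label Trace label.
#' @return A [decay_trace()] with attribute `"truth"` (list of the
#'   generating parameters).
#' @export
gen_decay_trace <- function(tau, amplitude = 1000, baseline = 0,
                            noise_sd = 0, window = c(0, 3000), step = 5,
                            poisson = FALSE, seed = NULL,
                            label = "synthetic decay") {
  stopifnot(tau > 0, amplitude > 0, baseline >= 0, step > 0,
            window[2L] > window[1L])
  t <- seq(window[1L], window[2L], by = step)
  mu <- amplitude * exp(-t / tau) + baseline
  y <- with_local_seed(seed, {
    if (poisson) {
      stats::rpois(length(t), mu)
    } else if (noise_sd > 0) {
      mu + stats::rnorm(length(t), 0, noise_sd * max(mu))
    } else {
      mu
    }
  })
  tr <- decay_trace(t, pmax(y, 0), label = label)
  attr(tr, "truth") <- list(tau = tau, amplitude = amplitude,
                            baseline = baseline, noise_sd = noise_sd,
                            poisson = poisson)
  tr
}

#' Generate an inner-filter-limited dilution series
#'
#' Emission intensity of a dilution series under the primary inner-filter
#' model: `I(c) = scale * (1 - 10^(-A(c)))` with absorbance linear in
#' concentration, `A(c) = A_ref * c / c_ref` (`c_ref` is the first, most
#' concentrated point). At high absorbance the response saturates, so a
#' 10-fold dilution reduces the intensity by much less than 10; in the
#' dilute limit the step ratio approaches the dilution factor. The model is
#' deliberately minimal -- no angular scattering term -- and is meant for
#' qualitative step-ratio behavior only.
#'
#' @param absorbance_at_reference Absorbance at the first (reference)
#'   concentration; >= 0.
#' @param concentrations Positive, decreasing concentrations (weight
#'   fractions); default `c(0.1, 0.01, 0.001)` (percent by weight).
#' @param emission_scale Overall intensity scale; default 1.
#' @return A data.frame with columns `concentration`, `absorbance`,
#'   `intensity`, plus attribute `"step_ratios"`: the intensity ratio of
#'   each point to the next (length one less than the series).
#' @export
#' @examples
#' d <- gen_dilution_series(2.0)
#' attr(d, "step_ratios")  # ~ (2.7, 8.2): inner-filter-compressed, then ~10
gen_dilution_series <- function(absorbance_at_reference,
                                concentrations = c(0.1, 0.01, 0.001),
                                emission_scale = 1) {
  stopifnot(absorbance_at_reference >= 0, emission_scale >= 0)
  if (any(concentrations <= 0) || any(diff(concentrations) >= 0)) {
    stop("concentrations must be positive and decreasing", call. = FALSE)
  }
  A <- absorbance_at_reference * concentrations / concentrations[1L]
  I <- emission_scale * (1 - 10^(-A))
  out <- data.frame(concentration = concentrations, absorbance = A,
                    intensity = I)
  n <- length(I)
  attr(out, "step_ratios") <- if (n > 1L) I[-n] / I[-1L] else numeric(0)
  out
}

#' Generate a synthetic lateral-flow strip image
#'
#' Uniform background plus Gaussian line bands spanning the strip width,
#' optional circular debris blobs (mimicking agglomerated-bead residue along
#' the flow trace), and seeded pixel noise. Pixel values are clamped to
#' `[0, 1]`.
#'
#' @param length_mm,width_mm Strip dimensions; flow runs along the length.
#' @param pixel_size mm per pixel.
#' @param line_positions_mm Centers of the test/control lines along the
#'   flow axis.
#' @param line_heights Peak lightness of each line above background.
#' @param line_sigma_mm Gaussian sigma of the line band profile, mm.
#' @param background Background lightness; default 0.1.
#' @param debris_count Number of random debris blobs; default 0.
#' @param debris_height Peak lightness of a debris blob above background.
#' @param debris_radius_mm Radius (sigma) of a debris blob.
#' @param noise_sd Pixel noise s.d. (lightness units).
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#' @return List with `image` (a [strip_image()], `flow_axis = "col"`) and
#'   `truth` (line positions/heights, debris coordinates, and a
#'   `lines_overlap` flag set when two lines sit closer than 3 sigma).
#' @export
gen_strip_image <- function(length_mm = 40, width_mm = 5, pixel_size = 0.05,
                            line_positions_mm = c(20, 30),
                            line_heights = c(0.3, 0.2),
                            line_sigma_mm = 0.5,
                            background = 0.1,
                            debris_count = 0, debris_height = 0.2,
                            debris_radius_mm = 0.3,
                            noise_sd = 0, seed = NULL) {
  stopifnot(length_mm > 0, width_mm > 0, pixel_size > 0,
            length(line_positions_mm) == length(line_heights),
            background >= 0, background <= 1)
  if (length(line_positions_mm) > 0 &&
      (any(line_positions_mm <= 0) || any(line_positions_mm >= length_mm))) {
    stop("line positions must lie inside the strip length", call. = FALSE)
  }
  nx <- round(length_mm / pixel_size)   # flow axis -> columns
  ny <- round(width_mm / pixel_size)    # width axis -> rows
  xpos <- (seq_len(nx) - 0.5) * pixel_size
  ypos <- (seq_len(ny) - 0.5) * pixel_size

  line_profile <- rep(0, nx)
  for (i in seq_along(line_positions_mm)) {
    line_profile <- line_profile + line_heights[i] *
      exp(-(xpos - line_positions_mm[i])^2 / (2 * line_sigma_mm^2))
  }
  img <- matrix(background, nrow = ny, ncol = nx) +
    matrix(line_profile, nrow = ny, ncol = nx, byrow = TRUE)

  overlap <- FALSE
  if (length(line_positions_mm) > 1L) {
    gaps <- diff(sort(line_positions_mm))
    overlap <- any(gaps < 3 * line_sigma_mm)
    if (overlap) {
      warning("lines closer than 3 sigma; peaks may merge", call. = FALSE)
    }
  }

  debris <- data.frame(x_mm = numeric(0), y_mm = numeric(0))
  img <- with_local_seed(seed, {
    if (debris_count > 0) {
      dx <- stats::runif(debris_count, 0, length_mm)
      dy <- stats::runif(debris_count, 0, width_mm)
      debris <- data.frame(x_mm = dx, y_mm = dy)
      for (i in seq_len(debris_count)) {
        r2 <- outer((ypos - dy[i])^2, (xpos - dx[i])^2, `+`)
        img <- img + debris_height * exp(-r2 / (2 * debris_radius_mm^2))
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
    }
    img
  })
  img <- pmin(pmax(img, 0), 1)
  list(
    image = strip_image(img, pixel_size = pixel_size, flow_axis = "col"),
    truth = list(line_positions_mm = line_positions_mm,
                 line_heights = line_heights,
                 line_sigma_mm = line_sigma_mm,
                 background = background, debris = debris,
                 lines_overlap = overlap)
  )
}

#' Generate a biotin-blocking titration series
#'
#' Linear-blocking model for the test-line signal as free biotin saturates
#' the bead-bound protein: `signal(dose) = signal0 * max(0, 1 - dose /
#' (sites_per_protein * sites_per_bead)) + plateau`, plus seeded Gaussian
#' noise. The truth endpoint is the dose at which all binding sites are
#' blocked, `sites_per_protein * sites_per_bead`.
#'
#' @param sites_per_bead Protein molecules per bead; default 1000.
#' @param sites_per_protein Biotin binding sites per protein; default 4.
#' @param dose_grid Increasing biotin doses (molecules per bead) at which
#'   chromatographies are run; default `seq(0, 8000, by = 500)`.
#' @param signal0 Unblocked test-line signal; default 0.5 (lightness units).
#' @param plateau Residual signal at full blocking (background adhesion);
#'   default 0.02.
#' @param noise_sd Per-point noise s.d. as a fraction of `signal0`;
#'   default 0.
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#' @return List with `series` (a [titration_series()], `noise_floor` set to
#'   `3 * noise_sd * signal0`) and `truth` (list with `endpoint_dose` and
#'   the generating parameters).
#' @export
#' @examples
#' ts <- gen_titration_series(noise_sd = 0)
#' titration_endpoint(ts$series)  # 4000
gen_titration_series <- function(sites_per_bead = 1000,
                                 sites_per_protein = 4L,
                                 dose_grid = seq(0, 8000, by = 500),
                                 signal0 = 0.5, plateau = 0.02,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(sites_per_bead > 0, sites_per_protein >= 1,
            signal0 > 0, plateau >= 0, noise_sd >= 0)
  if (any(diff(dose_grid) <= 0)) {
    stop("dose_grid must be increasing", call. = FALSE)
  }
  endpoint <- sites_per_protein * sites_per_bead
  s <- signal0 * pmax(0, 1 - dose_grid / endpoint) + plateau
  if (noise_sd > 0) {
    s <- with_local_seed(seed, {
      s + stats::rnorm(length(s), 0, noise_sd * signal0)
    })
    s <- pmax(s, 0)
  }
  list(
    series = titration_series(dose_grid, s,
                              noise_floor = 3 * noise_sd * signal0),
    truth = list(endpoint_dose = endpoint, sites_per_bead = sites_per_bead,
                 sites_per_protein = sites_per_protein, signal0 = signal0,
                 plateau = plateau, noise_sd = noise_sd)
  )
}
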