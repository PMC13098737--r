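#' Instrument forward model for synthetic acquisitions
#'
#' Parameterizes the emulated spectrometer: a 1024-bin detector covering
#' 300--1800 cm^-1, accumulation averaging, CCD dark level and read noise,
#' a smooth spectral response curve, a small monotone wavenumber distortion
#' (the map from reported bin positions to true Raman shifts, expressed as a
#' cubic in the centred coordinate `(x - 1050)/750`), Poisson-like shot
#' noise, and optional cosmic-ray spikes (off by default).
#'
#' @param bins Number of detector bins (default 1024).
#' @param range Axis span in cm^-1 (default `c(300, 1800)`).
#' @param accumulations Accumulations averaged per measurement (default 10).
#' @param dark_level Mean dark counts per bin (default 100).
#' @param dark_noise_sd Read-noise SD in counts per accumulation (default 4).
#' @param response Function of wavenumber returning the strictly positive
#'   relative spectral response.
#' @param certified Function of wavenumber returning the certified emission
#'   curve of the intensity standard (strictly positive).
#' @param distortion_coef Length-4 numeric: cubic coefficients (in cm^-1) of
#'   the additive distortion in the centred coordinate; `c(0,0,0,0)` is a
#'   perfectly calibrated axis.
#' @param shot_scale Shot-noise variance per signal count (default 0.5).
#' @param spike_prob Per-bin, per-accumulation probability of a cosmic-ray
#'   spike (default 0).
#' @param spike_amplitude Spike amplitude in counts (default 2000).
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(bins = 1024L,
                             range = c(300, 1800),
                             accumulations = 10L,
                             dark_level = 100,
                             dark_noise_sd = 4,
                             response = function(x) 0.55 + exp(-((x - 1150) / 500)^2),
                             certified = function(x) 0.8 + 0.4 * (x - 300) / 1500,
                             distortion_coef = c(1.2, 0.8, -0.5, 0.3),
                             shot_scale = 0.5,
                             spike_prob = 0,
                             spike_amplitude = 2000) {
  stopifnot(bins >= 8L, range[2] > range[1], accumulations >= 1L,
            dark_level >= 0, dark_noise_sd >= 0, shot_scale >= 0,
            length(distortion_coef) == 4L)
  im <- structure(
    list(bins = as.integer(bins), range = as.numeric(range),
         accumulations = as.integer(accumulations),
         dark_level = dark_level, dark_noise_sd = dark_noise_sd,
         response = response, certified = certified,
         distortion_coef = as.numeric(distortion_coef),
         shot_scale = shot_scale, spike_prob = spike_prob,
         spike_amplitude = spike_amplitude),
    class = "instrument_model")
  ax <- instrument_axis(im)
  if (any(response(ax) <= 0)) stop("response curve must be strictly positive")
  tw <- distortion_map(im)(ax)
  if (any(diff(tw) <= 0)) {
    stop("wavenumber distortion must be monotone over the axis")
  }
  im
}

#' Reported wavenumber axis of an instrument
#' @param instrument An `instrument_model`.
#' @return Numeric vector of nominal bin positions in cm^-1.
#' @export
instrument_axis <- function(instrument) {
  seq(instrument$range[1], instrument$range[2],
      length.out = instrument$bins)
}

#' Wavenumber distortion map of an instrument
#'
#' Returns the function mapping reported (measured) bin positions to true
#' Raman shifts: `true = x + c0 + c1*u + c2*u^2 + c3*u^3` with
#' `u = (x - 1050)/750`. This is the map the x-axis calibration step must
#' recover from the reference-compound measurement.
#'
#' @param instrument An `instrument_model`.
#' @return Function of numeric wavenumber.
#' @export
distortion_map <- function(instrument) {
  co <- instrument$distortion_coef
  function(x) {
    u <- (x - 1050) / 750
    x + co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
  }
}

# numeric inverse of the distortion map (true -> measured), Newton iteration
distortion_inverse <- function(instrument, true_pos) {
  f <- distortion_map(instrument)
  x <- true_pos
  for (i in 1:50) {
    fx <- f(x)
    if (max(abs(fx - true_pos)) < 1e-12) break
    eps <- 1e-4
    deriv <- (f(x + eps) - f(x - eps)) / (2 * eps)
    x <- x - (fx - true_pos) / deriv
  }
  x
}

# positions of shared nuisance bands (not class-discriminative); together
# with the 17 catalogue bands every class carries 24 detectable peaks
NUISANCE_POSITIONS <- c(720, 880, 965, 1155, 1365, 1490, 1680)

# per-band nominal mean heights (counts, before instrument response) and
# full widths at half maximum (cm^-1) for the 17 catalogue bands
catalogue_band_shapes <- function() {
  data.frame(
    position = band_catalogue()$position,
    base_height = c(70, 55, 75, 60, 140, 90, 65, 60, 55, 85, 95, 90, 120,
                    60, 110, 110, 110),
    fwhm = c(12, 11, 10, 12, 9, 11, 13, 12, 14, 13, 14, 13, 16, 12, 5, 5,
             15))
}

nuisance_band_shapes <- function() {
  data.frame(
    position = NUISANCE_POSITIONS,
    base_height = c(45, 50, 40, 45, 50, 40, 55),
    fwhm = c(13, 14, 12, 15, 14, 16, 12))
}

#' Default class profiles for the three cell populations
#'
#' Builds band tables for normal neurons, FCD IIa dysmorphic neurons and FCD
#' IIb dysmorphic/balloon cells. Each profile carries the 17 catalogue bands
#' plus 7 shared nuisance bands (24 peaks per spectrum). Between-class mean
#' height differences at each discriminative band equal
#' `effect_scale x within-class height SD` (the SD implied by the log-normal
#' height jitter, `height_cv x base height`), applied symmetrically about the
#' shared base height and with the observed contrast directions: FCD II above
#' normal at 758, 827, 852, 933, 1263, 1337, 1554, 1602 and 1657 cm^-1,
#' below normal at 1002, 1031, 1302 and 1447 cm^-1; IIb above IIa at 852,
#' 1031, 1101, 1124, 1201, 1263, 1302, 1447, 1554 and 1593 cm^-1 and below
#' at 1002 cm^-1.
#'
#' @param effect_scale Nonnegative multiplier of the within-class height SD;
#'   0 gives identical class mean profiles (null model).
#' @param height_cv Within-class coefficient of variation of band heights
#'   (log-normal jitter; default 0.15).
#' @param baseline_amplitude Mean autofluorescence baseline amplitude in
#'   counts; the default is 10x the mean band height so baseline removal is
#'   genuinely exercised.
#' @param baseline_tau Exponential decay scale of the baseline in cm^-1
#'   (default 600).
#' @return Named list of three `class_profile` objects
#'   (`normal`, `FCD_IIa`, `FCD_IIb`).
#' @export
default_profiles <- function(effect_scale = 3,
                             height_cv = 0.15,
                             baseline_amplitude = NULL,
                             baseline_tau = 600) {
  if (effect_scale < 0) stop("effect_scale must be nonnegative")
  shapes <- rbind(catalogue_band_shapes(), nuisance_band_shapes())
  shapes <- shapes[order(shapes$position), ]
  rownames(shapes) <- NULL
  if (is.null(baseline_amplitude)) {
    baseline_amplitude <- 10 * mean(shapes$base_height)
  }
  d1 <- contrast_fcd_vs_normal()   # +1 FCD higher, -1 normal higher
  d2 <- contrast_iib_vs_iia()      # +1 IIb higher, -1 IIa higher
  key <- as.character(shapes$position)
  dir1 <- ifelse(key %in% names(d1), d1[key], 0)
  dir2 <- ifelse(key %in% names(d2), d2[key], 0)
  delta <- effect_scale * height_cv * shapes$base_height
  h_normal <- shapes$base_height - dir1 * delta / 2
  h_fcd <- shapes$base_height + dir1 * delta / 2
  h_iia <- pmax(h_fcd - dir2 * delta / 2, 0.05 * shapes$base_height)
  h_iib <- pmax(h_fcd + dir2 * delta / 2, 0.05 * shapes$base_height)
  h_normal <- pmax(h_normal, 0.05 * shapes$base_height)
  mk <- function(diagnosis, h) {
    structure(
      list(diagnosis = diagnosis,
           bands = data.frame(position = shapes$position, mean_height = h,
                              height_cv = height_cv, fwhm = shapes$fwhm),
           baseline_amplitude = baseline_amplitude,
           baseline_tau = baseline_tau,
           baseline_cv = 0.3,
           patient_sd = 0.05),
      class = "class_profile")
  }
  list(normal = mk("normal", h_normal),
       FCD_IIa = mk("FCD_IIa", h_iia),
       FCD_IIb = mk("FCD_IIb", h_iib))
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile '%s'> %d bands, baseline A=%.0f tau=%.0f\n",
              x$diagnosis, nrow(x$bands), x$baseline_amplitude,
              x$baseline_tau))
  invisible(x)
}

# sum of Gaussian bands, FWHM parameterization
gaussian_band_sum <- function(x, position, height, fwhm) {
  y <- numeric(length(x))
  for (i in seq_along(position)) {
    y <- y + height[i] * exp(-4 * log(2) * (x - position[i])^2 / fwhm[i]^2)
  }
  y
}

# forward model for one measurement using the *current* RNG stream
simulate_spectrum_impl <- function(profile, instrument, spectrum_id = "s1",
                                  height_multiplier = 1) {
  x <- instrument_axis(instrument)
  true_w <- distortion_map(instrument)(x)
  b <- profile$bands
  cv <- b$height_cv
  sigma <- sqrt(log(1 + cv^2))
  jitter <- exp(stats::rnorm(nrow(b), -sigma^2 / 2, sigma))
  heights <- b$mean_height * jitter * height_multiplier
  clean <- gaussian_band_sum(true_w, b$position, heights, b$fwhm)
  amp <- profile$baseline_amplitude
  if (amp > 0 && profile$baseline_cv > 0) {
    bs <- sqrt(log(1 + profile$baseline_cv^2))
    amp <- amp * exp(stats::rnorm(1L, -bs^2 / 2, bs))
  }
  baseline <- amp * exp(-(true_w - instrument$range[1]) / profile$baseline_tau)
  signal <- clean * instrument$response(true_w) + baseline
  expected <- signal + instrument$dark_level
  n <- length(x)
  noise_sd <- sqrt(instrument$dark_noise_sd^2 +
                     instrument$shot_scale * pmax(signal, 0))
  acc <- vector("list", instrument$accumulations)
  for (a in seq_len(instrument$accumulations)) {
    y <- expected + stats::rnorm(n, 0, noise_sd)
    if (instrument$spike_prob > 0) {
      hit <- stats::runif(n) < instrument$spike_prob
      y[hit] <- y[hit] + instrument$spike_amplitude * stats::runif(sum(hit))
    }
    acc[[a]] <- raman_spectrum(sprintf("%s_acc%02d", spectrum_id, a),
                               x, pmax(y, 0), stage = "raw")
  }
  avg <- Reduce(`+`, lapply(acc, `[[`, "intensity")) / length(acc)
  list(accumulations = acc,
       averaged = raman_spectrum(spectrum_id, x, avg, stage = "averaged"))
}

#' Simulate one single-cell acquisition
#'
#' Forward model of a measurement: the clean signal is a sum of Gaussian
#' bands `h * exp(-4 ln2 (x - mu)^2 / w^2)` with per-spectrum log-normal
#' height jitter, multiplied by the instrument response, plus an
#' autofluorescence baseline `A * exp(-(x - 300)/tau)` and the CCD dark
#' level; Gaussian noise with variance `dark_sd^2 + shot_scale * signal` is
#' drawn independently per accumulation, and the accumulations are averaged.
#' Reproducible under a fixed seed.
#'
#' @param profile A `class_profile`.
#' @param instrument An `instrument_model`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream
#'   (useful for Monte-Carlo replication).
#' @param spectrum_id Identifier for the emitted spectra.
#' @return List with `accumulations` (list of raw `raman_spectrum`) and
#'   `averaged` (stage "averaged").
#' @export
simulate_spectrum <- function(profile, instrument, seed = NULL,
                              spectrum_id = "s1") {
  if (instrument$accumulations < 1L) stop("need at least one accumulation")
  if (!is.null(seed)) {
    if (length(seed) != 1L || !is.finite(seed) || seed != as.integer(seed)) {
      stop("seed must be a single integer")
    }
    set.seed(as.integer(seed))
  }
  simulate_spectrum_impl(profile, instrument, spectrum_id)
}

# deterministic near-even allocation of n items to k groups
allocate_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  rep(seq_len(k), times = base + (seq_len(k) <= extra))[seq_len(n)]
}

#' Simulate a full study dataset with calibration references
#'
#' Emits the requested numbers of averaged single-cell spectra per class with
#' a patient/specimen hierarchy (spectra nested in specimens nested in
#' patients; a patient-level log-normal offset on band heights induces
#' within-patient correlation), plus matching dark, intensity-standard and
#' wavenumber-reference measurements distorted by the same instrument model.
#'
#' @param profiles Named list of `class_profile` as from [default_profiles()].
#' @param instrument An `instrument_model`.
#' @param counts Named integer vector of spectra per class, e.g.
#'   `c(normal = 700, FCD_IIa = 396, FCD_IIb = 374)`.
#' @param patients_per_class Integer vector (recycled like `counts`) of
#'   patients per class; the default `c(18, 9, 8)` is capped at the
#'   per-class spectrum count.
#' @param specimens_per_class Specimens per class; default `c(35, 18, 17)`,
#'   likewise capped.
#' @param seed Integer seed.
#' @param ref_peaks True (known) positions of the wavenumber-reference
#'   compound bands in cm^-1.
#' @return A [raman_dataset()] whose `refs` element holds the
#'   [calibration_refs()].
#' @export
simulate_dataset <- function(profiles, instrument,
                             counts = c(normal = 700, FCD_IIa = 396,
                                        FCD_IIb = 374),
                             patients_per_class = NULL,
                             specimens_per_class = NULL,
                             seed = 1,
                             ref_peaks = c(390.9, 465.1, 651.6, 797.2,
                                           857.9, 968.7, 1168.5, 1236.8,
                                           1323.9, 1561.6, 1648.4)) {
  stopifnot(length(counts) >= 1L, all(counts >= 1L))
  classes <- names(counts)
  if (is.null(classes) || !all(classes %in% names(profiles))) {
    stop("counts must be named by classes present in profiles")
  }
  default_pats <- is.null(patients_per_class)
  if (default_pats) patients_per_class <- c(18, 9, 8)
  default_specs <- is.null(specimens_per_class)
  if (default_specs) specimens_per_class <- c(35, 18, 17)
  patients_per_class <- rep_len(patients_per_class, length(counts))
  specimens_per_class <- rep_len(specimens_per_class, length(counts))
  if (default_pats) patients_per_class <- pmin(patients_per_class, counts)
  if (default_specs) specimens_per_class <- pmin(specimens_per_class, counts)
  if (any(patients_per_class > counts)) {
    stop("patients_per_class cannot exceed the per-class spectrum count")
  }
  set.seed(as.integer(seed))
  spectra <- list()
  meta <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    prof <- profiles[[cls]]
    n <- counts[[ci]]
    n_pat <- patients_per_class[ci]
    n_spec <- max(specimens_per_class[ci], n_pat)
    spec_of_spectrum <- allocate_counts(n, n_spec)
    pat_of_specimen <- allocate_counts(n_spec, n_pat)
    sd_p <- prof$patient_sd
    sg <- sqrt(log(1 + sd_p^2))
    pat_mult <- matrix(exp(stats::rnorm(n_pat * nrow(prof$bands),
                                        -sg^2 / 2, sg)),
                       nrow = n_pat)
    cell_type <- switch(cls,
                        normal = "normal_neuron",
                        FCD_IIa = "dysmorphic_neuron",
                        FCD_IIb = sample(c("dysmorphic_neuron",
                                           "balloon_cell"), n,
                                         replace = TRUE))
    cell_type <- rep_len(cell_type, n)
    for (i in seq_len(n)) {
      sp_id <- sprintf("%s_%04d", cls, i)
      spec_i <- spec_of_spectrum[i]
      pat_i <- pat_of_specimen[spec_i]
      sim <- simulate_spectrum_impl(prof, instrument, sp_id,
                                    height_multiplier = pat_mult[pat_i, ])
      spectra[[sp_id]] <- sim$averaged
      meta[[sp_id]] <- data.frame(
        spectrum_id = sp_id,
        patient_id = sprintf("%s_P%02d", cls, pat_i),
        specimen_id = sprintf("%s_S%02d", cls, spec_i),
        cell_type = cell_type[i],
        diagnosis = cls)
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL

  x <- instrument_axis(instrument)
  acc <- instrument$accumulations
  dark <- raman_spectrum(
    "dark", x,
    pmax(instrument$dark_level +
           stats::rnorm(length(x), 0, instrument$dark_noise_sd / sqrt(acc)),
         0),
    stage = "averaged")
  true_w <- distortion_map(instrument)(x)
  resp_clean <- instrument$certified(x) * instrument$response(true_w) * 1000
  resp_meas <- raman_spectrum(
    "response_standard", x,
    pmax(resp_clean + stats::rnorm(length(x), 0, 2 / sqrt(acc)), 0),
    stage = "averaged")
  keep <- ref_peaks >= min(true_w) & ref_peaks <= max(true_w)
  known <- ref_peaks[keep]
  measured <- distortion_inverse(instrument, known)
  refs <- calibration_refs(
    dark = dark, response_measured = resp_meas,
    response_certified = instrument$certified(x),
    wavenumber_ref_peaks = data.frame(known = known, measured = measured))
  raman_dataset(spectra, meta, refs = refs)
}

#' Write a simulated dataset (spectra, metadata, references, provenance)
#'
#' @param ds A `raman_dataset` with `refs`.
#' @param dir Output directory.
#' @param params Optional list of generator parameters recorded in
#'   `provenance.json`.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(ds, file.path(dir, "spectra.csv"),
                file.path(dir, "meta.csv"))
  if (!is.null(ds$refs)) write_calibration_refs(ds$refs, file.path(dir, "refs"))
  prov <- list(package = "ramanfcd",
               version = as.character(utils::packageVersion("ramanfcd")),
               n_spectra = length(ds$spectra),
               params = params)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
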