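#' Preprocessing configuration
#'
#' Parameters of the seven-step preprocessing chain. Defaults follow the
#' acquisition protocol: Savitzky-Golay order 3 / window 11, truncation to
#' 700--1700 cm^-1, cubic wavenumber calibration resampling to a uniform
#' 1.1 cm^-1 grid, and a 120 cm^-1 rolling-ball radius (much larger than any
#' band FWHM, much smaller than the autofluorescence scale).
#'
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param sg_window Savitzky-Golay window length, odd and > `sg_order`
#'   (default 11).
#' @param ball_radius Rolling-ball radius in cm^-1 (default 120).
#' @param trunc_range Closed truncation interval in cm^-1
#'   (default `c(700, 1700)`).
#' @param calib_degree Wavenumber-calibration polynomial degree (default 3).
#' @param resample_spacing Uniform grid spacing after calibration in cm^-1
#'   (default 1.1); the grid is anchored at 700 cm^-1 so the closed
#'   truncation interval retains 910 bins.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_order = 3L, sg_window = 11L,
                              ball_radius = 120, trunc_range = c(700, 1700),
                              calib_degree = 3L, resample_spacing = 1.1) {
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  if (ball_radius <= 0) stop("ball_radius must be positive")
  if (trunc_range[2] <= trunc_range[1]) stop("invalid truncation range")
  structure(list(sg_order = as.integer(sg_order),
                 sg_window = as.integer(sg_window),
                 ball_radius = ball_radius,
                 trunc_range = as.numeric(trunc_range),
                 calib_degree = as.integer(calib_degree),
                 resample_spacing = resample_spacing),
            class = "preprocess_config")
}

#' Average repeated accumulations of one measurement
#'
#' @param accumulations Non-empty list of raw `raman_spectrum` sharing an
#'   axis.
#' @param spectrum_id Id for the averaged spectrum (default: id of the first
#'   accumulation stripped of any `_accNN` suffix).
#' @return Averaged `raman_spectrum`, stage "averaged".
#' @export
average_accumulations <- function(accumulations, spectrum_id = NULL) {
  if (length(accumulations) == 0L) stop("empty accumulation list")
  first <- accumulations[[1L]]
  for (s in accumulations[-1L]) assert_shared_axis(first, s, "accumulations")
  avg <- Reduce(`+`, lapply(accumulations, `[[`, "intensity")) /
    length(accumulations)
  if (is.null(spectrum_id)) {
    spectrum_id <- sub("_acc[0-9]+$", "", first$spectrum_id)
  }
  raman_spectrum(spectrum_id, first$wavenumber, avg, stage = "averaged")
}

#' Subtract the dark-count background
#'
#' Pointwise subtraction of a laser-off measurement; negative results are
#' allowed (noise around zero).
#'
#' @param s Spectrum to correct.
#' @param dark Dark `raman_spectrum` on the same axis.
#' @return Spectrum with stage "dark_subtracted".
#' @export
subtract_dark <- function(s, dark) {
  assert_shared_axis(s, dark)
  raman_spectrum(s$spectrum_id, s$wavenumber, s$intensity - dark$intensity,
                 stage = "dark_subtracted", validate = FALSE)
}

#' Estimate the relative instrument response from a standard measurement
#'
#' The measured emission of the intensity standard is smoothed (same
#' Savitzky-Golay settings as the smoothing step), divided by the certified
#' emission curve, and rescaled to unit mean. Division by the unit-mean
#' estimate makes the correction invariant to the standard's exposure.
#'
#' @param refs A `calibration_refs` object.
#' @param sg_order,sg_window Savitzky-Golay settings for smoothing the
#'   measured standard.
#' @return Numeric vector: unit-mean response estimate per raw-axis bin.
#' @export
estimate_response <- function(refs, sg_order = 3L, sg_window = 11L) {
  sm <- sg_filter(refs$response_measured$intensity, sg_order, sg_window)
  if (any(sm <= 0)) {
    stop("smoothed response-standard measurement is nonpositive at some bins")
  }
  est <- sm / refs$response_certified
  est / mean(est)
}

#' Correct a spectrum for the instrument spectral response
#'
#' @param s Spectrum on the raw axis.
#' @param refs A `calibration_refs` object.
#' @param sg_order,sg_window Savitzky-Golay settings used when smoothing the
#'   standard's measurement.
#' @param response_estimate Optional precomputed unit-mean estimate (from
#'   [estimate_response()]); avoids re-smoothing per spectrum.
#' @return Spectrum with stage "response_corrected".
#' @export
correct_instrument_response <- function(s, refs, sg_order = 3L,
                                        sg_window = 11L,
                                        response_estimate = NULL) {
  assert_shared_axis(s, refs$response_measured, "spectrum and response standard")
  if (is.null(response_estimate)) {
    response_estimate <- estimate_response(refs, sg_order, sg_window)
  }
  raman_spectrum(s$spectrum_id, s$wavenumber,
                 s$intensity / response_estimate,
                 stage = "response_corrected", validate = FALSE)
}

#' Fit the wavenumber calibration map from reference peak pairs
#'
#' Least-squares polynomial fit of known positions on measured positions of
#' the calibration compound, using a centred/scaled predictor for numerical
#' conditioning. The fitted map must be monotone over the axis span.
#'
#' @param refs A `calibration_refs` object.
#' @param degree Polynomial degree (default 3); needs `degree + 1` pairs.
#' @param axis_span Range over which monotonicity is verified.
#' @return List with `map` (function measured -> known), `residual_rms`, and
#'   `coef`.
#' @export
fit_wavenumber_map <- function(refs, degree = 3L,
                               axis_span = range(refs$dark$wavenumber)) {
  p <- refs$wavenumber_ref_peaks
  if (nrow(p) < degree + 1L) {
    stop(sprintf("need >= %d reference peak pairs for degree %d",
                 degree + 1L, degree))
  }
  u <- (p$measured - 1050) / 750
  X <- stats::poly(u, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), p$known)
  co <- fit$coefficients
  map <- function(x) {
    ux <- (x - 1050) / 750
    drop(cbind(1, stats::poly(ux, degree = degree, raw = TRUE)) %*% co)
  }
  grid <- seq(axis_span[1], axis_span[2], length.out = 512L)
  if (any(diff(map(grid)) <= 0)) {
    stop("fitted wavenumber calibration map is not monotone over the axis")
  }
  list(map = map, residual_rms = sqrt(mean(fit$residuals^2)), coef = co)
}

#' Calibrate the wavenumber axis of a spectrum
#'
#' Applies the fitted measured-to-known polynomial map to the axis. With
#' `spacing = NULL` the remapped axis is kept as-is (an identity map leaves
#' the axis unchanged); with a numeric `spacing` the intensities are linearly
#' re-interpolated onto a uniform grid `700 + k * spacing` covering the
#' remapped span, so that downstream closed truncation to
#' \[700, 1700\] cm^-1 retains exactly `floor(1000/spacing) + 1` bins.
#'
#' @param s Spectrum to calibrate.
#' @param refs A `calibration_refs` object.
#' @param degree Polynomial degree of the map (default 3).
#' @param spacing Uniform output grid spacing in cm^-1, or `NULL` to keep
#'   the remapped axis.
#' @param map Optional precomputed result of [fit_wavenumber_map()].
#' @return Spectrum with stage "calibrated"; the calibration residual RMS is
#'   attached as attribute `residual_rms`.
#' @export
calibrate_wavenumber <- function(s, refs, degree = 3L, spacing = NULL,
                                 map = NULL) {
  if (is.null(map)) {
    map <- fit_wavenumber_map(refs, degree,
                              axis_span = range(s$wavenumber))
  }
  mapped <- map$map(s$wavenumber)
  if (any(diff(mapped) <= 0)) {
    stop(sprintf("spectrum '%s': calibrated axis not monotone",
                 s$spectrum_id))
  }
  if (is.null(spacing)) {
    out <- raman_spectrum(s$spectrum_id, mapped, s$intensity,
                          stage = "calibrated", validate = FALSE)
  } else {
    k <- seq(ceiling((min(mapped) - 700) / spacing),
             floor((max(mapped) - 700) / spacing))
    grid <- 700 + k * spacing
    yi <- stats::approx(mapped, s$intensity, xout = grid)$y
    out <- raman_spectrum(s$spectrum_id, grid, yi,
                          stage = "calibrated", validate = FALSE)
  }
  attr(out, "residual_rms") <- map$residual_rms
  out
}

# Savitzky-Golay filter on a numeric vector (bin-index abscissa).
# Interior: convolution with the order-p centred least-squares weights.
# Edges: explicit polynomial fit on the truncated one-sided window.
sg_filter <- function(y, order = 3L, window = 11L) {
  n <- length(y)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window <= order) stop("Savitzky-Golay window must exceed the order")
  if (window > n) stop("Savitzky-Golay window exceeds the axis length")
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  w <- (solve(crossprod(A)) %*% t(A))[1L, ]  # value of the LS fit at 0
  out <- as.numeric(stats::filter(y, w, sides = 2L))
  for (i in seq_len(h)) {
    idx <- seq_len(min(n, i + h))
    Ai <- outer(idx - i, 0:order, `^`)
    out[i] <- drop(Ai[idx == i, , drop = FALSE] %*%
                     qr.solve(Ai, y[idx]))
    j <- n - i + 1L
    idxj <- seq(max(1L, j - h), n)
    Aj <- outer(idxj - j, 0:order, `^`)
    out[j] <- drop(Aj[idxj == j, , drop = FALSE] %*%
                     qr.solve(Aj, y[idxj]))
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each intensity by the value, at that bin, of the local
#' least-squares polynomial of the given order over the centred window; at
#' the edges the polynomial is fitted on the truncated one-sided window (no
#' reflection padding). An order-3 filter reproduces any cubic exactly.
#'
#' @param s Spectrum to smooth.
#' @param order Polynomial order (default 3).
#' @param window Odd window length (default 11).
#' @return Spectrum with stage "smoothed".
#' @export
smooth_savitzky_golay <- function(s, order = 3L, window = 11L) {
  raman_spectrum(s$spectrum_id, s$wavenumber,
                 sg_filter(s$intensity, order, window),
                 stage = "smoothed", validate = FALSE)
}

# morphological opening with a disc structuring element in
# (cm^-1, scaled-intensity) space; y_scale maps intensity to cm^-1 units
ball_opening <- function(x, y, radius, scale) {
  spacing <- stats::median(diff(x))
  K <- max(1L, floor(radius / spacing))
  # replicate the edge values for one ball radius on each side so the
  # opening has full support at the boundaries (no edge roll-off)
  yt <- c(rep(y[1L], K), y, rep(y[length(y)], K)) / scale
  offs <- seq(-K, K)
  ball <- sqrt(pmax(radius^2 - (offs * spacing)^2, 0))
  n <- length(yt)
  shift_pad <- function(v, k, pad) {
    if (k == 0L) return(v)
    if (k > 0L) c(v[-seq_len(k)], rep(pad, k))
    else c(rep(pad, -k), v[seq_len(n + k)])
  }
  ero <- rep(Inf, n)
  for (j in seq_along(offs)) {
    ero <- pmin(ero, shift_pad(yt, offs[j], Inf) - ball[j])
  }
  dil <- rep(-Inf, n)
  for (j in seq_along(offs)) {
    dil <- pmax(dil, shift_pad(ero, offs[j], -Inf) + ball[j])
  }
  dil[(K + 1L):(n - K)] * scale
}

# Iterated rolling ball: the first opening scales intensity by the full
# data range; each further pass rescales by the *peak-structure* range of
# the previous correction, so the ball geometry — and hence the residual
# penetration into inter-peak gaps — converges to a baseline-amplitude-
# independent shape. Three passes suffice (the scale is stationary after
# two).
rolling_ball_baseline <- function(x, y, radius, smooth_window = 11L,
                                  smooth_order = 3L) {
  rng <- max(y) - min(y)
  if (rng == 0) return(y)
  base <- ball_opening(x, y, radius, rng / radius)
  for (pass in 1:2) {
    rng2 <- max(y - base) - min(y - base)
    if (rng2 <= 0) break
    base <- ball_opening(x, y, radius, rng2 / radius)
  }
  if (smooth_window < length(y)) {
    base <- sg_filter(base, smooth_order, smooth_window)
  }
  base
}

#' Rolling-ball baseline removal
#'
#' Estimates the slowly varying autofluorescence background as the
#' morphological opening (erosion then dilation) of the spectrum with a disc
#' structuring element of the given radius in (cm^-1, scaled-intensity)
#' space — the envelope traced by a ball rolled under the spectrum — then
#' smooths the envelope with the same Savitzky-Golay window and subtracts it.
#' The intensity scaling is set in two passes: a first opening (scaled by the
#' full data range) strips the baseline, and the definitive opening scales
#' intensity by the range of that first correction, i.e. by the peak
#' structure alone, making the residual independent of the baseline
#' amplitude.
#'
#' @param s Spectrum to correct.
#' @param radius Ball radius in cm^-1 (default 120); must exceed the bin
#'   spacing and should be much larger than any band FWHM.
#' @param smooth_window,smooth_order Savitzky-Golay settings for smoothing
#'   the baseline estimate.
#' @return List with `corrected` (stage "debaselined") and `baseline`
#'   spectra.
#' @export
remove_baseline_rollingball <- function(s, radius = 120,
                                        smooth_window = 11L,
                                        smooth_order = 3L) {
  if (radius <= 0) stop("radius must be positive")
  spacing <- stats::median(diff(s$wavenumber))
  if (radius <= spacing) stop("radius must exceed the bin spacing")
  base <- rolling_ball_baseline(s$wavenumber, s$intensity, radius,
                                smooth_window, smooth_order)
  list(
    corrected = raman_spectrum(s$spectrum_id, s$wavenumber,
                               s$intensity - base,
                               stage = "debaselined", validate = FALSE),
    baseline = raman_spectrum(paste0(s$spectrum_id, "_baseline"),
                              s$wavenumber, base,
                              stage = "debaselined", validate = FALSE))
}

#' Truncate the wavenumber axis
#'
#' Retains bins with `lo <= wavenumber <= hi` (closed interval).
#'
#' @param s Spectrum.
#' @param lo,hi Interval bounds in cm^-1 (defaults 700 and 1700).
#' @return Spectrum with stage "truncated".
#' @export
truncate_axis <- function(s, lo = 700, hi = 1700) {
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) < 2L) {
    stop(sprintf("spectrum '%s': truncation to [%g, %g] leaves < 2 bins",
                 s$spectrum_id, lo, hi))
  }
  raman_spectrum(s$spectrum_id, s$wavenumber[keep], s$intensity[keep],
                 stage = "truncated", validate = FALSE)
}

#' Standard normal variate (SNV) normalization
#'
#' Per-spectrum transform `(x - mean) / sd` (sample SD), yielding mean 0 and
#' SD 1.
#'
#' @param s Spectrum.
#' @return Spectrum with stage "snv".
#' @export
normalize_snv <- function(s) {
  sdv <- stats::sd(s$intensity)
  if (!is.finite(sdv) || sdv == 0) {
    stop(sprintf("spectrum '%s': constant spectrum, SNV undefined",
                 s$spectrum_id))
  }
  raman_spectrum(s$spectrum_id, s$wavenumber,
                 (s$intensity - mean(s$intensity)) / sdv, stage = "snv")
}

#' Run the full preprocessing chain over a dataset
#'
#' Applies, in order: accumulation averaging (when raw accumulations are
#' supplied), dark subtraction, instrument response correction, wavenumber
#' calibration with resampling, Savitzky-Golay smoothing, rolling-ball
#' baseline removal, axis truncation, and SNV normalization. Spectra are
#' processed independently; the only shared state is the calibration
#' references.
#'
#' @param ds A `raman_dataset` (stages "raw" or "averaged").
#' @param refs A `calibration_refs` object; defaults to `ds$refs`.
#' @param config A [preprocess_config()].
#' @return List with `dataset` (processed, stage "snv") and `audit` (per-step
#'   per-spectrum log entries, serializable as JSON lines via
#'   [write_audit_log()]).
#' @export
run_preprocessing <- function(ds, refs = ds$refs,
                              config = preprocess_config()) {
  stopifnot(inherits(ds, "raman_dataset"))
  if (is.null(refs)) stop("calibration references are required")
  stages <- vapply(ds$spectra, `[[`, character(1), "stage")
  if (!all(stages %in% c("raw", "averaged"))) {
    stop("run_preprocessing expects raw or averaged spectra")
  }
  resp <- estimate_response(refs, config$sg_order, config$sg_window)
  wmap <- fit_wavenumber_map(refs, config$calib_degree,
                             axis_span = range(refs$dark$wavenumber))
  out <- vector("list", length(ds$spectra))
  audit <- vector("list", length(ds$spectra))
  for (i in seq_along(ds$spectra)) {
    s <- ds$spectra[[i]]
    id <- s$spectrum_id
    res <- tryCatch({
      s1 <- subtract_dark(s, refs$dark)
      s2 <- correct_instrument_response(s1, refs, response_estimate = resp)
      s3 <- calibrate_wavenumber(s2, refs, degree = config$calib_degree,
                                 spacing = config$resample_spacing,
                                 map = wmap)
      s4 <- smooth_savitzky_golay(s3, config$sg_order, config$sg_window)
      bl <- remove_baseline_rollingball(s4, config$ball_radius,
                                        config$sg_window, config$sg_order)
      s6 <- truncate_axis(bl$corrected, config$trunc_range[1],
                          config$trunc_range[2])
      s7 <- normalize_snv(s6)
      list(spectrum = s7,
           log = list(spectrum_id = id, ok = TRUE,
                      calibration_rms = wmap$residual_rms,
                      baseline_median = stats::median(bl$baseline$intensity),
                      snv_scale = stats::sd(s6$intensity),
                      n_bins = length(s7$wavenumber)))
    }, error = function(e) {
      stop(sprintf("preprocessing failed for spectrum '%s': %s",
                   id, conditionMessage(e)), call. = FALSE)
    })
    out[[i]] <- res$spectrum
    audit[[i]] <- res$log
  }
  list(dataset = raman_dataset(out, ds$meta, refs = refs),
       audit = audit)
}

#' Write a preprocessing audit log as JSON lines
#'
#' @param audit The `audit` element returned by [run_preprocessing()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_audit_log <- function(audit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in audit) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
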