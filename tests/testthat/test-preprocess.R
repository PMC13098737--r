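test_that("accumulation averaging is the pointwise mean", {
  x <- 700 + 0:9
  s1 <- raman_spectrum("a_acc01", x, rep(2, 10))
  s2 <- raman_spectrum("a_acc02", x, rep(4, 10))
  expect_equal(average_accumulations(list(s1))$intensity, rep(2, 10))
  avg <- average_accumulations(list(s1, s2))
  expect_equal(avg$intensity, rep(3, 10))
  expect_identical(avg$stage, "averaged")
  expect_identical(avg$spectrum_id, "a")
  expect_error(average_accumulations(list()), "empty")

  # brute-force oracle on simulated accumulations
  sim <- simulate_spectrum(default_profiles(3)$normal, small_instrument(),
                           seed = 4)
  manual <- colMeans(do.call(rbind,
                             lapply(sim$accumulations, `[[`, "intensity")))
  expect_lt(max(abs(average_accumulations(sim$accumulations)$intensity -
                      manual)), 1e-12)
  expect_lt(max(abs(sim$averaged$intensity - manual)), 1e-12)
})

test_that("dark subtraction removes the dark level", {
  x <- 700 + 0:49
  s <- raman_spectrum("s", x, 100 + sin(x / 10))
  expect_equal(subtract_dark(s, s)$intensity, rep(0, 50))
  zero <- raman_spectrum("dark", x, rep(0, 50))
  expect_equal(subtract_dark(s, zero)$intensity, s$intensity)
  expect_error(subtract_dark(s, raman_spectrum("d", x + 1, rep(0, 50))),
               "axis mismatch")
  # generator truth: known dark level 100 removed to within noise SD / sqrt(n)
  inst <- instrument_model(bins = 512L, dark_level = 100,
                           distortion_coef = c(0, 0, 0, 0))
  prof <- noiseless_profiles()$normal
  prof$bands$mean_height <- prof$bands$mean_height * 0
  ds <- simulate_dataset(list(normal = prof), inst, counts = c(normal = 1),
                         patients_per_class = 1, specimens_per_class = 1,
                         seed = 8)
  corrected <- subtract_dark(ds$spectra[[1]], ds$refs$dark)
  tol <- 3 * inst$dark_noise_sd / sqrt(inst$accumulations * 512)
  expect_lt(abs(mean(corrected$intensity)), tol + 1)
})

test_that("response correction recovers the flat-response spectrum", {
  inst <- instrument_model(bins = 512L, dark_level = 0, dark_noise_sd = 0,
                           shot_scale = 0, distortion_coef = c(0, 0, 0, 0),
                           accumulations = 1L)
  prof <- noiseless_profiles()
  ds <- simulate_dataset(prof["normal"], inst, counts = c(normal = 1),
                         patients_per_class = 1, specimens_per_class = 1,
                         seed = 3)
  flat <- quiet_instrument()
  ds_flat <- simulate_dataset(prof["normal"], flat, counts = c(normal = 1),
                              patients_per_class = 1,
                              specimens_per_class = 1, seed = 3)
  corrected <- correct_instrument_response(ds$spectra[[1]], ds$refs)
  truth <- ds_flat$spectra[[1]]$intensity
  # unit-mean normalization leaves a global scale; compare after rescaling
  sc <- mean(corrected$intensity) / mean(truth)
  rel_rms <- sqrt(mean((corrected$intensity / sc - truth)^2)) /
    sqrt(mean(truth^2))
  expect_lt(rel_rms, 0.01)

  # identity response: flat measured equal to certified leaves data unchanged
  x <- instrument_axis(flat)
  refs_id <- calibration_refs(
    dark = raman_spectrum("d", x, rep(0, length(x)), stage = "averaged"),
    response_measured = raman_spectrum("r", x, rep(5, length(x)),
                                       stage = "averaged"),
    response_certified = rep(5, length(x)),
    wavenumber_ref_peaks = data.frame(known = c(400, 800, 1200, 1600),
                                      measured = c(400, 800, 1200, 1600)))
  s <- raman_spectrum("s", x, 10 + sin(x / 50), stage = "averaged")
  expect_equal(correct_instrument_response(s, refs_id)$intensity,
               s$intensity, tolerance = 1e-12)
  # doubling the standard's exposure changes nothing (unit-mean rescaling)
  refs2 <- refs_id
  refs2$response_measured$intensity <- refs2$response_measured$intensity * 2
  expect_equal(correct_instrument_response(s, refs2)$intensity,
               correct_instrument_response(s, refs_id)$intensity,
               tolerance = 1e-12)
})

test_that("wavenumber calibration recovers the distortion map", {
  inst <- small_instrument()
  ds <- simulate_dataset(default_profiles(3), inst, counts = c(normal = 1),
                         patients_per_class = 1, specimens_per_class = 1,
                         seed = 6)
  wmap <- fit_wavenumber_map(ds$refs, degree = 3)
  x <- instrument_axis(inst)
  truth <- distortion_map(inst)(x)
  expect_lt(max(abs(wmap$map(x) - truth) / pmax(abs(truth), 1)), 1e-6)
  expect_lt(wmap$residual_rms, 1e-6)

  # identity pairs leave the axis unchanged (no resampling by default)
  refs_id <- ds$refs
  refs_id$wavenumber_ref_peaks$measured <- refs_id$wavenumber_ref_peaks$known
  s <- ds$spectra[[1]]
  cal <- calibrate_wavenumber(s, refs_id, degree = 3)
  expect_lt(max(abs(cal$wavenumber - s$wavenumber)), 1e-9)
  expect_lt(attr(cal, "residual_rms"), 1e-9)

  refs3 <- ds$refs
  refs3$wavenumber_ref_peaks <- refs3$wavenumber_ref_peaks[1:3, ]
  expect_error(fit_wavenumber_map(refs3, degree = 3),
               "reference peak pairs")
})

test_that("calibration resampling produces the anchored uniform grid", {
  inst <- small_instrument()
  ds <- simulate_dataset(default_profiles(3), inst, counts = c(normal = 1),
                         patients_per_class = 1, specimens_per_class = 1,
                         seed = 6)
  cal <- calibrate_wavenumber(ds$spectra[[1]], ds$refs, degree = 3,
                              spacing = 1.1)
  w <- cal$wavenumber
  expect_lt(max(abs((w - 700) / 1.1 - round((w - 700) / 1.1))), 1e-9)
  expect_equal(diff(range(diff(w))), 0, tolerance = 1e-9)
  # closed truncation of the 1.1 grid retains 910 bins
  tr <- truncate_axis(cal, 700, 1700)
  expect_identical(length(tr$wavenumber), 910L)
})

test_that("Savitzky-Golay filter matches the windowed least-squares oracle", {
  # order-3 filter reproduces cubics exactly, interior and edges
  x <- 700 + 0:99
  y_cubic <- 2 + 0.5 * (x - 750) + 0.01 * (x - 750)^2 - 1e-4 * (x - 750)^3
  s <- raman_spectrum("c", x, y_cubic - min(y_cubic) + 1)
  sm <- smooth_savitzky_golay(s, 3, 11)
  expect_lt(max(abs(sm$intensity - s$intensity)), 1e-9)

  # brute-force oracle at every interior point, several random spectra
  set.seed(42)
  for (r in 1:10) {
    y <- rnorm(60)
    sg <- ramanfcd:::sg_filter(y, 3, 11)
    oracle <- vapply(6:55, function(i) {
      idx <- (i - 5):(i + 5)
      fit <- lm(y[idx] ~ poly(idx - i, 3, raw = TRUE))
      unname(fit$fitted.values[idx == i])
    }, numeric(1))
    expect_lt(max(abs(sg[6:55] - oracle)), 1e-9)
    # edges: truncated one-sided window fit
    idx <- 1:7
    fit2 <- lm(y[idx] ~ poly(idx - 2, 3, raw = TRUE))
    expect_equal(sg[2], unname(fit2$fitted.values[idx == 2]),
                 tolerance = 1e-9)
  }

  # smoothing contracts white noise
  set.seed(1)
  y <- rnorm(500)
  expect_lt(var(ramanfcd:::sg_filter(y, 3, 11)), var(y))
  expect_error(smooth_savitzky_golay(
    raman_spectrum("e", x, y_cubic - min(y_cubic) + 1), 3, 10), "odd")
  expect_error(smooth_savitzky_golay(
    raman_spectrum("e", x, y_cubic - min(y_cubic) + 1), 3, 3), "exceed")
})

test_that("interior Savitzky-Golay agrees with the signal package", {
  skip_if_not_installed("signal")
  set.seed(7)
  y <- rnorm(200)
  ours <- ramanfcd:::sg_filter(y, 3, 11)
  theirs <- signal::sgolayfilt(y, p = 3, n = 11)
  expect_lt(max(abs(ours[6:195] - theirs[6:195])), 1e-9)
})

test_that("rolling ball removes slow baselines and preserves peaks", {
  x <- seq(700, 1700, by = 1.1)
  # pure slowly-varying exponential baseline
  base <- 800 * exp(-(x - 700) / 600)
  s <- raman_spectrum("b", x, base)
  out <- remove_baseline_rollingball(s, 120)
  expect_lt(sqrt(mean(out$corrected$intensity^2)), 0.02 * 800)

  # zero input -> zero baseline and zero output
  z <- raman_spectrum("z", x, rep(0, length(x)), stage = "averaged")
  outz <- remove_baseline_rollingball(z, 120)
  expect_equal(outz$corrected$intensity, rep(0, length(x)))

  # narrow Gaussian on a linear baseline: fitted height within 5% of truth
  y <- gauss_fwhm(x, 1200, 50, 10) + 0.05 * (x - 700) + 30
  sp <- raman_spectrum("p", x, y)
  outp <- remove_baseline_rollingball(sp, 120)
  fit <- fit_gaussian_peaks(
    snv_spectrum(x, outp$corrected$intensity), 1200)
  scale_truth <- 50  # corrected spectrum is still in intensity units here
  expect_lt(abs(fit$height - scale_truth) / scale_truth, 0.05)
  expect_error(remove_baseline_rollingball(sp, -1), "positive")
})

test_that("axis truncation keeps the closed interval", {
  x <- seq(300, 1800, by = 1)
  s <- raman_spectrum("t", x, rexp(length(x)))
  tr <- truncate_axis(s, 700, 1700)
  expect_gte(min(tr$wavenumber), 700)
  expect_lte(max(tr$wavenumber), 1700)
  expect_identical(length(tr$wavenumber), 1001L)  # closed 1 cm^-1 grid
  expect_equal(truncate_axis(s, 300, 1800)$intensity, s$intensity)
  expect_error(truncate_axis(s, 2000, 2100), "leaves")
})

test_that("SNV normalization has the closed form and affine invariance", {
  x <- 700 + 0:2
  s <- raman_spectrum("s", x, c(1, 2, 3))
  expect_equal(normalize_snv(s)$intensity, c(-1, 0, 1))
  set.seed(5)
  y <- rexp(200)
  s1 <- raman_spectrum("a", 700 + 0:199, y)
  s2 <- raman_spectrum("b", 700 + 0:199, 3.7 * y + 11)
  expect_equal(normalize_snv(s1)$intensity, normalize_snv(s2)$intensity,
               tolerance = 1e-12)
  out <- normalize_snv(s1)
  expect_lt(abs(mean(out$intensity)), 1e-9)
  expect_lt(abs(sd(out$intensity) - 1), 1e-9)
  expect_error(normalize_snv(raman_spectrum("c", x, rep(2, 3))), "constant")
})

test_that("the full chain yields valid SNV spectra independent of dataset order", {
  prof <- default_profiles(3)
  inst <- small_instrument()
  ds <- simulate_dataset(prof, inst,
                         counts = c(normal = 3, FCD_IIa = 2, FCD_IIb = 2),
                         patients_per_class = 1, specimens_per_class = 1,
                         seed = 31)
  pp <- run_preprocessing(ds)
  for (s in pp$dataset$spectra) {
    expect_identical(s$stage, "snv")
    expect_silent(validate_spectrum(s))
  }
  # permuting the dataset leaves each spectrum's output unchanged
  perm <- rev(seq_along(ds$spectra))
  ds_perm <- raman_dataset(ds$spectra[perm], ds$meta, refs = ds$refs)
  pp2 <- run_preprocessing(ds_perm)
  for (id in names(ds$spectra)) {
    expect_identical(pp$dataset$spectra[[id]]$intensity,
                     pp2$dataset$spectra[[id]]$intensity)
  }
})

test_that("SNV-domain class contrasts carry the profile contrast signs", {
  prof <- default_profiles(effect_scale = 3)
  for (nm in names(prof)) prof[[nm]]$patient_sd <- 1e-12
  inst <- small_instrument()
  ds <- simulate_dataset(prof, inst,
                         counts = c(normal = 12, FCD_IIa = 6, FCD_IIb = 6),
                         patients_per_class = 2, specimens_per_class = 3,
                         seed = 17)
  pp <- run_preprocessing(ds)
  mat <- do.call(rbind, lapply(pp$dataset$spectra, `[[`, "intensity"))
  w <- pp$dataset$spectra[[1]]$wavenumber
  dx <- pp$dataset$meta$diagnosis
  mean_at <- function(cls, pos) {
    rowm <- colMeans(mat[dx %in% cls, , drop = FALSE])
    rowm[which.min(abs(w - pos))]
  }
  d1 <- ramanfcd:::contrast_fcd_vs_normal()
  # bands with no disease-vs-control contrast impose no sign constraint
  agree <- vapply(names(d1), function(p) {
    pos <- as.numeric(p)
    diffv <- mean_at(c("FCD_IIa", "FCD_IIb"), pos) - mean_at("normal", pos)
    d1[[p]] == 0 || sign(diffv) == d1[[p]]
  }, logical(1))
  expect_gte(sum(agree), 15L)
})

test_that("preprocessed output is insensitive to the baseline amplitude", {
  inst <- quiet_instrument(bins = 1024L)  # the study's native resolution
  mk <- function(amp) {
    prof <- noiseless_profiles()
    prof$normal$baseline_amplitude <- amp
    ds <- simulate_dataset(prof["normal"], inst, counts = c(normal = 1),
                           patients_per_class = 1, specimens_per_class = 1,
                           seed = 12)
    run_preprocessing(ds)$dataset$spectra[[1]]$intensity
  }
  lo <- mk(400)
  hi <- mk(1600)
  expect_lt(sqrt(mean((hi - lo)^2)), 0.02 * sqrt(mean(lo^2)))
})

test_that("preprocessing config validates its invariants", {
  expect_error(preprocess_config(sg_window = 10), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_order = 3), "exceed")
  expect_error(preprocess_config(ball_radius = 0), "positive")
})
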