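# Shared fixtures built in code. Small instruments keep unit tests fast;
# the full-size default instrument is used only where the study-scale
# conditions matter.

# compact instrument: fewer bins, otherwise the default acquisition model
small_instrument <- function(...) {
  instrument_model(bins = 512L, ...)
}

# noiseless, distortion-free instrument for exact-recovery oracles
quiet_instrument <- function(bins = 512L, ...) {
  instrument_model(bins = bins, dark_level = 0, dark_noise_sd = 0,
                   shot_scale = 0, distortion_coef = c(0, 0, 0, 0),
                   response = function(x) rep(1, length(x)),
                   certified = function(x) rep(1, length(x)),
                   accumulations = 1L, ...)
}

# deterministic class profiles with no jitter / baseline / patient effects
noiseless_profiles <- function(effect_scale = 3) {
  prof <- default_profiles(effect_scale = effect_scale)
  for (nm in names(prof)) {
    prof[[nm]]$bands$height_cv <- 1e-12
    prof[[nm]]$baseline_amplitude <- 0
    prof[[nm]]$baseline_cv <- 0
    prof[[nm]]$patient_sd <- 1e-12
  }
  prof
}

# small three-class dataset run through the full preprocessing chain
make_processed_dataset <- function(n_per_class = 6, seed = 101,
                                   effect_scale = 3,
                                   instrument = small_instrument(),
                                   profiles = default_profiles(effect_scale)) {
  counts <- c(normal = n_per_class, FCD_IIa = n_per_class,
              FCD_IIb = n_per_class)
  ds <- simulate_dataset(profiles, instrument, counts = counts,
                         patients_per_class = max(2, n_per_class %/% 3),
                         specimens_per_class = max(2, n_per_class %/% 2),
                         seed = seed)
  run_preprocessing(ds)$dataset
}

# an SNV-stage spectrum holding an arbitrary intensity vector (bypasses the
# constructor's SNV invariant; used to probe detector edge cases)
snv_spectrum <- function(wavenumber, intensity, id = "probe") {
  raman_spectrum(id, wavenumber, intensity, stage = "snv", validate = FALSE)
}

# Gaussian band in the FWHM parameterization
gauss_fwhm <- function(x, mu, h, w) h * exp(-4 * log(2) * (x - mu)^2 / w^2)

# one moderately sized three-class feature matrix shared across test files
# (memoised: the pipeline runs once per session)
.shared_cache <- new.env(parent = emptyenv())

shared_pipeline_features <- function() {
  if (is.null(.shared_cache$fm)) {
    ds <- simulate_dataset(default_profiles(effect_scale = 3),
                           instrument_model(),
                           counts = c(normal = 16, FCD_IIa = 8,
                                      FCD_IIb = 8),
                           patients_per_class = c(4, 2, 2),
                           specimens_per_class = c(6, 3, 3), seed = 314)
    pp <- run_preprocessing(ds)
    fits <- fit_dataset_peaks(pp$dataset)
    cons <- build_consensus(fits)
    .shared_cache$fm <- extract_features(pp$dataset, cons, fits)
  }
  .shared_cache$fm
}

# random feature matrix with class labels; optionally a planted mean shift
random_feature_matrix <- function(n, p, seed, shift = 0, shifted_cols = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- rep(c("A", "B"), length.out = n)
  if (shifted_cols > 0) {
    X[y == "B", seq_len(shifted_cols)] <-
      X[y == "B", seq_len(shifted_cols)] + shift
  }
  fm <- data.frame(spectrum_id = sprintf("s%04d", seq_len(n)),
                   patient_id = sprintf("p%03d", rep(seq_len(max(2, n %/% 5)),
                                                     length.out = n)))
  cbind(fm, as.data.frame(X), stringsAsFactors = FALSE)
}
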