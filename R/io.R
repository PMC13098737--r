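#' Read spectra and cell metadata from CSV
#'
#' The canonical interchange format is long form: one row per
#' (spectrum, wavenumber) with columns `spectrum_id`, `wavenumber`,
#' `intensity`. A wide matrix (column `wavenumber` plus one numeric column
#' per spectrum) is also accepted when all spectra share an axis. Axes are
#' sorted ascending on read; a descending input axis is reordered with a
#' message. Joins are by `spectrum_id`, never by row order.
#'
#' @param path Spectral CSV (UTF-8, header, '.' decimal).
#' @param meta_path Metadata CSV with columns `spectrum_id`, `patient_id`,
#'   `specimen_id`, `cell_type`, `diagnosis`.
#' @param stage Stage tag to assign to the read spectra (default "raw").
#' @return A [raman_dataset()].
#' @export
read_spectra <- function(path, meta_path, stage = "raw") {
  if (!file.exists(path)) stop("spectral file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  dt <- data.table::fread(path, showProgress = FALSE)
  long <- all(c("spectrum_id", "wavenumber", "intensity") %in% names(dt))
  wide <- !long && !"spectrum_id" %in% names(dt) &&
    "wavenumber" %in% names(dt) && ncol(dt) >= 2L &&
    all(vapply(dt, is.numeric, logical(1)))
  if (wide) {
    # wide layout: melt to long; every non-wavenumber column is a spectrum
    dt <- data.table::melt(
      dt, id.vars = "wavenumber", variable.name = "spectrum_id",
      value.name = "intensity", variable.factor = FALSE)
  } else if (!long) {
    missing_cols <- setdiff(c("spectrum_id", "wavenumber", "intensity"),
                            names(dt))
    stop("spectral file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(dt, by = c("spectrum_id", "wavenumber"))
  if (any(dup)) {
    d <- dt[which(dup)[1L]]
    stop(sprintf(
      "duplicated (spectrum_id, wavenumber) row: ('%s', %g)",
      d$spectrum_id, d$wavenumber))
  }
  meta <- validate_cell_meta(utils::read.csv(meta_path))
  ids <- unique(dt$spectrum_id)
  spectra <- lapply(ids, function(id) {
    sub <- dt[dt$spectrum_id == id]
    if (all(diff(sub$wavenumber) < 0)) {
      message("spectrum '", id, "': descending axis sorted ascending on read")
    }
    o <- order(sub$wavenumber)
    raman_spectrum(id, sub$wavenumber[o], sub$intensity[o], stage = stage)
  })
  raman_dataset(spectra, meta)
}

#' Write a dataset to long-form CSV
#'
#' Inverse of [read_spectra()]; round-trips axis, intensity and metadata at
#' full double precision.
#'
#' @param ds A `raman_dataset`.
#' @param path Output spectral CSV path.
#' @param meta_path Output metadata CSV path.
#' @return Invisibly, the normalized `path`.
#' @export
write_spectra <- function(ds, path, meta_path) {
  stopifnot(inherits(ds, "raman_dataset"))
  long <- data.table::rbindlist(lapply(ds$spectra, function(s) {
    data.table::data.table(spectrum_id = s$spectrum_id,
                           wavenumber = fmt_full(s$wavenumber),
                           intensity = fmt_full(s$intensity))
  }))
  data.table::fwrite(long, path, quote = FALSE)
  data.table::fwrite(ds$meta, meta_path)
  invisible(path)
}

# 17 significant digits: doubles survive the text round-trip bit-for-bit
fmt_full <- function(x) sprintf("%.17g", x)

#' Write calibration reference measurements to a directory
#'
#' Emits `dark.csv`, `response.csv` (measured and certified curves on the raw
#' axis) and `wavenumber_refs.csv` (known vs measured reference peak
#' positions) under `dir`.
#'
#' @param refs A `calibration_refs` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_calibration_refs <- function(refs, dir) {
  stopifnot(inherits(refs, "calibration_refs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(
    data.frame(wavenumber = fmt_full(refs$dark$wavenumber),
               intensity = fmt_full(refs$dark$intensity)),
    file.path(dir, "dark.csv"), quote = FALSE)
  data.table::fwrite(
    data.frame(wavenumber = fmt_full(refs$response_measured$wavenumber),
               measured = fmt_full(refs$response_measured$intensity),
               certified = fmt_full(refs$response_certified)),
    file.path(dir, "response.csv"), quote = FALSE)
  data.table::fwrite(
    data.frame(known = fmt_full(refs$wavenumber_ref_peaks$known),
               measured = fmt_full(refs$wavenumber_ref_peaks$measured)),
    file.path(dir, "wavenumber_refs.csv"), quote = FALSE)
  invisible(dir)
}

#' Read calibration references written by [write_calibration_refs()]
#'
#' @param dir Directory containing `dark.csv`, `response.csv`,
#'   `wavenumber_refs.csv`.
#' @return A `calibration_refs` object.
#' @export
read_calibration_refs <- function(dir) {
  dark <- utils::read.csv(file.path(dir, "dark.csv"))
  resp <- utils::read.csv(file.path(dir, "response.csv"))
  peaks <- utils::read.csv(file.path(dir, "wavenumber_refs.csv"))
  calibration_refs(
    dark = raman_spectrum("dark", dark$wavenumber, dark$intensity,
                          stage = "averaged"),
    response_measured = raman_spectrum("response_standard", resp$wavenumber,
                                       resp$measured, stage = "averaged"),
    response_certified = resp$certified,
    wavenumber_ref_peaks = peaks)
}

#' Bundle calibration reference measurements
#'
#' @param dark Laser-off `raman_spectrum` on the raw axis.
#' @param response_measured Spectrum of the intensity standard on the raw axis.
#' @param response_certified Numeric vector: certified smooth emission curve of
#'   the standard, one value per raw-axis bin.
#' @param wavenumber_ref_peaks data.frame with columns `known` and `measured`
#'   (cm^-1) for the wavenumber-calibration compound; at least 4 rows so a
#'   cubic map is identifiable.
#' @return An object of class `calibration_refs`.
#' @export
calibration_refs <- function(dark, response_measured, response_certified,
                             wavenumber_ref_peaks) {
  stopifnot(inherits(dark, "raman_spectrum"),
            inherits(response_measured, "raman_spectrum"))
  assert_shared_axis(dark, response_measured, "calibration references")
  if (length(response_certified) != length(dark$wavenumber)) {
    stop("certified response curve length does not match the raw axis")
  }
  if (any(response_certified <= 0)) {
    stop("certified response curve must be strictly positive")
  }
  p <- as.data.frame(wavenumber_ref_peaks)
  if (!all(c("known", "measured") %in% names(p))) {
    stop("wavenumber_ref_peaks needs columns 'known' and 'measured'")
  }
  if (nrow(p) < 4L) {
    stop("need >= 4 wavenumber reference peaks (cubic map)")
  }
  structure(list(dark = dark, response_measured = response_measured,
                 response_certified = as.numeric(response_certified),
                 wavenumber_ref_peaks = p),
            class = "calibration_refs")
}

#' @export
print.calibration_refs <- function(x, ...) {
  cat(sprintf(
    "<calibration_refs> %d-bin raw axis, %d wavenumber reference peaks\n",
    length(x$dark$wavenumber), nrow(x$wavenumber_ref_peaks)))
  invisible(x)
}
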