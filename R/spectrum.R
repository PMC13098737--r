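# let data.table's `[` use data.table semantics inside this namespace
.datatable.aware <- TRUE

#' Processing stages of a Raman spectrum
#'
#' Ordered vocabulary of the stages a spectrum passes through, from the raw
#' CCD read-out to the standard-normal-variate (SNV) normalized spectrum that
#' enters peak fitting.
#'
#' @format Character vector of stage names.
#' @export
SPECTRUM_STAGES <- c(
  "raw", "averaged", "dark_subtracted", "response_corrected",
  "calibrated", "smoothed", "debaselined", "truncated", "snv"
)

#' Construct a single Raman spectrum
#'
#' A spectrum couples a wavenumber axis (Raman shift, cm^-1) with one
#' intensity per bin and a processing-stage tag. The axis must be finite,
#' strictly increasing and lie within the physically sensible window
#' 100--4000 cm^-1.
#'
#' @param spectrum_id Opaque identifier string.
#' @param wavenumber Numeric vector of Raman shifts in cm^-1.
#' @param intensity Numeric vector, one value per axis bin. Counts for raw
#'   data, unitless after SNV.
#' @param stage One of [SPECTRUM_STAGES].
#' @param validate Run [validate_spectrum()] on the result (default `TRUE`).
#'   Internal callers that construct intermediate objects (e.g. an all-zero
#'   template) may disable it.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(spectrum_id, wavenumber, intensity,
                           stage = "raw", validate = TRUE) {
  s <- structure(
    list(
      spectrum_id = as.character(spectrum_id),
      wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity),
      stage = match.arg(stage, SPECTRUM_STAGES)
    ),
    class = "raman_spectrum"
  )
  if (validate) validate_spectrum(s)
  s
}

#' Validate a spectrum against its stage-specific invariants
#'
#' Checks the wavenumber-axis invariants (length >= 2, finite, strictly
#' increasing, within 100--4000 cm^-1), intensity/axis length agreement, and
#' per-stage constraints: raw intensities must be nonnegative; SNV spectra
#' must have mean 0 and sample SD 1 within `tol`.
#'
#' @param s A `raman_spectrum`.
#' @param tol Numeric tolerance for the SNV mean/SD check (default 1e-9).
#' @return `s`, invisibly; errors describe the offending spectrum by id.
#' @export
validate_spectrum <- function(s, tol = 1e-9) {
  stopifnot(inherits(s, "raman_spectrum"))
  id <- s$spectrum_id
  w <- s$wavenumber
  if (length(w) < 2L) {
    stop(sprintf("spectrum '%s': axis must have >= 2 bins", id))
  }
  if (!all(is.finite(w))) {
    stop(sprintf("spectrum '%s': non-finite wavenumber values", id))
  }
  if (any(diff(w) <= 0)) {
    stop(sprintf("spectrum '%s': wavenumber axis not strictly increasing", id))
  }
  if (min(w) < 100 || max(w) > 4000) {
    stop(sprintf("spectrum '%s': axis outside [100, 4000] cm^-1", id))
  }
  if (length(s$intensity) != length(w)) {
    stop(sprintf("spectrum '%s': intensity length %d != axis length %d",
                 id, length(s$intensity), length(w)))
  }
  if (!all(is.finite(s$intensity))) {
    stop(sprintf("spectrum '%s': non-finite intensity values", id))
  }
  if (s$stage == "raw" && any(s$intensity < 0)) {
    stop(sprintf("spectrum '%s': raw intensities must be nonnegative", id))
  }
  if (s$stage == "snv") {
    m <- mean(s$intensity)
    sdv <- stats::sd(s$intensity)
    if (abs(m) > tol || abs(sdv - 1) > tol) {
      stop(sprintf(
        "spectrum '%s': SNV invariant violated (mean %.3g, sd %.6g)",
        id, m, sdv))
    }
  }
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum '%s'> %d bins, %.1f-%.1f cm^-1, stage=%s\n",
    x$spectrum_id, length(x$wavenumber),
    min(x$wavenumber), max(x$wavenumber), x$stage))
  invisible(x)
}

# shared-axis check used by all pointwise binary operations
assert_shared_axis <- function(a, b, what = "spectra") {
  if (length(a$wavenumber) != length(b$wavenumber) ||
      max(abs(a$wavenumber - b$wavenumber)) > 1e-8) {
    stop(sprintf("axis mismatch between %s ('%s' vs '%s')",
                 what, a$spectrum_id, b$spectrum_id))
  }
  invisible(TRUE)
}

CELL_TYPES <- c("normal_neuron", "dysmorphic_neuron", "balloon_cell")
DIAGNOSES <- c("normal", "FCD_IIa", "FCD_IIb")

#' Validate a cell metadata table
#'
#' The metadata table links each spectrum to its patient, specimen, cell type
#' and diagnosis. Histopathological consistency is enforced: a `normal`
#' diagnosis implies `normal_neuron`, and FCD type IIa tissue contains only
#' dysmorphic neurons (balloon cells define type IIb).
#'
#' @param meta data.frame with columns `spectrum_id`, `patient_id`,
#'   `specimen_id`, `cell_type`, `diagnosis`.
#' @return `meta` (as a plain data.frame), invisibly validated.
#' @export
validate_cell_meta <- function(meta) {
  meta <- as.data.frame(meta)
  required <- c("spectrum_id", "patient_id", "specimen_id",
                "cell_type", "diagnosis")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$spectrum_id)) {
    stop("metadata has duplicated spectrum_id: ",
         meta$spectrum_id[duplicated(meta$spectrum_id)][1L])
  }
  bad_ct <- setdiff(unique(meta$cell_type), CELL_TYPES)
  if (length(bad_ct)) stop("unknown cell_type: ", paste(bad_ct, collapse = ", "))
  bad_dx <- setdiff(unique(meta$diagnosis), DIAGNOSES)
  if (length(bad_dx)) stop("unknown diagnosis: ", paste(bad_dx, collapse = ", "))
  i <- meta$diagnosis == "normal" & meta$cell_type != "normal_neuron"
  if (any(i)) {
    stop("diagnosis 'normal' requires cell_type 'normal_neuron' (spectrum ",
         meta$spectrum_id[i][1L], ")")
  }
  i <- meta$diagnosis == "FCD_IIa" & meta$cell_type != "dysmorphic_neuron"
  if (any(i)) {
    stop("diagnosis 'FCD_IIa' is associated only with dysmorphic neurons ",
         "(spectrum ", meta$spectrum_id[i][1L], ")")
  }
  invisible(meta)
}

#' Bundle spectra and metadata into a dataset
#'
#' @param spectra List of `raman_spectrum` objects.
#' @param meta Cell metadata data.frame (see [validate_cell_meta()]); must
#'   contain every `spectrum_id` present in `spectra`.
#' @param refs Optional `calibration_refs` object travelling with the data.
#' @return An object of class `raman_dataset` with elements `spectra`
#'   (named list keyed by spectrum_id), `meta`, and `refs`.
#' @export
raman_dataset <- function(spectra, meta, refs = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated spectrum_id in dataset: ", ids[duplicated(ids)][1L])
  }
  names(spectra) <- ids
  meta <- validate_cell_meta(meta)
  orphan <- setdiff(ids, meta$spectrum_id)
  if (length(orphan)) {
    stop("spectrum_id present in data but not in metadata: ",
         paste(utils::head(orphan, 3L), collapse = ", "))
  }
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(spectra = spectra, meta = meta, refs = refs),
            class = "raman_dataset")
}

#' @export
print.raman_dataset <- function(x, ...) {
  tab <- table(x$meta$diagnosis)
  cat(sprintf("<raman_dataset> %d spectra (%s); stage=%s\n",
              length(x$spectra),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$spectra[[1L]]$stage))
  invisible(x)
}

#' Run the stage-appropriate validation over every spectrum of a dataset
#'
#' @param ds A `raman_dataset`.
#' @return A list (JSON-serializable validation report) with per-spectrum
#'   status and a global `ok` flag.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "raman_dataset"))
  res <- lapply(ds$spectra, function(s) {
    err <- tryCatch({ validate_spectrum(s); NA_character_ },
                    error = function(e) conditionMessage(e))
    list(spectrum_id = s$spectrum_id, stage = s$stage,
         ok = is.na(err), error = if (is.na(err)) NULL else err)
  })
  list(n_spectra = length(res),
       ok = all(vapply(res, `[[`, logical(1), "ok")),
       spectra = unname(res))
}
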