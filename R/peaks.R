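#' Detect candidate peaks in an SNV spectrum
#'
#' Local maxima whose topographic prominence exceeds
#' `prominence_factor x noise`, where the noise level is the robust SD of
#' successive differences divided by sqrt(2) (`mad(diff(y))/sqrt(2)`).
#' Candidates closer than `min_separation` are pruned greedily in order of
#' decreasing prominence.
#'
#' @param s Spectrum of stage "snv".
#' @param prominence_factor Multiplier of the noise level (default 3).
#' @param min_separation Minimum candidate separation in cm^-1 (default 8).
#' @return data.frame with columns `position`, `index`, `height`,
#'   `prominence`, ordered by position.
#' @export
detect_peaks <- function(s, prominence_factor = 3, min_separation = 8) {
  if (s$stage != "snv") {
    stop("detect_peaks expects an SNV-normalized spectrum (stage 'snv')")
  }
  y <- s$intensity
  x <- s$wavenumber
  n <- length(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  dy <- diff(y)
  is_max <- which(dy[-length(dy)] > 0 & dy[-1L] <= 0) + 1L
  if (!length(is_max)) {
    return(data.frame(position = numeric(0), index = integer(0),
                      height = numeric(0), prominence = numeric(0)))
  }
  prominence <- vapply(is_max, function(p) {
    yp <- y[p]
    left <- if (p > 1L) {
      higher <- which(y[seq_len(p - 1L)] > yp)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:p])
    } else yp
    right <- if (p < n) {
      higher <- which(y[(p + 1L):n] > yp)
      hi <- if (length(higher)) p + min(higher) - 1L else n
      min(y[p:hi])
    } else yp
    yp - max(left, right)
  }, numeric(1))
  keep <- prominence >= prominence_factor * noise
  is_max <- is_max[keep]
  prominence <- prominence[keep]
  o <- order(prominence, decreasing = TRUE)
  chosen <- integer(0)
  for (p in is_max[o]) {
    if (!length(chosen) || all(abs(x[chosen] - x[p]) >= min_separation)) {
      chosen <- c(chosen, p)
    }
  }
  chosen <- sort(chosen)
  data.frame(position = x[chosen], index = chosen, height = y[chosen],
             prominence = prominence[match(chosen, is_max)])
}

# residual and Jacobian for one Gaussian band (FWHM parameterization)
# plus a local additive offset: f(x) = h exp(-4 ln2 (x-mu)^2 / w^2) + c
gauss_resid <- function(par, x, y) {
  g <- exp(-4 * log(2) * (x - par[2])^2 / par[3]^2)
  y - (par[1] * g + par[4])
}

gauss_jac <- function(par, x, y) {
  h <- par[1]; mu <- par[2]; w <- par[3]
  g <- exp(-4 * log(2) * (x - mu)^2 / w^2)
  d_h <- g
  d_mu <- h * g * 8 * log(2) * (x - mu) / w^2
  d_w <- h * g * 8 * log(2) * (x - mu)^2 / w^3
  -cbind(d_h, d_mu, d_w, rep(1, length(x)))
}

# FWHM start value from the half-maximum crossings around index i0
estimate_fwhm <- function(x, y, i0, floor_val, fwhm_range) {
  half <- floor_val + (y[i0] - floor_val) / 2
  li <- i0
  while (li > 1L && y[li] > half) li <- li - 1L
  ri <- i0
  while (ri < length(y) && y[ri] > half) ri <- ri + 1L
  w <- x[ri] - x[li]
  min(max(w, fwhm_range[1]), fwhm_range[2])
}

fit_one_gaussian <- function(x, y, candidate, position_tol, fwhm_range,
                             window_halfwidth, others = numeric(0)) {
  sel <- abs(x - candidate) <= window_halfwidth
  if (length(others)) {
    # territory masking: a bin belongs to the nearest candidate, so the
    # fit of one band is not contaminated by an overlapping neighbour
    d_own <- abs(x - candidate)
    d_other <- rep(Inf, length(x))
    for (o in others) d_other <- pmin(d_other, abs(x - o))
    sel <- sel & d_own <= d_other
  }
  xs <- x[sel]; ys <- y[sel]
  if (length(xs) < 5L) {  # widen degenerate windows to the plain cut
    sel <- abs(x - candidate) <= window_halfwidth
    xs <- x[sel]; ys <- y[sel]
  }
  i0 <- which.min(abs(xs - candidate))
  c0 <- min(ys)
  h0 <- max(ys[i0] - c0, 1e-6)
  w0 <- estimate_fwhm(xs, ys, i0, c0, fwhm_range)
  start <- c(h = h0, mu = candidate, w = w0, c = c0)
  lower <- c(0, candidate - position_tol, fwhm_range[1], -Inf)
  upper <- c(Inf, candidate + position_tol, fwhm_range[2], Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = gauss_resid, jac = gauss_jac, x = xs, y = ys,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4
  if (ok) {
    p <- fit$par
    data.frame(position = p[2], height = p[1], fwhm = p[3],
               rms = sqrt(mean(fit$fvec^2)), converged = TRUE)
  } else {
    # fallback: candidate position, local-max height, moment-based width
    wgt <- pmax(ys - c0, 0)
    width <- if (sum(wgt) > 0) {
      mu_m <- sum(xs * wgt) / sum(wgt)
      2.355 * sqrt(sum(wgt * (xs - mu_m)^2) / sum(wgt))
    } else w0
    data.frame(position = candidate, height = h0,
               fwhm = min(max(width, fwhm_range[1]), fwhm_range[2]),
               rms = NA_real_, converged = FALSE)
  }
}

#' Fit Gaussian line shapes at candidate peak positions
#'
#' For each candidate, a bounded Levenberg-Marquardt least-squares fit of
#' `h * exp(-4 ln2 (x - mu)^2 / w^2) + c` over a window of +/-15 cm^-1
#' around the candidate, with `h >= 0`, FWHM `w` in \[2, 60\] cm^-1, `mu`
#' within `position_tol` of the candidate, and a local additive offset `c`
#' absorbing the residual inter-peak level of the SNV spectrum. Within the
#' window, bins closer to another candidate than to this one are masked out,
#' so overlapping neighbours (e.g. the 1593/1602 cm^-1 doublet) do not pull
#' the fit. A non-converged fit falls back to the candidate position, the
#' local maximum height and a moment-based width, and is flagged.
#'
#' @param s Spectrum of stage "snv".
#' @param candidates Numeric candidate positions (cm^-1) or the data.frame
#'   returned by [detect_peaks()].
#' @param window_halfwidth Fit window half-width in cm^-1 (default 15).
#' @param position_tol Allowed deviation of `mu` from the candidate
#'   (default 5).
#' @param fwhm_range Bounds on the FWHM in cm^-1 (default `c(2, 60)`).
#' @return data.frame with one row per candidate: `position`, `height`,
#'   `fwhm`, `rms`, `converged`.
#' @export
fit_gaussian_peaks <- function(s, candidates, window_halfwidth = 15,
                               position_tol = 5, fwhm_range = c(2, 60)) {
  if (is.data.frame(candidates)) candidates <- candidates$position
  if (!length(candidates)) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      fwhm = numeric(0), rms = numeric(0),
                      converged = logical(0)))
  }
  if (any(candidates < min(s$wavenumber) | candidates > max(s$wavenumber))) {
    stop("candidate position outside the spectrum axis")
  }
  out <- lapply(seq_along(candidates), function(i) {
    fit_one_gaussian(s$wavenumber, s$intensity, candidates[i], position_tol,
                     fwhm_range, window_halfwidth,
                     others = candidates[-i])
  })
  do.call(rbind, out)
}

#' Build the dataset-wide consensus peak set
#'
#' Single-linkage clustering of all fitted peak positions with the linkage
#' cut at `tolerance` (for 1-D positions this is equivalent to splitting the
#' sorted positions at gaps larger than `tolerance`). Clusters detected in at
#' least `prevalence_threshold` of the spectra are retained; the consensus
#' position is the median of the cluster members.
#'
#' @param fits Named list (by spectrum_id) of per-spectrum fit tables from
#'   [fit_gaussian_peaks()].
#' @param tolerance Linkage cut in cm^-1 (default 5).
#' @param prevalence_threshold Minimum fraction of spectra in which a
#'   cluster must appear (default 0.8).
#' @return An object of class `consensus_peaks`: data.frame `peaks` with
#'   `position`, `prevalence`, `n_members`, plus the `tolerance` used.
#' @export
build_consensus <- function(fits, tolerance = 5, prevalence_threshold = 0.8) {
  if (length(fits) < 2L) stop("need fits from at least 2 spectra")
  ids <- names(fits)
  if (is.null(ids)) stop("fits must be a named list keyed by spectrum_id")
  pos <- unlist(lapply(fits, `[[`, "position"), use.names = FALSE)
  sid <- rep(ids, vapply(fits, nrow, integer(1)))
  o <- order(pos)
  pos <- pos[o]; sid <- sid[o]
  cluster <- cumsum(c(1, diff(pos) > tolerance))
  n_spec <- length(fits)
  rows <- lapply(split(seq_along(pos), cluster), function(ix) {
    data.frame(position = stats::median(pos[ix]),
               prevalence = length(unique(sid[ix])) / n_spec,
               n_members = length(ix))
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[peaks$prevalence >= prevalence_threshold, , drop = FALSE]
  if (!nrow(peaks)) stop("no peak cluster reaches the prevalence threshold")
  peaks <- peaks[order(peaks$position), ]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, tolerance = tolerance,
                 prevalence_threshold = prevalence_threshold,
                 n_spectra = n_spec),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat(sprintf(
    "<consensus_peaks> %d peaks (tolerance %.1f cm^-1, prevalence >= %.2f)\n",
    nrow(x$peaks), x$tolerance, x$prevalence_threshold))
  cat(" positions:", paste(round(x$peaks$position, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the per-spectrum feature matrix over the consensus peak set
#'
#' For every spectrum and consensus position, uses the spectrum's matched
#' peak fit (nearest fitted position within the consensus tolerance) or,
#' when the peak was not detected in that spectrum, runs a constrained refit
#' in a window fixed at the consensus position (height bounded at 0), so the
#' height feature stays on the intensity scale and the matrix has no gaps.
#' Columns are named `p<position>_position`, `p<position>_height`,
#' `p<position>_fwhm`.
#'
#' @param ds Processed `raman_dataset` (stage "snv").
#' @param consensus A `consensus_peaks` object.
#' @param fits Optional named list of per-spectrum fit tables (as passed to
#'   [build_consensus()]); missing entries are refit as needed.
#' @param window_halfwidth,fwhm_range Passed to the constrained refit.
#' @return data.frame with `spectrum_id`, `patient_id`, `diagnosis`,
#'   `cell_type`, then `3 x n_peaks` numeric feature columns; the consensus
#'   object is attached as attribute `consensus`.
#' @export
extract_features <- function(ds, consensus, fits = NULL,
                             window_halfwidth = 15, fwhm_range = c(2, 60)) {
  stopifnot(inherits(consensus, "consensus_peaks"))
  cpos <- consensus$peaks$position
  if (!length(cpos)) stop("empty consensus peak set")
  tol <- consensus$tolerance
  rows <- lapply(ds$spectra, function(s) {
    if (min(s$wavenumber) > min(cpos) || max(s$wavenumber) < max(cpos)) {
      stop(sprintf("spectrum '%s' does not cover all consensus positions",
                   s$spectrum_id))
    }
    f <- fits[[s$spectrum_id]]
    feat <- numeric(3L * length(cpos))
    for (k in seq_along(cpos)) {
      row <- NULL
      if (!is.null(f) && nrow(f)) {
        d <- abs(f$position - cpos[k])
        if (min(d) <= tol) row <- f[which.min(d), ]
      }
      if (is.null(row)) {
        row <- fit_one_gaussian(s$wavenumber, s$intensity, cpos[k],
                                position_tol = tol, fwhm_range = fwhm_range,
                                window_halfwidth = window_halfwidth,
                                others = cpos[-k])
      }
      feat[3L * (k - 1L) + 1:3] <- c(row$position, row$height, row$fwhm)
    }
    feat
  })
  mat <- do.call(rbind, rows)
  nm <- sprintf("p%d", round(cpos))
  colnames(mat) <- as.vector(t(outer(nm, c("position", "height", "fwhm"),
                                     paste, sep = "_")))
  meta_cols <- ds$meta[match(names(ds$spectra), ds$meta$spectrum_id),
                       c("spectrum_id", "patient_id", "diagnosis",
                         "cell_type")]
  out <- cbind(meta_cols, as.data.frame(mat))
  rownames(out) <- NULL
  attr(out, "consensus") <- consensus
  out
}

#' Detect and fit peaks for every spectrum of a dataset
#'
#' Convenience wrapper running [detect_peaks()] then [fit_gaussian_peaks()]
#' per spectrum.
#'
#' @param ds Processed `raman_dataset` (stage "snv").
#' @param prominence_factor,min_separation Passed to [detect_peaks()].
#' @param window_halfwidth,position_tol,fwhm_range Passed to
#'   [fit_gaussian_peaks()].
#' @return Named list (by spectrum_id) of fit tables.
#' @export
fit_dataset_peaks <- function(ds, prominence_factor = 3, min_separation = 8,
                              window_halfwidth = 15, position_tol = 5,
                              fwhm_range = c(2, 60)) {
  fits <- lapply(ds$spectra, function(s) {
    cand <- detect_peaks(s, prominence_factor, min_separation)
    fit_gaussian_peaks(s, cand, window_halfwidth, position_tol, fwhm_range)
  })
  names(fits) <- names(ds$spectra)
  fits
}

#' Feature-matrix helpers: numeric feature columns
#'
#' @param fm Feature matrix from [extract_features()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(fm) {
  grep("^p[0-9]+_(position|height|fwhm)$", names(fm), value = TRUE)
}
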