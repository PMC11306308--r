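# Continuum estimation and baseline handling.
#
# "Baseline" has two components here: a constant dark offset of the
# spectrometer (removed as the per-spectrum minimum) and the smooth plasma
# continuum (estimated by robust smoothing). The maximum of the estimated
# continuum is the "baseline peak" used as the normalization reference, so
# the whole chain is self-contained per spectrum and scale invariant.

# rolling mean; windows shrink symmetrically at the edges so sloped regions
# are not biased there
.rolling_mean <- function(y, k) {
  n <- length(y)
  if (k <= 1L || n < 3L) return(y)
  half <- k %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
}

#' Estimate the smooth continuum of an emission spectrum
#'
#' Repeated rolling-median smoothing (robust to narrow emission lines, which
#' occupy far less than half of any window) followed by a rolling-mean
#' polish. The window is specified in nm and converted to an odd number of
#' grid points.
#'
#' @param wavelength ascending wavelength grid (nm).
#' @param intensity intensity values (AU), same length.
#' @param window_nm smoothing window width (nm).
#' @param passes number of rolling-median passes.
#' @return numeric vector: the estimated continuum.
#' @export
estimate_continuum <- function(wavelength, intensity, window_nm = 20, passes = 3L) {
  .check_spectrum(wavelength, intensity)
  step <- stats::median(diff(wavelength))
  k <- max(3L, as.integer(round(window_nm / step)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(intensity) %% 2L == 1L) length(intensity)
            else length(intensity) - 1L)
  b <- intensity
  for (i in seq_len(passes)) b <- stats::runmed(b, k, endrule = "median")
  .rolling_mean(b, k)
}

.check_spectrum <- function(wavelength, intensity) {
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelength must be strictly ascending")
  invisible(TRUE)
}

#' Deduct the spectrometer baseline from a spectrum
#'
#' Two-step deduction: the per-spectrum minimum is removed as the dark
#' offset, then the estimated continuum (see [estimate_continuum()]) is
#' subtracted. The maximum of the estimated continuum is attached as the
#' `"reference"` attribute for [normalize_to_baseline_peak()]. The input is
#' not modified.
#'
#' @param spectrum list with `wavelength` and `intensity`.
#' @param window_nm,passes continuum-estimation parameters.
#' @return list with `wavelength`, `intensity` (baseline-deducted) and
#'   attribute `reference` (AU, the baseline-peak height).
#' @export
deduct_baseline <- function(spectrum, window_nm = 20, passes = 3L) {
  w <- spectrum$wavelength; y <- spectrum$intensity
  .check_spectrum(w, y)
  if (all(y == 0)) {
    warning("all-zero spectrum: baseline deduction is a no-op")
    out <- list(wavelength = w, intensity = y)
    attr(out, "reference") <- 0
    return(out)
  }
  y0 <- y - min(y)
  cont <- estimate_continuum(w, y0, window_nm = window_nm, passes = passes)
  out <- list(wavelength = w, intensity = y0 - cont)
  attr(out, "reference") <- max(cont)
  out
}

#' Normalize a spectrum to the baseline-peak intensity
#'
#' Divides every intensity by the reference scalar (by default the maximum of
#' the estimated continuum, carried as the `"reference"` attribute from
#' [deduct_baseline()]). Multiplying the raw spectrum by any positive
#' constant leaves the normalized output unchanged.
#'
#' @param spectrum list with `wavelength` and `intensity`.
#' @param reference positive scalar; defaults to the spectrum's `reference`
#'   attribute.
#' @return the normalized spectrum (same structure).
#' @export
normalize_to_baseline_peak <- function(spectrum, reference = attr(spectrum, "reference")) {
  if (is.null(reference) || !is.finite(reference) || reference <= 0)
    stop("unquantifiable spectrum: normalization reference must be positive")
  out <- list(wavelength = spectrum$wavelength,
              intensity = spectrum$intensity / reference)
  attr(out, "reference") <- 1
  out
}
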