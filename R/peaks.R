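#' Processing configuration for electrolyte quantification
#'
#' Fixes the emission lines (K at 765 and 770 nm; soluble Ca at 547, 596 and
#' 610 nm), the half-width of the integration window around each line, and
#' the continuum-estimation parameters. Windows of distinct lines must not
#' overlap (at the default half-width of 2 nm the adjacent K windows
#' 763--767 and 768--772 are disjoint).
#'
#' @param k_lines,ca_lines line centers (nm).
#' @param window_halfwidth integration half-width (nm).
#' @param baseline_window_nm,baseline_passes passed to [estimate_continuum()].
#' @return object of class `processing_config`.
#' @export
processing_config <- function(k_lines = c(765, 770),
                              ca_lines = c(547, 596, 610),
                              window_halfwidth = 2,
                              baseline_window_nm = 20,
                              baseline_passes = 3L) {
  if (window_halfwidth <= 0) stop("window_halfwidth must be positive")
  centers <- sort(c(k_lines, ca_lines))
  if (any(diff(centers) <= 2 * window_halfwidth))
    stop("integration windows of distinct lines overlap at halfwidth ",
         window_halfwidth, " nm")
  structure(list(k_lines = k_lines, ca_lines = ca_lines,
                 window_halfwidth = window_halfwidth,
                 baseline_window_nm = baseline_window_nm,
                 baseline_passes = as.integer(baseline_passes)),
            class = "processing_config")
}

#' Integrated peak area above a local linear background
#'
#' Trapezoidal integral, over the window `center +/- halfwidth`, of the
#' intensity minus the straight line through the window's two endpoints.
#' Negative results (pure-noise windows) are clipped to zero; the clip is
#' reported via the `"clipped"` attribute.
#'
#' @param spectrum list with `wavelength` and `intensity`.
#' @param center line center (nm).
#' @param halfwidth window half-width (nm).
#' @return scalar area (AU x nm) with logical attribute `clipped`.
#' @export
peak_area <- function(spectrum, center, halfwidth) {
  w <- spectrum$wavelength; y <- spectrum$intensity
  .check_spectrum(w, y)
  if (center - halfwidth < w[1] || center + halfwidth > w[length(w)])
    stop(sprintf("integration window for line %.4g nm lies outside the wavelength grid",
                 center))
  idx <- which(w >= center - halfwidth & w <= center + halfwidth)
  wx <- w[idx]; yx <- y[idx]
  n <- length(idx)
  # local linear background through the window endpoints
  bg <- yx[1] + (yx[n] - yx[1]) * (wx - wx[1]) / (wx[n] - wx[1])
  r <- yx - bg
  area <- sum(diff(wx) * (r[-n] + r[-1]) / 2)
  clipped <- area < 0
  structure(max(area, 0), clipped = clipped)
}

#' Electrolyte emission values of one processed spectrum
#'
#' Sums the windowed peak areas over the K lines and over the soluble-Ca
#' lines of a baseline-deducted, normalized spectrum, and forms the soluble
#' Ca/K ratio. A zero K emission leaves the ratio undefined (`NA`) and flags
#' the spectrum; it is retained for the K and Ca tables and excluded from
#' ratio analyses downstream.
#'
#' @param spectrum a processed spectrum (list with `wavelength`, `intensity`).
#' @param config a [processing_config()].
#' @return one-row `data.frame`: `k_emission`, `soluble_ca`, `ca_k_ratio`,
#'   `qc_flag` ("" or "undefined_ratio"), `n_clipped`.
#' @export
electrolyte_profile <- function(spectrum, config = processing_config()) {
  areas_k <- lapply(config$k_lines, function(c0)
    peak_area(spectrum, c0, config$window_halfwidth))
  areas_ca <- lapply(config$ca_lines, function(c0)
    peak_area(spectrum, c0, config$window_halfwidth))
  k <- sum(unlist(areas_k))
  ca <- sum(unlist(areas_ca))
  n_clipped <- sum(vapply(c(areas_k, areas_ca), attr, logical(1), "clipped"))
  if (k > 0) {
    ratio <- ca / k
    flag <- ""
  } else {
    ratio <- NA_real_
    flag <- "undefined_ratio"
  }
  data.frame(k_emission = k, soluble_ca = ca, ca_k_ratio = ratio,
             qc_flag = flag, n_clipped = n_clipped,
             stringsAsFactors = FALSE)
}

#' Run the full processing chain on one raw spectrum
#'
#' Baseline deduction, baseline-peak normalization, and electrolyte
#' quantification in one step. Spectra whose normalization reference is not
#' positive are returned with `qc_flag = "zero_reference"` and `NA` emissions.
#'
#' @inheritParams electrolyte_profile
#' @return one-row `data.frame` as in [electrolyte_profile()].
#' @export
process_spectrum <- function(spectrum, config = processing_config()) {
  ded <- suppressWarnings(deduct_baseline(spectrum,
                                          window_nm = config$baseline_window_nm,
                                          passes = config$baseline_passes))
  ref <- attr(ded, "reference")
  if (!is.finite(ref) || ref <= 0) {
    return(data.frame(k_emission = NA_real_, soluble_ca = NA_real_,
                      ca_k_ratio = NA_real_, qc_flag = "zero_reference",
                      n_clipped = 0L, stringsAsFactors = FALSE))
  }
  electrolyte_profile(normalize_to_baseline_peak(ded), config)
}

#' Process every spectrum of a cohort into an electrolyte profile table
#'
#' @param cohort a `libs_cohort` from [generate_cohort()], or any list with
#'   `wavelength`, a spectra matrix `spectra` (one column per spectrum) and a
#'   `spectrum_meta` data.frame (`spectrum_id`, `spot_id`, `shot_index`).
#' @param config a [processing_config()].
#' @return `data.frame` with one row per spectrum: ids plus the
#'   [electrolyte_profile()] columns.
#' @export
process_cohort <- function(cohort, config = processing_config()) {
  w <- cohort$wavelength
  meta <- cohort$spectrum_meta
  res <- vector("list", ncol(cohort$spectra))
  for (j in seq_len(ncol(cohort$spectra))) {
    res[[j]] <- process_spectrum(list(wavelength = w,
                                      intensity = cohort$spectra[, j]), config)
  }
  cbind(meta[, c("spectrum_id", "spot_id", "shot_index")],
        do.call(rbind, res))
}

#' Aggregate per-shot profiles of one laser-spot position
#'
#' Component-wise median of K and soluble Ca across the shots of one spot;
#' the ratio is recomputed from the aggregated values. Optional mode: the
#' default analysis unit is the single spectrum (no averaging was used when
#' recording), so this is only applied when per-position aggregation is
#' explicitly requested.
#'
#' @param profiles `data.frame` of profiles sharing one `spot_id`.
#' @return one-row `data.frame` with aggregated values.
#' @export
aggregate_position <- function(profiles) {
  if (nrow(profiles) == 0L) stop("aggregate_position: empty input")
  if (length(unique(profiles$spot_id)) != 1L)
    stop("aggregate_position: profiles must share one spot_id")
  k <- stats::median(profiles$k_emission, na.rm = TRUE)
  ca <- stats::median(profiles$soluble_ca, na.rm = TRUE)
  data.frame(spot_id = profiles$spot_id[1], shot_index = NA_integer_,
             k_emission = k, soluble_ca = ca,
             ca_k_ratio = if (k > 0) ca / k else NA_real_,
             qc_flag = if (k > 0) "" else "undefined_ratio",
             n_clipped = sum(profiles$n_clipped),
             stringsAsFactors = FALSE)
}
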