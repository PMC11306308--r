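# Shared fixtures built in code.

small_config <- function(n = 40L, seed = 11L, ...) {
  cohort_config(class_counts = c(tumor = n, very_close = n,
                                 close = n, clear = n),
                seed = seed, ...)
}

# a flat-continuum spectrum with optional Gaussian lines, for oracle tests
flat_spectrum <- function(lines = NULL, continuum = 0,
                          wavelength = seq(200, 900, by = 0.25)) {
  y <- rep(continuum, length(wavelength))
  if (!is.null(lines)) {
    for (i in seq_len(nrow(lines))) {
      s <- lines$fwhm[i] / (2 * sqrt(2 * log(2)))
      y <- y + lines$amplitude[i] *
        exp(-0.5 * ((wavelength - lines$center[i]) / s)^2)
    }
  }
  list(wavelength = wavelength, intensity = y)
}

# The full-size default cohort, generated and processed once per test run
# and shared by the heavier checks.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_results <- function() {
  if (is.null(.cohort_cache$res)) {
    cfg <- cohort_config()
    cohort <- generate_cohort(cfg)
    profiles <- process_cohort(cohort)
    tab <- analysis_table(cohort, profiles)
    cohort$spectra <- NULL  # free ~120 MB once profiled
    .cohort_cache$res <- list(cfg = cfg, cohort = cohort, tab = tab)
  }
  .cohort_cache$res
}
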