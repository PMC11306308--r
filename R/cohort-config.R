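#' Margin-distance classes, ordered from tumor outward
#'
#' Resection margin status is binned by the signed distance (mm) from the
#' histologically validated tumor border: the border and everything inside it
#' is `tumor`, < 1 mm is `very_close`, 1--5 mm is `close`, > 5 mm is `clear`.
#'
#' @export
margin_classes <- function() c("tumor", "very_close", "close", "clear")

# Median processed emission targets (AU) per class that the default generator
# is calibrated to recover: K, soluble Ca, and the soluble Ca/K ratio.
.default_median_targets <- function() {
  list(
    k        = c(tumor = 6.079, very_close = 0.587,  close = 0.463,  clear = 0.326),
    ca       = c(tumor = 3.968, very_close = 22.422, close = 21.044, clear = 21.153),
    ca_k     = c(tumor = 0.681, very_close = 37.070, close = 44.340, clear = 62.782)
  )
}

# Log-scale dispersion of the per-spectrum amplitude draws. sigma_k is fixed
# by requiring that a K threshold at 1.9505 AU detects tumor (median 6.079)
# with sensitivity 0.95: sigma = log(6.079/1.9505)/qnorm(0.95). sigma_ca is
# fixed analogously from the tumor-vs-very-close soluble-Ca AUC of 0.949:
# sigma = log(22.422/3.968)/(qnorm(0.949)*sqrt(2)).
.default_sigma <- function() {
  c(k  = log(6.079 / 1.9505) / stats::qnorm(0.95),
    ca = log(22.422 / 3.968) / (stats::qnorm(0.949) * sqrt(2)))
}

# HOES grade probabilities (grades 0..3) per class, stochastically ordered
# tumor > very_close > close > clear for both histological parameters.
.default_hoes_probs <- function() {
  list(
    neogenesis_fibrosis = list(
      tumor      = c(0.05, 0.10, 0.25, 0.60),
      very_close = c(0.15, 0.30, 0.35, 0.20),
      close      = c(0.40, 0.35, 0.15, 0.10),
      clear      = c(0.75, 0.18, 0.05, 0.02)
    ),
    lymphocyte_macrophage = list(
      tumor      = c(0.10, 0.20, 0.30, 0.40),
      very_close = c(0.25, 0.35, 0.25, 0.15),
      close      = c(0.45, 0.35, 0.15, 0.05),
      clear      = c(0.70, 0.22, 0.06, 0.02)
    )
  )
}

#' Build a synthetic LIBS cohort configuration
#'
#' Parameterizes the synthetic study: class sizes, emission-line placement and
#' per-class amplitude distributions, continuum shape, noise, measurement
#' grid, HOES grade probabilities, patient covariates, and the seed. Defaults
#' reproduce the study conditions: 1298 tumor, 336 very-close, 1092 close and
#' 2610 clear-margin spectra (5,336 in total) on a 1 mm grid with 240 um
#' laser spots and 30 shots per position, with per-class amplitude medians
#' calibrated so the processed electrolyte medians recover the study's
#' per-class values.
#'
#' @param class_counts named integer vector of spectra per margin class.
#' @param n_patients number of patients the spots are distributed over.
#' @param median_targets list with numeric vectors `k`, `ca` and `ca_k`
#'   giving the target processed median emission (AU) per class. Because the
#'   per-spectrum K and Ca values are independent lognormals, the ratio
#'   median is tied to the K and Ca medians; the generator splits any
#'   inconsistency among the three targets evenly on the log scale, so each
#'   is recovered within |log(ratio_target * k_target / ca_target)|/3
#'   (under 1.5% for the defaults).
#' @param sigma_log named vector `c(k=, ca=)` of log-scale standard deviations
#'   of the per-spectrum amplitude distributions.
#' @param wavelength_range,wavelength_step spectral grid (nm).
#' @param continuum list: `peak_wavelength`, `peak_amplitude` (AU, the
#'   baseline peak), `width` (nm), `offset` (dark offset, AU).
#' @param fwhm_nm full width at half maximum of every emission line (nm).
#' @param na_amplitude_median median raw amplitude (AU) of the Na distractor
#'   doublet at 589.0/589.6 nm; 0 disables it.
#' @param noise_sd additive Gaussian noise, raw AU per grid point.
#' @param grid_spacing_mm,spot_diameter_um,shots_per_position measurement
#'   geometry metadata.
#' @param hoes_probs list of two lists (`neogenesis_fibrosis`,
#'   `lymphocyte_macrophage`), each mapping class to a length-4 probability
#'   vector over grades 0--3.
#' @param covariates list: `age_mean`, `age_sd`, `age_range`, `p_female`,
#'   `g_status_probs` (probabilities of grades 1..3).
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(class_counts = c(tumor = 1298L, very_close = 336L,
                                           close = 1092L, clear = 2610L),
                          n_patients = 10L,
                          median_targets = .default_median_targets(),
                          sigma_log = .default_sigma(),
                          wavelength_range = c(200, 900),
                          wavelength_step = 0.25,
                          continuum = list(peak_wavelength = 360,
                                           peak_amplitude = 200,
                                           width = 130, offset = 20),
                          fwhm_nm = 0.7,
                          na_amplitude_median = 50,
                          noise_sd = 1.0,
                          grid_spacing_mm = 1,
                          spot_diameter_um = 240,
                          shots_per_position = 30L,
                          hoes_probs = .default_hoes_probs(),
                          covariates = list(age_mean = 65, age_sd = 10,
                                            age_range = c(30, 95),
                                            p_female = 0.5,
                                            g_status_probs = c(0.2, 0.6, 0.2)),
                          seed = 20240808L) {
  cfg <- list(
    class_counts = class_counts, n_patients = as.integer(n_patients),
    median_targets = median_targets, sigma_log = sigma_log,
    wavelength_range = wavelength_range, wavelength_step = wavelength_step,
    continuum = continuum, fwhm_nm = fwhm_nm,
    k_lines = c(765, 770), ca_lines = c(547, 596, 610),
    na_lines = c(589.0, 589.6),
    na_amplitude_median = na_amplitude_median,
    noise_sd = noise_sd,
    grid_spacing_mm = grid_spacing_mm,
    spot_diameter_um = spot_diameter_um,
    shots_per_position = as.integer(shots_per_position),
    hoes_probs = hoes_probs, covariates = covariates,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: positive counts, probability vectors
#' summing to one, positive line widths and grid spacing, amplitude medians
#' positive for every class.
#'
#' @param cfg a `cohort_config`.
#' @return `cfg`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  cls <- margin_classes()
  if (!setequal(names(cfg$class_counts), cls))
    stop("class_counts must be named with exactly: ", paste(cls, collapse = ", "))
  if (any(cfg$class_counts <= 0) || any(cfg$class_counts != round(cfg$class_counts)))
    stop("class_counts must be positive integers")
  if (cfg$n_patients <= 0) stop("n_patients must be positive")
  for (el in c("k", "ca", "ca_k")) {
    m <- cfg$median_targets[[el]]
    if (is.null(m) || !all(cls %in% names(m)))
      stop("median_targets$", el, " must cover every margin class")
    if (any(m <= 0))
      stop("median_targets$", el, ": amplitude distributions must have positive medians")
  }
  if (any(cfg$sigma_log <= 0)) stop("sigma_log must be positive")
  if (cfg$fwhm_nm <= 0) stop("fwhm_nm must be positive")
  if (cfg$wavelength_step <= 0) stop("wavelength_step must be positive")
  if (diff(cfg$wavelength_range) <= 0) stop("wavelength_range must be increasing")
  if (cfg$grid_spacing_mm <= 0) stop("grid_spacing_mm must be positive")
  if (cfg$shots_per_position <= 0) stop("shots_per_position must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  for (par in names(cfg$hoes_probs)) {
    for (cl in cls) {
      p <- cfg$hoes_probs[[par]][[cl]]
      if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("hoes_probs$", par, "$", cl,
             " must be 4 non-negative probabilities summing to 1")
    }
  }
  gp <- cfg$covariates$g_status_probs
  if (abs(sum(gp) - 1) > 1e-9 || any(gp < 0))
    stop("g_status_probs must sum to 1")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  spectra per class:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts), collapse = ", "),
      sprintf(" (total %d)\n", sum(x$class_counts)))
  cat(sprintf("  patients: %d | grid %.1f mm | spot %g um | %d shots/position\n",
              x$n_patients, x$grid_spacing_mm, x$spot_diameter_um,
              x$shots_per_position))
  cat(sprintf("  wavelengths: %g-%g nm @ %g nm | line FWHM %g nm | noise sd %g AU\n",
              x$wavelength_range[1], x$wavelength_range[2], x$wavelength_step,
              x$fwhm_nm, x$noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Wavelength grid of a configuration
#' @param cfg a `cohort_config`.
#' @return ascending numeric vector of wavelengths (nm).
#' @export
config_wavelength <- function(cfg) {
  seq(cfg$wavelength_range[1], cfg$wavelength_range[2], by = cfg$wavelength_step)
}
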