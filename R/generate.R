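# Synthetic LIBS cohort generation.
#
# Per-spectrum electrolyte targets are drawn from class-conditional lognormal
# distributions whose medians are the calibration targets; raw line
# amplitudes are obtained by inverting the processing pipeline (measuring its
# response to unit-amplitude lines on a noiseless spectrum), so the processed
# medians recover the targets by construction.

.gauss_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# deterministic per-stage seed derived from the master seed
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Continuum intensity of the synthetic instrument model
#'
#' A broad Gaussian bump (the plasma continuum, whose maximum is the
#' "baseline peak") on top of a constant dark offset.
#'
#' @param wavelength wavelengths (nm).
#' @param params list: `peak_wavelength`, `peak_amplitude`, `width`, `offset`.
#' @return numeric vector of continuum intensities (AU).
#' @export
continuum_intensity <- function(wavelength, params) {
  params$offset + params$peak_amplitude *
    exp(-0.5 * ((wavelength - params$peak_wavelength) / params$width)^2)
}

#' Generate one synthetic emission spectrum
#'
#' Intensity = continuum + sum of Gaussian lines (unit peak height times
#' amplitude) + additive Gaussian noise, clipped at zero.
#'
#' @param wavelength ascending wavelength grid (nm).
#' @param lines `data.frame` with columns `center` (nm), `amplitude` (AU),
#'   `fwhm` (nm); may have zero rows.
#' @param continuum_params see [continuum_intensity()].
#' @param noise_sd additive noise standard deviation (AU).
#' @return list with `wavelength` and `intensity`.
#' @export
generate_spectrum <- function(wavelength, lines, continuum_params, noise_sd = 0) {
  y <- continuum_intensity(wavelength, continuum_params)
  if (!is.null(lines) && nrow(lines) > 0) {
    if (any(lines$fwhm <= 0)) stop("line FWHM must be positive")
    for (i in seq_len(nrow(lines))) {
      s <- .gauss_sigma(lines$fwhm[i])
      y <- y + lines$amplitude[i] * exp(-0.5 * ((wavelength - lines$center[i]) / s)^2)
    }
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  list(wavelength = wavelength, intensity = pmax(y, 0))
}

# unit-amplitude line basis over the grid for a set of centers
.line_basis <- function(wavelength, centers, fwhm) {
  s <- .gauss_sigma(fwhm)
  rowSums(vapply(centers,
                 function(c0) exp(-0.5 * ((wavelength - c0) / s)^2),
                 numeric(length(wavelength))))
}

#' Processed-emission response of the pipeline to unit-amplitude lines
#'
#' Builds a noiseless spectrum holding the configured continuum plus the K
#' (or Ca) lines at unit amplitude each, runs the full processing chain, and
#' returns the resulting K and soluble-Ca emission per unit amplitude. The
#' generator divides its per-spectrum electrolyte targets by this response,
#' so the processing chain recovers the targets exactly in the noiseless
#' limit (the chain is linear in line amplitude: the continuum estimator is
#' an order statistic unaffected by the narrow lines).
#'
#' @param cfg a [cohort_config()].
#' @param pconfig a [processing_config()].
#' @return named numeric vector `c(k = , ca = )`.
#' @export
pipeline_response <- function(cfg, pconfig = processing_config()) {
  w <- config_wavelength(cfg)
  resp <- numeric(2); names(resp) <- c("k", "ca")
  for (el in c("k", "ca")) {
    centers <- if (el == "k") cfg$k_lines else cfg$ca_lines
    lines <- data.frame(center = centers, amplitude = 1, fwhm = cfg$fwhm_nm)
    sp <- generate_spectrum(w, lines, cfg$continuum, noise_sd = 0)
    prof <- process_spectrum(sp, pconfig)
    resp[el] <- if (el == "k") prof$k_emission else prof$soluble_ca
  }
  if (any(resp <= 0)) stop("degenerate pipeline response; check continuum/line config")
  resp
}

# Ratio of the noisy to the noiseless normalization reference, averaged over
# a few line-free replicate spectra (uses the current RNG stream).
.reference_noise_factor <- function(cfg, pconfig, reps = 8L) {
  if (cfg$noise_sd <= 0) return(1)
  w <- config_wavelength(cfg)
  cont <- continuum_intensity(w, cfg$continuum)
  ref0 <- attr(deduct_baseline(list(wavelength = w, intensity = cont),
                               window_nm = pconfig$baseline_window_nm,
                               passes = pconfig$baseline_passes), "reference")
  refs <- vapply(seq_len(reps), function(i) {
    y <- pmax(cont + stats::rnorm(length(w), 0, cfg$noise_sd), 0)
    attr(deduct_baseline(list(wavelength = w, intensity = y),
                         window_nm = pconfig$baseline_window_nm,
                         passes = pconfig$baseline_passes), "reference")
  }, numeric(1))
  mean(refs) / ref0
}

#' Draw HOES grades for spots of one margin class
#'
#' Grades 0--3 for the two histological parameters (bone neogenesis/fibrosis
#' and lymphocyte/macrophage infiltrates), drawn from the class-conditional
#' probability vectors, which are stochastically ordered from tumor to clear.
#'
#' @param margin_class one of [margin_classes()].
#' @param n number of spots.
#' @param hoes_probs as in [cohort_config()].
#' @return `data.frame` with columns `hoes_nf`, `hoes_lm`.
#' @export
simulate_hoes <- function(margin_class, n = 1L, hoes_probs = .default_hoes_probs()) {
  stopifnot(margin_class %in% margin_classes())
  draw <- function(p) sample(0:3, n, replace = TRUE, prob = p)
  data.frame(hoes_nf = draw(hoes_probs$neogenesis_fibrosis[[margin_class]]),
             hoes_lm = draw(hoes_probs$lymphocyte_macrophage[[margin_class]]))
}

.simulate_patients <- function(cfg) {
  cv <- cfg$covariates
  n <- cfg$n_patients
  age <- numeric(0)
  while (length(age) < n) {
    a <- stats::rnorm(n, cv$age_mean, cv$age_sd)
    age <- c(age, a[a > cv$age_range[1] & a < cv$age_range[2]])
  }
  data.frame(patient_id = seq_len(n),
             age = round(age[seq_len(n)], 1),
             gender = stats::rbinom(n, 1, cv$p_female),
             g_status = sample(seq_along(cv$g_status_probs), n,
                               replace = TRUE, prob = cv$g_status_probs))
}

# Low-discrepancy paired lognormal draws (randomly shifted Kronecker R2
# lattice). The empirical joint distribution of the pair concentrates on the
# product of the two lognormals at ~O(log n / n), so per-class sample
# medians of K, Ca AND their ratio all sit on the configured values far
# tighter than under iid sampling, while the two margins stay effectively
# independent. The lattice order is shuffled so spectrum order carries no
# structure.
.lattice_lognormal_pair <- function(n, meanlog1, sdlog1, meanlog2, sdlog2) {
  g <- 1.32471795724474602596  # plastic number; alphas 1/g, 1/g^2
  i <- seq_len(n)
  u <- (i / g + stats::runif(1)) %% 1
  v <- (i / g^2 + stats::runif(1)) %% 1
  ord <- sample.int(n)
  list(t1 = stats::qlnorm(u[ord], meanlog1, sdlog1),
       t2 = stats::qlnorm(v[ord], meanlog2, sdlog2))
}

.distance_bounds <- list(tumor = c(-5, 0), very_close = c(0, 1),
                         close = c(1, 5), clear = c(5, 10))

# uniform distances within a class bin; open bounds nudged inward so the
# binning invariant holds exactly
.draw_distances <- function(class, n) {
  b <- .distance_bounds[[class]]
  d <- stats::runif(n, b[1], b[2])
  switch(class,
         tumor = pmin(d, 0),
         very_close = pmin(pmax(d, 1e-6), 1 - 1e-6),
         close = pmin(pmax(d, 1), 5),
         clear = pmax(d, 5 + 1e-6))
}

#' Generate a complete synthetic LIBS cohort
#'
#' Produces patients, laser-spot records and raw spectra with exactly
#' `class_counts[c]` spectra per margin class. Spots are laid out on the
#' configured measurement grid per patient; distances to the tumor border
#' are drawn uniformly within each class's bin; HOES grades follow the
#' class-conditional probabilities. All randomness derives from
#' `cfg$seed`, so an identical configuration yields a byte-identical
#' dataset.
#'
#' @param cfg a [cohort_config()].
#' @param pconfig the [processing_config()] used to calibrate raw line
#'   amplitudes against the processing chain.
#' @return object of class `libs_cohort`: list with `config`, `wavelength`,
#'   `patients`, `spots` (one row per spot), `spectrum_meta` (one row per
#'   spectrum) and `spectra` (matrix, one column per spectrum).
#' @export
generate_cohort <- function(cfg = cohort_config(), pconfig = processing_config()) {
  validate_cohort_config(cfg)
  w <- config_wavelength(cfg)
  resp <- pipeline_response(cfg, pconfig)

  set.seed(.stage_seed(cfg$seed, "cohort"))
  patients <- .simulate_patients(cfg)

  classes <- margin_classes()
  n_total <- sum(cfg$class_counts)
  cls <- rep(classes, times = cfg$class_counts[classes])

  dist <- numeric(n_total)
  hoes <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    sel <- cls == classes[i]
    dist[sel] <- .draw_distances(classes[i], sum(sel))
    hoes[[i]] <- simulate_hoes(classes[i], sum(sel), cfg$hoes_probs)
  }
  hoes <- do.call(rbind, hoes)

  patient_id <- sample(rep_len(patients$patient_id, n_total))
  # row/column grid layout per patient at the configured spacing
  x_mm <- numeric(n_total); y_mm <- numeric(n_total)
  for (p in patients$patient_id) {
    sel <- which(patient_id == p)
    idx <- seq_along(sel) - 1L
    x_mm[sel] <- (idx %% 50L) * cfg$grid_spacing_mm
    y_mm[sel] <- (idx %/% 50L) * cfg$grid_spacing_mm
  }

  spots <- data.frame(spot_id = seq_len(n_total), patient_id = patient_id,
                      x_mm = x_mm, y_mm = y_mm,
                      distance_mm = dist,
                      margin_class = assign_margin_class(dist),
                      hoes_nf = hoes$hoes_nf, hoes_lm = hoes$hoes_lm)
  stopifnot(identical(spots$margin_class, cls))

  # Per-spectrum electrolyte targets (AU). With independent lognormal K and
  # Ca, median(Ca/K) = median(Ca)/median(K); the three per-class targets are
  # mutually inconsistent by a factor exp(delta), which is split evenly on
  # the log scale so each target is met within |delta|/3.
  mt <- cfg$median_targets
  delta <- log(mt$ca_k[cls] * mt$k[cls] / mt$ca[cls])
  mu_k <- log(mt$k[cls]) - delta / 3
  mu_ca <- log(mt$ca[cls]) + delta / 3
  t_k <- numeric(n_total); t_ca <- numeric(n_total)
  for (cl in classes) {
    sel <- cls == cl
    tt <- .lattice_lognormal_pair(sum(sel), mu_k[sel][1], cfg$sigma_log["k"],
                                  mu_ca[sel][1], cfg$sigma_log["ca"])
    t_k[sel] <- tt$t1
    t_ca[sel] <- tt$t2
  }
  # Noise raises the estimated continuum maximum (the normalization
  # reference) slightly above its noiseless value; measure that factor on
  # line-free noisy spectra and fold it into the amplitude calibration.
  ref_factor <- .reference_noise_factor(cfg, pconfig)
  a_k <- t_k * ref_factor / resp["k"]
  a_ca <- t_ca * ref_factor / resp["ca"]

  basis_k <- .line_basis(w, cfg$k_lines, cfg$fwhm_nm)
  basis_ca <- .line_basis(w, cfg$ca_lines, cfg$fwhm_nm)
  cont <- continuum_intensity(w, cfg$continuum)

  spectra <- outer(basis_k, a_k) + outer(basis_ca, a_ca)
  if (cfg$na_amplitude_median > 0) {
    basis_na <- .line_basis(w, cfg$na_lines, cfg$fwhm_nm)
    a_na <- exp(stats::rnorm(n_total, log(cfg$na_amplitude_median), 0.5))
    spectra <- spectra + outer(basis_na, a_na)
  }
  spectra <- spectra + cont
  if (cfg$noise_sd > 0)
    spectra <- spectra + matrix(stats::rnorm(length(spectra), 0, cfg$noise_sd),
                                nrow = nrow(spectra))
  spectra <- pmax(spectra, 0)
  colnames(spectra) <- sprintf("s%05d", seq_len(n_total))

  meta <- data.frame(spectrum_id = colnames(spectra),
                     spot_id = spots$spot_id,
                     shot_index = 1L)

  structure(list(config = cfg, wavelength = w, patients = patients,
                 spots = spots, spectrum_meta = meta, spectra = spectra),
            class = "libs_cohort")
}

#' @export
print.libs_cohort <- function(x, ...) {
  cat("<libs_cohort>\n")
  cat(sprintf("  %d spectra over %d spots, %d patients\n",
              ncol(x$spectra), nrow(x$spots), nrow(x$patients)))
  print(table(x$spots$margin_class)[margin_classes()])
  invisible(x)
}

#' Deterministic content checksum of a cohort (or any R object)
#'
#' MD5 of the canonical serialization (version 2, no serialization header
#' dependence on the running session). Used to verify that identical
#' configurations reproduce identical datasets.
#'
#' @param object any R object.
#' @return character MD5 digest.
#' @export
content_checksum <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(object, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
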