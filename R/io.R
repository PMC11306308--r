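# Plain-text persistence: wide spectra CSV, metadata CSV, JSON/YAML config
# snapshots and JSON rule sets. Every file starts with a versioned schema
# comment line.

.schema_header <- "# marginlibs schema v1"

.write_csv_with_header <- function(df, path) {
  writeLines(.schema_header, path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

.read_csv_with_header <- function(path) {
  as.data.frame(data.table::fread(path, skip = 1L, header = TRUE))
}

#' Combined spot/patient metadata table of a cohort
#'
#' @param cohort a `libs_cohort`.
#' @return `data.frame`: spot_id, patient_id, x_mm, y_mm, distance_mm,
#'   margin_class, hoes_nf, hoes_lm, age, gender, g_status.
#' @export
cohort_metadata <- function(cohort) {
  m <- merge(cohort$spots, cohort$patients, by = "patient_id", sort = FALSE)
  m <- m[order(m$spot_id), c("spot_id", "patient_id", "x_mm", "y_mm",
                             "distance_mm", "margin_class", "hoes_nf",
                             "hoes_lm", "age", "gender", "g_status")]
  rownames(m) <- NULL
  m
}

#' Analysis-ready profile table
#'
#' Joins the electrolyte profiles with the spot metadata (margin class,
#' distance, HOES grades and patient covariates).
#'
#' @param cohort a `libs_cohort`.
#' @param profiles result of [process_cohort()].
#' @return merged `data.frame`, one row per spectrum.
#' @export
analysis_table <- function(cohort, profiles) {
  merge(profiles, cohort_metadata(cohort), by = "spot_id", sort = FALSE)
}

#' Write a cohort to a directory of plain-text files
#'
#' `metadata.csv` (one row per spot), `spectrum_meta.csv`, `config.json`,
#' and optionally the wide `spectra.csv` (first column `wavelength_nm`, one
#' column per spectrum id; large for full-size cohorts).
#'
#' @param cohort a `libs_cohort`.
#' @param dir output directory (created if needed).
#' @param spectra write the wide spectra matrix too?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spectra = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv_with_header(cohort_metadata(cohort), file.path(dir, "metadata.csv"))
  .write_csv_with_header(cohort$spectrum_meta, file.path(dir, "spectrum_meta.csv"))
  write_config(cohort$config, file.path(dir, "config.json"))
  if (spectra) {
    wide <- data.table::data.table(wavelength_nm = cohort$wavelength)
    wide <- cbind(wide, data.table::as.data.table(cohort$spectra))
    .write_csv_with_header(wide, file.path(dir, "spectra.csv"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `libs_cohort` (without per-patient table split if spectra were
#'   not persisted, `spectra` is NULL).
#' @export
read_cohort <- function(dir) {
  meta <- .read_csv_with_header(file.path(dir, "metadata.csv"))
  smeta <- .read_csv_with_header(file.path(dir, "spectrum_meta.csv"))
  cfg <- read_config(file.path(dir, "config.json"))
  patients <- unique(meta[, c("patient_id", "age", "gender", "g_status")])
  patients <- patients[order(patients$patient_id), ]
  rownames(patients) <- NULL
  spots <- meta[, c("spot_id", "patient_id", "x_mm", "y_mm", "distance_mm",
                    "margin_class", "hoes_nf", "hoes_lm")]
  spectra <- NULL; wavelength <- NULL
  sp_path <- file.path(dir, "spectra.csv")
  if (file.exists(sp_path)) {
    wide <- data.table::fread(sp_path, skip = 1L, header = TRUE)
    wavelength <- wide$wavelength_nm
    spectra <- as.matrix(wide[, -1])
  }
  structure(list(config = cfg, wavelength = wavelength, patients = patients,
                 spots = spots, spectrum_meta = smeta, spectra = spectra),
            class = "libs_cohort")
}

#' Write / read a cohort configuration (JSON or YAML by extension)
#'
#' @param cfg a `cohort_config`.
#' @param path destination ending in `.json`, `.yaml` or `.yml`.
#' @return `path` / the restored `cohort_config`.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  # named atomic vectors serialize as bare arrays; keep the names as keys
  x$class_counts <- as.list(x$class_counts)
  x$sigma_log <- as.list(x$sigma_log)
  x$median_targets <- lapply(x$median_targets, as.list)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cohort_config(
    class_counts = unlist(x$class_counts)[margin_classes()],
    n_patients = x$n_patients,
    median_targets = lapply(x$median_targets, function(v) unlist(v)[margin_classes()]),
    sigma_log = unlist(x$sigma_log),
    wavelength_range = unlist(x$wavelength_range),
    wavelength_step = x$wavelength_step,
    continuum = x$continuum,
    fwhm_nm = x$fwhm_nm,
    na_amplitude_median = x$na_amplitude_median,
    noise_sd = x$noise_sd,
    grid_spacing_mm = x$grid_spacing_mm,
    spot_diameter_um = x$spot_diameter_um,
    shots_per_position = x$shots_per_position,
    hoes_probs = lapply(x$hoes_probs, function(p) lapply(p, unlist)),
    covariates = within(x$covariates, {
      age_range <- unlist(age_range)
      g_status_probs <- unlist(g_status_probs)
    }),
    seed = x$seed
  )
  cfg
}

#' Serialize / restore a margin rule set as JSON
#'
#' Rule sets can be stored and reapplied to new cohorts without refitting.
#'
#' @param rule_set a `margin_rule_set`.
#' @param path JSON destination.
#' @return `path` / the restored `margin_rule_set`.
#' @export
write_rule_set <- function(rule_set, path) {
  x <- list(scores = rule_set$scores,
            rules = lapply(rule_set$rules, function(tr)
              lapply(tr, function(r) unclass(r))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_set
#' @export
read_rule_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- lapply(x$rules, function(tr)
    lapply(tr, function(r) {
      r$ci <- unlist(r$ci)
      structure(r, class = "threshold_rule")
    }))
  structure(list(rules = rules, scores = x$scores), class = "margin_rule_set")
}
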