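# End-to-end orchestration: generate -> process -> stats -> classify, with
# a JSON run manifest (config snapshot, seed, stage checksums) so identical
# runs are verifiably identical.

#' Run the full margin-assessment pipeline
#'
#' Generates the synthetic cohort, processes the spectra into electrolyte
#' profiles, computes the group-comparison and logistic-regression reports,
#' fits the ROC/Youden rule set, produces per-spot margin calls, and writes
#' every stage artifact plus a manifest under `out_dir`. All randomness
#' derives from the single seed via per-stage substreams.
#'
#' @param cfg a [cohort_config()].
#' @param out_dir output directory.
#' @param seed optional override of `cfg$seed`.
#' @param pconfig a [processing_config()].
#' @param persist_spectra write the (large) wide spectra CSV?
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `profiles`, `table_data`, `electrolytes`, `hoes`, `transitions`,
#'   `rule_set`, `calls`, `manifest`).
#' @export
run_pipeline <- function(cfg = cohort_config(), out_dir, seed = NULL,
                         pconfig = processing_config(),
                         persist_spectra = FALSE) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_cohort_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(cfg, pconfig)
  write_cohort(cohort, file.path(out_dir, "cohort"), spectra = persist_spectra)

  profiles <- process_cohort(cohort, pconfig)
  tab <- analysis_table(cohort, profiles)
  .write_csv_with_header(profiles, file.path(out_dir, "profiles.csv"))

  electrolytes <- electrolyte_comparison(tab, tab$margin_class)
  hoes <- hoes_comparison(cohort$spots)
  transitions <- transition_report(tab)
  .write_csv_with_header(comparison_report(electrolytes),
                         file.path(out_dir, "electrolyte_summary.csv"))
  .write_csv_with_header(comparison_report(hoes),
                         file.path(out_dir, "hoes_summary.csv"))
  .write_csv_with_header(transitions, file.path(out_dir, "transition_models.csv"))

  rule_set <- build_rule_set(tab)
  write_rule_set(rule_set, file.path(out_dir, "rule_set.json"))
  .write_csv_with_header(rule_set_report(rule_set),
                         file.path(out_dir, "roc_summary.csv"))

  calls <- classify_margin(tab, rule_set)
  calls$true_class <- tab$margin_class
  .write_csv_with_header(calls, file.path(out_dir, "margin_calls.csv"))

  files <- c("cohort/metadata.csv", "cohort/spectrum_meta.csv",
             "cohort/config.json", "profiles.csv",
             "electrolyte_summary.csv", "hoes_summary.csv",
             "transition_models.csv", "rule_set.json", "roc_summary.csv",
             "margin_calls.csv")
  if (persist_spectra) files <- c(files, "cohort/spectra.csv")
  checksums <- vapply(files, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("marginlibs")),
    seed = cfg$seed,
    n_spectra = ncol(cohort$spectra),
    timestamp = format(Sys.time(), tz = "UTC"),
    stage_checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, profiles = profiles, table_data = tab,
                 electrolytes = electrolytes, hoes = hoes,
                 transitions = transitions, rule_set = rule_set,
                 calls = calls, manifest = manifest))
}
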