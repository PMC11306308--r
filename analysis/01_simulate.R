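#!/usr/bin/env Rscript
# Stage 1: generate the full-size synthetic LIBS cohort.
#
# 5,336 spectra over four margin-distance classes (1298 tumor / 336 very
# close / 1092 close / 2610 clear) from 10 patients on a 1 mm measurement
# grid. Writes the spot/patient metadata and the config snapshot; the
# spectra themselves are regenerated deterministically from the snapshot by
# later stages instead of being persisted (the wide matrix is ~120 MB as
# CSV).

suppressPackageStartupMessages(library(marginlibs))

seed <- if (length(a <- commandArgs(TRUE)) >= 1) as.integer(a[1]) else 20240808L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, file.path(out, "cohort"), spectra = FALSE)

cat("Generated", ncol(cohort$spectra), "spectra:\n")
print(table(cohort$spots$margin_class)[margin_classes()])
cat("HOES median grades by class (neogenesis/fibrosis):\n")
print(tapply(cohort$spots$hoes_nf, cohort$spots$margin_class, median)[margin_classes()])
cat("Cohort metadata written to", file.path(out, "cohort"), "\n")
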