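#!/usr/bin/env Rscript
# Stage 4: diagnostic thresholds and margin-status prediction.
#
# ROC analysis with DeLong CIs for each margin transition x score,
# Youden-optimal threshold rules, and the cascaded four-class margin
# classifier applied back to the cohort.

suppressPackageStartupMessages(library(marginlibs))

out <- "results/analysis"
cohort <- read_cohort(file.path(out, "cohort"))
profiles <- marginlibs:::.read_csv_with_header(file.path(out, "profiles.csv"))
tab <- analysis_table(cohort, profiles)

rs <- build_rule_set(tab)
write_rule_set(rs, file.path(out, "rule_set.json"))
rep_tab <- rule_set_report(rs)
marginlibs:::.write_csv_with_header(rep_tab, file.path(out, "roc_summary.csv"))
cat("ROC/Youden rules per transition:\n")
print(rep_tab, row.names = FALSE, digits = 4)

calls <- classify_margin(tab, rs)
calls$true_class <- tab$margin_class
marginlibs:::.write_csv_with_header(calls, file.path(out, "margin_calls.csv"))
cm <- table(true = calls$true_class, predicted = calls$predicted)
cat("\nCascade confusion matrix (rows = true class):\n")
print(cm)
cat(sprintf("\nTumor recall %.3f | overall accuracy %.3f\n",
            cm["tumor", "tumor"] / sum(cm["tumor", ]),
            sum(diag(cm[margin_classes(), margin_classes()])) / sum(cm)))
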