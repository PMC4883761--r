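#!/usr/bin/env Rscript
# Data preparation on the simulated cohort: outlier trimming at the 1%/99%
# quantiles with mean imputation, a "missing" category for nominal features,
# outcome-conditional log-ratio encoding of the surgeon identifier, and
# prefix-tree aggregation of procedure codes with the threshold chosen by
# grid search. Writes the cleaning report, the encoder map, and the code
# grouping.

library(postoprisk)

cohort <- read_cohort("results", name = "cohort")

cl <- clean_cohort(cohort)
cat("cleaning: imputed", sum(cl$report$imputed), "entries;",
    sum(cl$report$outliers_flagged), "outliers flagged\n")
write_cleaning_report(cl$report, "results/cleaning_report.json")

y <- cl$cohort$outcomes$aki
enc <- fit_encoder(cl$cohort$features$surgeon, y, min_count = 100,
                   n_clusters = 5, seed = 1)
n_groups <- length(unique(enc$group))
cat("surgeon encoding:", length(enc$score), "levels ->", n_groups,
    "scored groups\n")
write_encoding_map(enc, "results/surgeon_encoding.json")

codes <- cl$cohort$features$proc_code
gs <- grid_search_min_count(codes, y, candidates = c(50, 100, 150, 250, 500),
                            seed = 1)
cat("grid search over aggregation thresholds (held-out univariate AUC):\n")
print(round(gs$auc, 4))
cat("chosen min_count:", gs$min_count, "\n")
grouping <- aggregate_codes(build_prefix_tree(codes), gs$min_count)
cat("procedure codes:", length(unique(codes)), "levels ->",
    nrow(grouping$groups), "groups\n")
write_code_grouping(grouping, "results/code_grouping.json")
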