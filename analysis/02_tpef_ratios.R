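#!/usr/bin/env Rscript
# TPEF autofluorescence ratios: per-region 755-860 and Col-Cal ratio means
# per animal, and the diet-by-week comparisons per region. The expectation
# under the generative model: pro-calcific week-16 commissures show a
# depressed 755-860 ratio.

library(valveoptics)

study <- readRDS("results/study.rds")
tab <- study_table(study)
write.csv(tab, "results/metrics_long.csv", row.names = FALSE)

for (metric in c("mean_ratio_755_860", "mean_ratio_col_cal")) {
  cat("\n==", metric, "==\n")
  for (region in c("leaflet", "commissure", "root")) {
    cmp <- compare_groups(tab, metric, region)
    cat("\n--", region, "(", cmp$test_used, ")\n")
    print(cmp$factors, row.names = FALSE)
    hit <- grepl("pro_calcific:16", cmp$contrasts$contrast) &
      grepl("control:16", cmp$contrasts$contrast)
    print(cmp$contrasts[hit, ], row.names = FALSE)
  }
}
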