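#!/usr/bin/env Rscript
# Histological quantification: ARS percent-positive calcified area by
# constant-threshold particle analysis (expected to ramp with week in the
# pro-calcific arm) and PSR fiber-thickness composition by hue binning.

library(valveoptics)

study <- readRDS("results/study.rds")
tab <- read.csv("results/metrics_long.csv")

ars <- tab[tab$metric == "ars_percent_area", ]
cat("Mean ARS percent-positive area by diet and week (commissures):\n")
com <- ars[ars$region == "commissure", ]
print(round(tapply(com$value, list(com$diet, com$week), mean), 2))

cmp <- compare_groups(tab, "ars_percent_area", "commissure")
cat("\nCommissure ARS comparison (", cmp$test_used, "):\n")
print(cmp$factors, row.names = FALSE)

psr <- tab[grepl("^pct_", tab$metric), ]
cat("\nPSR thickness-bin composition (mean % per region):\n")
print(round(tapply(psr$value, list(psr$region, psr$metric), mean), 1))

write.csv(ars, "results/ars_percent_area.csv", row.names = FALSE)
write.csv(psr, "results/psr_composition.csv", row.names = FALSE)
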