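#!/usr/bin/env Rscript
# Echocardiographic function (Teichholz volumes, EF, CO) from the study's
# M-mode measurements, and immunohistochemistry rater-score aggregation
# into -/+/++/+++ grades.

library(valveoptics)

study <- readRDS("results/study.rds")

ed <- echo_derive(study$echo_table$lvidd_mm, study$echo_table$lvids_mm,
                  study$echo_table$hr_bpm)
echo <- cbind(study$echo_table[c("animal", "diet", "week")],
              round(ed[c("edv", "esv", "ef", "co")], 2))
write.csv(echo, "results/echo_derived.csv", row.names = FALSE)
cat("Mean EF (%) by diet and week:\n")
print(round(tapply(echo$ef, list(echo$diet, echo$week), mean), 1))

st <- study$score_table
grades <- do.call(rbind, lapply(split(st, list(st$animal, st$marker), drop = TRUE),
  function(d) {
    ag <- aggregate_scores(d$score)
    data.frame(animal = d$animal[1], diet = d$diet[1], week = d$week[1],
               marker = d$marker[1], mean_score = round(ag$mean, 3),
               grade = as.character(ag$grade))
  }))
rownames(grades) <- NULL
write.csv(grades, "results/ihc_grades.csv", row.names = FALSE)
cat("\nRUNX2 grade distribution by diet at week 16:\n")
r16 <- grades[grades$marker == "RUNX2" & grades$week == 16, ]
print(table(r16$diet, r16$grade))
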