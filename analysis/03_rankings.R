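#!/usr/bin/env Rscript
# Multi-criteria scenario assessment: rank the nine scenarios by mean PM
# absorption, final Shannon diversity, joint improvement over the baseline,
# and winter absorption (the last from seasonal-mode runs). Also shows how
# the joint criterion depends on the intensive ratio and the turnover
# scheduling.

suppressPackageStartupMessages(library(treedyn))
dir.create("results", showWarnings = FALSE)

params <- reference_species()
flat <- run_scenarios(reference_scenarios(0.7, mode = "flat"), params)
seas <- run_scenarios(reference_scenarios(0.7, mode = "seasonal"), params)

rr <- rank_scenarios(flat$summaries)
rr$winter <- rank_scenarios(seas$summaries)$winter  # winter axis from seasonal runs
print(rr)

report <- data.frame(rank = seq_len(9),
                     pm = rr$pm,
                     diversity = rr$diversity,
                     both = c(rr$both, rep("", 9 - length(rr$both))),
                     winter = rr$winter)
write.csv(report, "results/ranking_report_r70.csv", row.names = FALSE,
          quote = FALSE)

cat("\nSensitivity of the joint (both-improved) criterion:\n")
for (r in c(0.7, 0.9)) {
  both <- rank_scenarios(run_scenarios(reference_scenarios(r), params)$summaries)$both
  cat(sprintf("  first-order turnover, r = %.1f: %s\n", r,
              paste(both, collapse = ", ")))
}
coh <- run_scenarios(reference_scenarios(0.7,
                                         settings = turnover_settings(scheme = "cohort")),
                     params)
cat(sprintf("  cohort turnover,      r = 0.7: %s\n",
            paste(rank_scenarios(coh$summaries)$both, collapse = ", ")))
cat("\nAt r = 0.7 with first-order turnover, Plant_more_Pinus joins
Plant_more_Mix on the joint criterion: 1.5 turnover time-constants leave its
diversity gain (a fourth abundant species) still above the baseline. Faster
conversion (r = 0.9, or cohort scheduling) leaves Plant_more_Mix alone.\n")
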