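#!/usr/bin/env Rscript
# Seasonal (leaf-phenology-aware) runs of the nine scenarios: deciduous
# species absorb only during the April-November leaf-on window (1-month
# ramps), the evergreen Pinus keeps 60% of its plateau through winter.
# Reports winter (Dec-Feb) mean absorption per scenario.

suppressPackageStartupMessages(library(treedyn))

dir.create("results", showWarnings = FALSE)
res <- run_scenarios(reference_scenarios(0.7, mode = "seasonal"),
                     reference_species(), profile = seasonal_profile())
write_summaries(res$summaries, "results/summaries_seasonal_r70.csv")

sm <- res$summaries[order(-res$summaries$winter_mean_mpa_g), ]
cat("Winter (Dec-Feb) mean PM absorption, seasonal mode, r = 0.7:\n")
print(sm[c("name", "winter_mean_mpa_g", "mean_mpa_g")], digits = 4,
      row.names = FALSE)
cat(sprintf("\nBest winter absorber: %s (%.0f g/month).\n",
            sm$name[1], sm$winter_mean_mpa_g[1]))
cat("Annual totals are unchanged by seasonality: each species' twelve monthly\n")
cat("absorptions sum to its annual rate, so seasonal and flat modes agree on\n")
cat("whole-year sums.\n")
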