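#!/usr/bin/env Rscript
# Synthetic drug screen: control plus three compounds with planted
# effects (a responder-probability blocker, a decay-slowing compound,
# and a no-effect compound), measured over three experimental days,
# normalized to the same-day control, and compared with nonparametric
# tests.

library(touchtrace)
dir.create("results", showWarnings = FALSE)
set.seed(7)

records <- simulate_screen(
  effects = list(blocker = list(respond_prob = 0.05),
                 slowpoke = list(tau_decay_mult = 2),
                 dud = list()),
  n_per_group = 25, days = 3)
report <- screen_report(records)

write.csv(report$summary, "results/05_screen_summary.csv", row.names = FALSE)
write.csv(report$kruskal, "results/05_screen_kruskal.csv", row.names = FALSE)
write.csv(report$pairwise, "results/05_screen_pairwise.csv",
          row.names = FALSE)
write.csv(report$normalized, "results/05_screen_records.csv",
          row.names = FALSE)

cat("Response fractions:\n")
print(report$summary[, c("compound", "n", "response_fraction")])
cat("\nKruskal-Wallis across groups per metric:\n")
print(report$kruskal)
cat("\nCompounds flagged as affecting mechanosensory dynamics (any\n",
    "pairwise Mann-Whitney vs control with p < 0.05):\n")
print(report$affected)
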