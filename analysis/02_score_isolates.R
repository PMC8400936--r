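#!/usr/bin/env Rscript
# Stage 2: rank the simulated isolates by standard score and select the
# screening winners. Each of the nine assay variables is min-max
# normalized to [0, 1] and the standard score is their equal-weight sum,
# so an isolate near 1 performs near-optimally on every assay at once.
# Writes results/scores.csv and prints the selection.

suppressPackageStartupMessages(library(micpkin))

pan <- read_assay_panel("results/data/assay_panel.csv")
res <- standard_score(pan)
write_score_result(res, "results/scores.csv")

top <- select_top(res, n = 5)
message("top 5 isolates by standard score:")
for (id in top)
  message(sprintf("  %-8s SS = %.3f", id, res$scores[id]))
message(sprintf("score range across panel: %.3f - %.3f",
                min(res$scores), max(res$scores)))
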