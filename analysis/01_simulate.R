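#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Two data sets are produced under results/data/:
#   - an assay panel of 43 isolates plus planted high-performers, emulating
#     the screening stage in which a handful of isolates excel on all nine
#     MICP assays;
#   - trajectory bundles for the seven strain profiles (noiseless, for
#     parameter-recovery checks, and with modest measurement noise, for the
#     goodness-of-fit analysis), at the hourly ureolysis-phase schedule and
#     the daily MICP-phase schedule.

suppressPackageStartupMessages(library(micpkin))
seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pan <- simulate_assay_panel(n_isolates = 43, n_top = 5, seed = seed)
write.csv(data.frame(isolate_id = pan$isolate_ids, pan$raw,
                     check.names = FALSE),
          file.path(out, "assay_panel.csv"), row.names = FALSE)
message("wrote assay panel: ", nrow(pan$raw), " isolates x ",
        ncol(pan$raw), " assays")

noiseless <- synthetic_config(seed = seed)
write_fixture_bundle(noiseless, file.path(out, "noiseless"))
message("wrote noiseless trajectory bundle (7 strains x 5 variables)")

# measurement noise: 0.3 g/L urea, 0.05 pH units, 0.1 log CFU/mL,
# 0.01 g precipitate, 20 mg/L calcium
noisy <- synthetic_config(noise = c(urea_gL = 0.3, pH = 0.05,
                                    log_cells = 0.1, precipitate_g = 0.01,
                                    calcium_mgL = 20),
                          seed = seed)
write_fixture_bundle(noisy, file.path(out, "noisy"))
message("wrote noisy trajectory bundle")
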