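#!/usr/bin/env Rscript

# Stage 6: how often does the AICc comparison detect the caniniform
# dimorphism at the study's sample size, and how often does it cry
# dimorphism on a matched unimodal population?

suppressPackageStartupMessages(library(dimorph))

seed <- 1L
reps <- 300L
sizes <- c(8L, 16L, 28L, 50L)

rows <- lapply(sizes, function(n) {
  pw <- power_experiment(n_per_dataset = n, n_reps = reps, seed = seed)
  tibble::tibble(n = n, n_reps = reps,
                 detection_rate = pw$win_dimorphic,
                 false_detection_rate = pw$win_monomorphic)
})
res <- dplyr::bind_rows(rows)
readr::write_csv(res, "results/power.csv")

cat("Bimodal-AICc win rates under the published caniniform mixture\n")
cat("(detection) and a moment-matched single normal (false detection):\n\n")
print(as.data.frame(res), row.names = FALSE)
cat("\nWritten to results/power.csv\n")
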