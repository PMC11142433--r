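#!/usr/bin/env Rscript

# Stage 5: within-morph and pooled associations between maxilla lengths
# (adjusted R^2 headline, raw R^2 beside it, two-sided slope p), using
# the stage-3 morph assignments.

suppressPackageStartupMessages(library(dimorph))

tab <- read_measurements("results/population.csv")
asg <- readr::read_csv("results/morph_assignments.csv",
                       show_col_types = FALSE)
morphs <- asg[, c("specimen_id", "label")]

pairs <- list(c("jcp_DV", "jpp_ML"), c("jcp_DV", "jpm_AP"),
              c("ttc", "jcp_DV"), c("ad", "jcp_DV"))
res <- dplyr::bind_rows(lapply(pairs, function(p) {
  r <- group_associations(tab, "maxilla", p[1], p[2], morphs)
  r$code_x <- p[1]; r$code_y <- p[2]
  r
}))
res <- res[, c("code_x", "code_y", "group", "n", "available", "slope",
               "r2_raw", "r2_adjusted", "p_value")]
readr::write_csv(res, "results/allometry.csv")

cat("Within-morph and pooled log-log regressions (maxilla):\n\n")
print(as.data.frame(res), digits = 3, row.names = FALSE)
cat("\nWritten to results/allometry.csv\n")
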