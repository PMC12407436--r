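#!/usr/bin/env Rscript
# Juvenile growth and fate analysis for the 2x2 factorial: absolute growth
# rates (um/day), two-way ANOVA with Tukey HSD, and per-factor tests of
# each fate category.

suppressPackageStartupMessages(library(thermopt))

records <- read_table("results/data/growth.csv", "growth")
message("fates: ", paste(names(table(records$fate)), table(records$fate),
                         sep = "=", collapse = ", "))

res <- factorial_growth_anova(records, metric = "abs")
message(res$n_excluded, " bona fide mortality record(s) excluded from growth")
print(res$cell_means, digits = 3)
print(res$table, digits = 3)
write.csv(res$table, "results/growth_anova.csv", row.names = FALSE)
write.csv(res$cell_means, "results/growth_cell_means.csv", row.names = FALSE)
write.csv(res$tukey, "results/growth_tukey.csv", row.names = FALSE)

fates <- do.call(rbind, lapply(c("MIA", "high_and_dry", "mortality"),
                               function(f) {
  ft <- fate_tests(records, f,
                   factors = c("juvenile_temp", "larval_temp", "box_side",
                               "chamber_position"))
  ft$fate <- f
  ft
}))
print(fates[!fates$skipped, c("fate", "factor", "F", "p", "fisher_p")],
      digits = 3)
write.csv(fates, "results/fate_tests.csv", row.names = FALSE)
message("wrote results/growth_anova.csv, results/fate_tests.csv")
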