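#!/usr/bin/env Rscript
# Stage 6: qPCR relative quantification over the osteogenic time course.
# Computes 2^-ddCt trajectories for the target gene and the planted
# inhibitory miRNA, tests each timepoint against day 0, and correlates the
# two trajectories (expected: negative, the miRNA mirrors the target).

library(runx2reg)
dir.create("results", showWarnings = FALSE)

ct <- read_ct_csv("results/fixtures/ct_table.csv")

rq_target <- delta_delta_ct(ct, "RUNX2", "ACTB")
print(rq_target)
tests <- timepoint_tests(rq_target, "vs_calibrator")
cat("per-timepoint tests vs day 0:\n")
print(tests, row.names = FALSE, digits = 3)
utils::write.table(cbind(rq_target$summary,
                         stars = c("", tests$stars)),
                   "results/expression_target.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rq_mir <- delta_delta_ct(ct, "miR-3150a-3p", "cel-miR-39-3p")
corr <- trajectory_correlation(rq_target, rq_mir)
cat("target vs miRNA trajectory: ")
print(corr)
utils::write.table(rq_mir$summary, "results/expression_mirna.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(r = corr$r, p = corr$p, n = corr$n,
       stars = significance_stars(corr$p)),
  "results/trajectory_correlation.json", auto_unbox = TRUE, digits = NA)
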