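#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# Everything downstream consumes the fixture directory written here: a
# 2-kb locus allele pair (10 planted substitutions), a 50x quality-weighted
# pileup, a region map mirroring the locus layout (promoters, UTRs,
# exons/introns, two antisense lncRNAs), UTR alleles differing by one base
# that completes an 8mer seed site, a five-concentration SPR titration of
# a KD = 1 uM binder with 1 RU noise, and a five-replicate qPCR table with
# target-up / miRNA-down trajectories.

library(runx2reg)

fixture_dir <- "results/fixtures"
truth <- simulate_fixture_dir(fixture_dir, sim_config(seed = 20260101 %% 99999L))

cat("fixture directory:", fixture_dir, "\n")
cat("planted substitutions:", nrow(truth$variants), "at positions",
    paste(truth$variants$position, collapse = ", "), "\n")
cat("planted seed-site core at UTR position", truth$seed_site$core_start,
    "(completed by the change at", paste0(truth$seed_site$changed_position, ")"), "\n")
cat("planted SPR parameters: kon =", truth$spr$kon, "1/(M*s), koff =",
    truth$spr$koff, "1/s, KD =", truth$spr$KD * 1e6, "uM\n")
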