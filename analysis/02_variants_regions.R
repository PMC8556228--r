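#!/usr/bin/env Rscript
# Stage 2: call derived variants from the quality-weighted pileup with the
# strict >79% rule, compare the packaged probe alleles directly, attribute
# calls to locus regions, and polarize an example site against primate
# outgroups.

library(runx2reg)

dir.create("results", showWarnings = FALSE)

## direct allele comparison: the two fixed distal 3'UTR changes
probes <- runx2_probe_alleles()
pd <- diff_sequences(probes[["AMH"]], probes[["archaic"]])
cat("distal 3'UTR probe alleles differ at", nrow(pd), "positions:",
    paste(sprintf("%d (%s/%s)", pd$position, pd$base_a, pd$base_b),
          collapse = ", "), "\n")

## pileup calling on the synthetic locus
pu <- read_pileup_tsv("results/fixtures/pileup.tsv")
calls <- call_variants(pu, threshold = 0.79)
truth <- jsonlite::read_json("results/fixtures/truth.json",
                             simplifyVector = TRUE)
cat("called", nrow(calls), "variants;",
    sum(calls$position %in% truth$variants$position), "of",
    nrow(truth$variants), "planted sites recovered\n")
write_variants_tsv(calls, "results/variant_calls.tsv")
write_variants_vcf(calls, "results/variant_calls.vcf")

## region attribution
map <- read_region_bed("results/fixtures/regions.bed")
ann <- annotate_variants(calls, map)
cat("variant counts by category (overlaps counted in every category):\n")
print(ann$counts[ann$counts > 0])
utils::write.table(ann$table, "results/region_annotation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## lineage polarization of an AMH-specific-style site
lc <- classify_lineage(c(AMH = "T", Neandertal = "C", Denisovan = "C",
                         chimp = "C", gorilla = "C", orangutan = "C",
                         gibbon = "C", macaque = "C"))
cat("example site with archaic allele conserved across five primates:",
    lc$class, "\n")
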