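#!/usr/bin/env Rscript
# Stage 4: miRNA seed-site analysis of the UTR alleles. Scans the fixture
# UTR pair (one base apart) with the miRNA panel and reports which sites
# the derived allele gained or lost, then checks which changed positions
# fall inside seed-matched spans.

library(runx2reg)
dir.create("results", showWarnings = FALSE)

utrs <- read_alleles_fasta("results/fixtures/utr_alleles.fa")
panel <- read_mirna_tsv("results/fixtures/mirna_panel.tsv")

d <- diff_sites(utrs[["utr_ref"]], utrs[["utr_alt"]], panel)
print(d)
cat("changed UTR position(s):", paste(d$changed_positions, collapse = ", "),
    "\n")
if (nrow(d$gained)) {
  cat("gained sites:\n")
  print(d$gained, row.names = FALSE)
  write_sites(d$gained, "results/sites_gained.tsv", "tsv")
  write_sites(d$gained, "results/sites_gained.bed", "bed",
              utr_name = "utr_alt")
  inside <- variant_in_seed_region(d$changed_positions[1], d$gained)
  cat("variant inside the seed-matched span of the gained site:",
      inside, "\n")
}

## the packaged probe alleles under the shipped panel: the spike-in control
## has no site in either 36-nt probe, and placeholder rows are skipped
probes <- runx2_probe_alleles()
pd <- diff_sites(probes[["archaic"]], probes[["AMH"]],
                 read_mirna_tsv(system.file("extdata", "mirna_panel.tsv",
                                            package = "runx2reg")))
cat("probe alleles, shipped panel:", nrow(pd$gained), "gained,",
    nrow(pd$lost), "lost (mature sequences are user-supplied for all",
    "panel members except the spike-in control)\n")
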