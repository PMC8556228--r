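#!/usr/bin/env Rscript
# Stage 7: one-shot pipeline run. Re-executes every stage through the
# orchestrator against the fixture directory and writes the combined
# report; the section values equal the standalone stage outputs above.

library(runx2reg)

rep <- run_pipeline(run_config("results/fixtures",
                               out_dir = "results/report"))
cat(readLines("results/report/report.md"), sep = "\n")
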