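#!/usr/bin/env Rscript
# Somatic burden per exome, recurrently mutated genes, enrichment of the
# recurrent set in a planted annotation panel, and the binned CNV
# recurrence track.

library(intgen)

cfg <- study_config(seed = 20260101)
sim <- sim_config(seed = cfg$seed)
run_pipeline("results/bundle", c("burden", "cnv_tracks"), cfg, sim)

bd <- read.delim("results/bundle/burden.tsv", comment.char = "#")
cat(sprintf("burden: %d somatic variants over %d tumors -> %.1f per exome\n",
            sum(bd$n_variants), nrow(bd), sum(bd$n_variants) / nrow(bd)))

rec <- read.delim("results/bundle/recurrent_genes.tsv", comment.char = "#")
truth <- jsonlite::fromJSON("results/bundle/truth.json")
cat(sprintf("recurrent genes (>= 2 tumors): %s (planted: %s)\n",
            paste(rec$gene, collapse = ", "),
            paste(sort(unlist(truth$recurrent_genes)), collapse = ", ")))

tr <- read.delim("results/bundle/cnv_tracks.tsv", comment.char = "#")
peak <- function(cl) {
  i <- which.max(tr[[cl]])
  sprintf("%s @ %s:%d-%d (%.0f%% of samples)", cl, tr$chrom[i],
          tr$start[i], tr$end[i], 100 * tr[[cl]][i])
}
cat("CNV recurrence peaks:\n")
for (cl in c("gain", "loss", "cnLOH")) cat(" ", peak(cl), "\n")
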