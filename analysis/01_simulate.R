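#!/usr/bin/env Rscript
# Generate the synthetic study bundle: a two-group (tumor vs control)
# negative-binomial expression matrix with planted DE genes and
# co-expression modules, exon-bin counts with planted usage shifts,
# reference-biased allele counts with planted imbalanced loci, mark
# signatures coupled to DE direction, and variant/CNV tables with planted
# recurrence. Downstream scripts consume results/bundle/.

library(intgen)

cfg <- study_config(seed = 20260101)
sim <- sim_config(seed = cfg$seed)
run_pipeline("results/bundle", "simulate", cfg, sim)

truth <- jsonlite::read_json("results/bundle/truth.json")
cat("bundle written to results/bundle/\n")
cat(sprintf("  %d genes, %d planted DE, %d module genes, %d ASE signal loci\n",
            sim$n_genes, length(truth$de_genes),
            sum(unlist(truth$module_assignment) > 0),
            length(truth$ase_signal_loci)))
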