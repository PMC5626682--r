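#!/usr/bin/env Rscript
# Signed co-expression network: module detection on log-CPM, module
# eigengenes, module-membership p-values and hub ranking by intramodular
# connectivity. Reports agreement with the planted module structure.

library(intgen)

cfg <- study_config(seed = 20260101)
sim <- sim_config(seed = cfg$seed)
run_pipeline("results/bundle", "network", cfg, sim)
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

mods <- read.delim("results/bundle/modules.tsv", comment.char = "#")
truth <- jsonlite::fromJSON("results/bundle/truth.json")
sizes <- table(mods$module[mods$module > 0])
cat(sprintf("network: %d modules (sizes %s), %d unassigned genes\n",
            length(sizes), paste(sizes, collapse = ", "),
            sum(mods$module == 0)))
tl <- unlist(truth$module_assignment)[mods$gene]
for (m in sort(unique(tl[tl > 0]))) {
  det <- mods$module[tl == m]
  top <- names(sort(table(det[det > 0]), decreasing = TRUE))[1]
  cat(sprintf("  planted module %d -> detected module %s (%.0f%% of genes)\n",
              m, top %||% "none",
              100 * mean(det == as.integer(top %||% "-1"))))
}
hub <- read.delim("results/bundle/hub_genes.tsv", comment.char = "#")
cat("top hub genes:", paste(head(hub$gene, 5), collapse = ", "), "\n")
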