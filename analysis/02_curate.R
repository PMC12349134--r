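#!/usr/bin/env Rscript
# Curate the raw phenome table: event retention, missingness pruning,
# near-constant filtering, indicator encoding, imputation, and robust
# z-scoring with winsorization. Writes the curated matrix and a report that
# accounts for every input variable exactly once.

suppressPackageStartupMessages(library(phenostrat))

raw <- read_phenome("results/cohort/phenome_raw.tsv",
                    "results/cohort/phenome_meta.tsv")
out <- curate(raw, curation_config())

dir.create("results/curated", showWarnings = FALSE, recursive = TRUE)
write_phenome(out$table,
              "results/curated/phenome_curated.tsv",
              "results/curated/phenome_curated_meta.tsv")
jsonlite::write_json(
  list(dropped_events = out$report$dropped_events,
       dropped_missingness = out$report$dropped_missingness,
       dropped_near_constant = out$report$dropped_near_constant,
       encoded = out$report$encoded,
       winsorized_counts = as.list(out$report$winsorized_counts),
       retained_events = out$report$retained_events),
  "results/curated/curation_report.json", auto_unbox = TRUE, digits = 6)

print(out$report)
print(out$table)
cat(sprintf("%d raw variables -> %d curated columns\n",
            nrow(raw$meta), ncol(out$table$values)))
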