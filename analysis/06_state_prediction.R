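#!/usr/bin/env Rscript
# Validate the multidimensional socioeconomic signal: predict each
# participant's state of residence from socioeconomic-only component scores
# with one-vs-rest ridge logistic regression under stratified 10-fold
# cross-validation, and compare against a label-permutation null.

suppressPackageStartupMessages(library(phenostrat))

table <- read_phenome("results/curated/phenome_curated.tsv",
                      "results/curated/phenome_curated_meta.tsv")
cm <- readRDS("results/components/components.rds")
ses_components <- readRDS("results/profiles/ses_components.rds")
dir.create("results/state_prediction", showWarnings = FALSE, recursive = TRUE)

scores <- ses_component_scores(table, cm$loadings, cm$mask, ses_components)
result <- predict_state(scores, table$state, n_folds = 10, seed = 303L)

conf <- data.table::as.data.table(as.matrix(result$confusion), keep.rownames = "true_state")
data.table::fwrite(conf, "results/state_prediction/confusion.tsv",
                   sep = "\t", quote = FALSE)
coefs <- data.table::as.data.table(result$coefficients, keep.rownames = "state")
data.table::fwrite(coefs, "results/state_prediction/coefficients.tsv",
                   sep = "\t", quote = FALSE)
data.table::fwrite(most_influential_component(result),
                   "results/state_prediction/top_component_per_state.tsv",
                   sep = "\t", quote = FALSE)

# evaluated density curves of per-state score distributions (plot-ready)
dens <- data.table::rbindlist(lapply(names(result$densities), function(s) {
  data.table::rbindlist(lapply(seq_along(result$densities[[s]]), function(j) {
    d <- result$densities[[s]][[j]]
    data.table::data.table(state = s, component = colnames(scores)[j],
                           x = d$x, y = d$y)
  }))
}))
data.table::fwrite(dens, "results/state_prediction/score_densities.tsv",
                   sep = "\t", quote = FALSE)

nulls <- permutation_null_accuracy(scores, table$state, n_folds = 10,
                                   n_permutations = 20, seed = 404L)
jsonlite::write_json(
  list(overall_accuracy_pct = result$overall_accuracy,
       chance_level_pct = result$chance_level,
       n_states_above_chance = sum(result$above_chance),
       n_states = length(result$above_chance),
       permutation_null_mean = mean(nulls),
       permutation_null_sd = stats::sd(nulls)),
  "results/state_prediction/summary.json", auto_unbox = TRUE, digits = 4)

print(result)
cat(sprintf("permutation null: %.2f%% +/- %.2f%%\n", mean(nulls), sd(nulls)))
print(most_influential_component(result), row.names = FALSE, digits = 3)
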