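#!/usr/bin/env Rscript
# Characterise the leading components: mean weight strength and retained
# proportion per predefined category, and the overlap structure of retained
# socioeconomic measures across the four most SES-centric components.

suppressPackageStartupMessages(library(phenostrat))

table <- read_phenome("results/curated/phenome_curated.tsv",
                      "results/curated/phenome_curated_meta.tsv")
cm <- readRDS("results/components/components.rds")
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

lets <- component_letters(cm$ranking, n = max(4, cm$ranking$elbow_cut))
profile <- category_profile(cm$loadings, cm$mask, table$meta,
                            components = lets,
                            categories = unique(table$meta$category))
profile$letter <- names(lets)[match(profile$component, lets)]
data.table::fwrite(profile, "results/profiles/category_profile.tsv",
                   sep = "\t", quote = FALSE)

# the four components with the strongest socioeconomic signature
ses <- profile[profile$category == "Socioeconomic", ]
ses <- ses[order(-ses$mean_weight_strength), ]
cat("Socioeconomic signature of the leading components:\n")
print(ses[, c("letter", "mean_weight_strength", "retained_count",
              "retained_proportion")], row.names = FALSE, digits = 3)
ses_components <- lets[match(ses$letter[1:4], names(lets))]

overlap <- ses_overlap(cm$mask, table$meta, ses_components)
jsonlite::write_json(
  list(components = as.list(ses_components),
       sets = overlap$sets, intersections = overlap$intersections,
       unique = overlap$unique),
  "results/profiles/ses_overlap.json", auto_unbox = TRUE)
saveRDS(ses_components, "results/profiles/ses_components.rds")

print(overlap)
for (letter in names(ses_components)) {
  top <- top_phenotype_table(cm$loadings, cm$mask, ses_components[[letter]],
                             table$meta)
  data.table::fwrite(top, sprintf("results/profiles/top_phenotypes_%s.tsv", letter),
                     sep = "\t", quote = FALSE)
}
all4 <- overlap$intersections[[paste(names(ses_components), collapse = "&")]]
cat(sprintf("measures retained in all four SES-centric components: %d\n", all4))
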