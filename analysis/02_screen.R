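#!/usr/bin/env Rscript
# Stage 1-2 of the screen: merge the herb inventories, attach targets, and
# intersect with the disease gene sets to obtain active compounds and
# potential targets.

library(herbnetscreen)

bundle <- read_bundle("results/bundle")
merged <- merge_and_deduplicate(bundle$compound_tables)
compound_targets <- attach_targets(merged, bundle$interactions)
active <- map_to_diseases(compound_targets, bundle$disease_sets, merged)

s <- stage_summary(active, merged)
readr::write_tsv(s, "results/stage_summary.tsv")
jsonlite::write_json(
  list(active_compounds = active$active_compounds,
       potential_targets = active$potential_targets,
       target_to_diseases = active$target_to_diseases,
       per_herb_targets = active$per_herb_targets),
  "results/active_set.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)

cat("stage summary (results/stage_summary.tsv):\n")
print.data.frame(as.data.frame(s), row.names = FALSE)
val <- function(m) s$value[s$metric == m]
cat(sprintf("\ninclusion-exclusion check: %g + %g - %g = %g pooled targets\n",
            val("targets_fuzi"), val("targets_rougui"),
            val("common_targets"), val("pooled_targets")))
cat(sprintf("%g of %g compounds hit a disease-mapped target and are active\n",
            val("active_compounds"), val("merged_compounds")))
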