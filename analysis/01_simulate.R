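#!/usr/bin/env Rscript
# Generate the synthetic database bundle the rest of the analysis consumes.
#
# The generator stands in for the live compound/target/disease/PPI databases:
# two herb inventories (65 + 100 compounds, 2 shared), a heavy-tailed
# compound-target map over a 500-gene universe, five overlapping disease gene
# sets, twenty pathway annotation sets (a quarter enriched for the
# disease-mapped targets), and a uniformly scored sparse PPI graph.

library(herbnetscreen)

seed <- 2026L
out <- "results/bundle"

bundle <- generate_bundle(sim_config(seed = seed))
write_bundle(bundle, out)

cat("bundle written to", out, "\n")
for (h in names(bundle$compound_tables)) {
  cat(sprintf("  %-8s %3d compounds\n", h, nrow(bundle$compound_tables[[h]])))
}
cat(sprintf("  %d compound-target interactions over %d distinct targets\n",
            nrow(bundle$interactions),
            length(unique(bundle$interactions$target_symbol))))
cat(sprintf("  %d disease sets, %d pathway sets, %d scored PPI edges\n",
            nrow(bundle$disease_sets), nrow(bundle$pathway_sets),
            nrow(bundle$ppi_edges)))
cat(sprintf("  ground truth: %d active compounds, %d potential targets\n",
            length(bundle$truth$active_compounds),
            length(bundle$truth$potential_targets)))
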