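#!/usr/bin/env Rscript
# Build the three screening networks, compute degree / betweenness /
# closeness centralities, and apply the threshold rules: triple-above-average
# key compounds, degree-above-mean hub genes, and key pathways.

library(herbnetscreen)

bundle <- read_bundle("results/bundle")
merged <- merge_and_deduplicate(bundle$compound_tables)
compound_targets <- attach_targets(merged, bundle$interactions)
active <- map_to_diseases(compound_targets, bundle$disease_sets, merged)
selected <- as.character(jsonlite::read_json(
  "results/selected_pathways.json", simplifyVector = TRUE)$selected_pathways)

nets <- list(
  ctd = build_ctd(active, compound_targets),
  tp = build_tp(active$potential_targets, bundle$pathway_sets, selected),
  ppi = build_ppi(bundle$ppi_edges, active$potential_targets, threshold = 0.4)
)
cen <- list()
for (nm in names(nets)) {
  write_network(nets[[nm]], file.path("results", paste0(nm, ".graphml")), "graphml")
  write_network(nets[[nm]], file.path("results", paste0(nm, ".sif")), "sif")
  cen[[nm]] <- compute_centralities(nets[[nm]])
  readr::write_tsv(cen[[nm]], file.path("results", paste0("centrality_", nm, ".tsv")))
  cat(sprintf("%-4s %4d nodes %5d edges\n", nm,
              igraph::vcount(nets[[nm]]), igraph::ecount(nets[[nm]])))
}

key_compounds <- screen_key_compounds(cen$ctd)
hub_genes <- select_hub_nodes(cen$ppi)
key_pathways <- if (any(cen$tp$role == "pathway")) {
  select_key_pathways(cen$tp)
} else character()

thr <- role_averages(cen$ctd, "compound")
cat(sprintf("\ncompound averages: DC %.4f, BC %.4f, CC %.4f\n",
            thr$mean_DC, thr$mean_BC, thr$mean_CC))
cat(sprintf("%d key compounds exceed all three averages (truth: %d actives)\n",
            nrow(key_compounds), length(bundle$truth$active_compounds)))
cat(sprintf("%d hub genes exceed the PPI mean degree\n", nrow(hub_genes)))
cat(sprintf("%d key pathways under the centrality rule\n", length(key_pathways)))

jsonlite::write_json(
  list(thresholds = thr,
       key_compounds = key_compounds$node_id,
       hub_genes = hub_genes$node_id,
       key_pathways = key_pathways),
  "results/screening.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
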