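#' Worked-example pathway gene sets for the rougui-fuzi screen
#'
#' The three curated CCVD pathway gene lists used throughout the package's
#' worked example: complement and coagulation cascades (7 genes), arachidonic
#' acid metabolism (5 genes), and the PI3K-Akt signaling pathway (6 genes).
#' Together they cover the 16 proteins submitted to the PPI stage of the
#' example.
#'
#' @return A gene-set collection of category `"PATHWAY"`.
#' @export
reference_pathway_gene_sets <- function() {
  gene_set_collection(
    set_id = c("complement and coagulation cascades",
               "arachidonic acid metabolism",
               "PI3K-Akt signaling pathway"),
    description = c("coagulation and complement cascade genes",
                    "arachidonic acid metabolic enzymes",
                    "PI3K-Akt signaling genes"),
    category = rep("PATHWAY", 3L),
    members = list(
      c("F10", "F3", "F2", "SERPINE1", "F7", "PLG", "PLAU"),
      c("PTGS2", "PTGS1", "PLA2G2A", "LTA4H", "ALOX5"),
      c("IFNB1", "IL4", "INS", "PTEN", "RXRA", "TLR4")
    )
  )
}

#' Worked-example key-compound centrality table
#'
#' The 21 rougui-fuzi compounds whose degree, betweenness, and closeness
#' centralities all exceeded the compound-node averages of the
#' compound-target-disease network in the worked example (averages
#' DC 2.7619, BC 0.0068, CC 0.3464). Values are the 4-decimal display form.
#'
#' @return A centrality tibble (`node_id`, `name`, `role`, `DC`, `BC`, `CC`).
#' @export
reference_key_compounds <- function() {
  tbl <- tibble::tribble(
    ~node_id,    ~name,                                        ~DC, ~BC,    ~CC,
    "MOL000675", "Oleic acid",                                 17L, 0.1394, 0.4577,
    "MOL002526", "delta-Guaijene",                              8L, 0.0242, 0.3040,
    "MOL000911", "Terpilene",                                   8L, 0.0248, 0.3916,
    "MOL000126", "(-)-Nopinene",                                6L, 0.0398, 0.4362,
    "MOL000069", "Palmitic acid",                               6L, 0.0332, 0.3779,
    "MOL000118", "(L)-Alpha-terpineol",                         5L, 0.0119, 0.3892,
    "MOL000254", "Eugenol",                                     5L, 0.0297, 0.4305,
    "MOL003521", "Isohomogenol",                                5L, 0.0083, 0.3869,
    "MOL000677", "(1R,4R)-4-Isopropyl-1,6-dimethyltetralin",    5L, 0.0067, 0.3916,
    "MOL002392", "Deltoin",                                     5L, 0.0093, 0.3916,
    "MOL002417", "Fuzitine",                                    5L, 0.0086, 0.3801,
    "MOL000431", "Coumarin",                                    5L, 0.0127, 0.3757,
    "MOL003525", "Pyruvophenone",                               5L, 0.0253, 0.3631,
    "MOL000198", "(R)-Linalool",                                4L, 0.0075, 0.3736,
    "MOL000131", "Linoleic acid",                               4L, 0.0181, 0.4140,
    "MOL001393", "Myristic acid",                               4L, 0.0146, 0.3693,
    "MOL000932", "Alpha-farnesene",                             4L, 0.0121, 0.3652,
    "MOL000991", "Cinnamaldehyde",                              4L, 0.0121, 0.3652,
    "MOL002295", "Cinnamic acid",                               3L, 0.0141, 0.4037,
    "MOL000249", "Methylcinnamate",                             3L, 0.0141, 0.4037,
    "MOL003531", "3-Methoxycinnamaldehyde",                     3L, 0.0141, 0.4037
  )
  tibble(node_id = tbl$node_id, name = tbl$name, role = "compound",
         DC = tbl$DC, BC = tbl$BC, CC = tbl$CC)
}

#' Worked-example pathway centrality table
#'
#' Centralities of the seven CCVD-relevant pathways in the worked example's
#' target-pathway network (role averages: DC 5.1429, BC 0.3818, CC 0.2141).
#'
#' @return A centrality tibble (`node_id`, `role`, `DC`, `BC`, `CC`).
#' @export
reference_pathway_centralities <- function() {
  tbl <- tibble::tribble(
    ~node_id,                                ~DC, ~BC,    ~CC,
    "complement and coagulation cascades",    7L, 0.5017, 0.2381,
    "Neuroactive ligand-receptor interaction", 6L, 0.2193, 0.1795,
    "PI3K-Akt signaling pathway",             6L, 0.5513, 0.2518,
    "Arachidonic acid metabolism",            5L, 0.2185, 0.2000,
    "Cholesterol metabolism",                 4L, 0.1664, 0.1515,
    "PPAR signaling pathway",                 4L, 0.3479, 0.1977,
    "NF-kappa B signaling pathway",           4L, 0.6673, 0.2800
  )
  tibble(node_id = tbl$node_id, role = "pathway",
         DC = tbl$DC, BC = tbl$BC, CC = tbl$CC)
}

#' Worked-example hub-gene centrality table
#'
#' The eight proteins of the worked example's 18-node PPI network whose
#' degree strictly exceeded the network's mean degree.
#'
#' @return A centrality tibble (`node_id`, `role`, `DC`, `BC`, `CC`).
#' @export
reference_hub_genes <- function() {
  tbl <- tibble::tribble(
    ~node_id,   ~DC, ~BC,    ~CC,
    "PTGS2",    14L, 0.2411, 0.8500,
    "INS",      12L, 0.1764, 0.7727,
    "IL4",      11L, 0.0701, 0.7391,
    "TLR4",     11L, 0.0734, 0.7391,
    "F3",       10L, 0.0361, 0.7083,
    "PLG",      10L, 0.0361, 0.7083,
    "SERPINE1", 10L, 0.0361, 0.7083,
    "F2",        9L, 0.0275, 0.6800
  )
  tibble(node_id = tbl$node_id, role = "protein",
         DC = tbl$DC, BC = tbl$BC, CC = tbl$CC)
}

#' Stage counts of the worked example
#'
#' The count chain the worked example reports: 165 candidate compounds (65 +
#' 100) merging to 163 after removing 2 duplicates; 84 active compounds, 42
#' potential targets and 5 disease sets giving a 131-node, 293-edge
#' compound-target-disease network; a 36-node, 41-edge target-pathway
#' network over 29 annotated targets and 7 pathways; and an 18-node, 67-edge
#' PPI network over the 16 key-pathway proteins.
#'
#' @return A named list of integer counts.
#' @export
reference_counts <- function() {
  list(candidate_compounds = 165L, merged_compounds = 163L,
       active_compounds = 84L, potential_targets = 42L, disease_sets = 5L,
       ctd_nodes = 131L, ctd_edges = 293L,
       tp_nodes = 36L, tp_edges = 41L,
       ppi_input_targets = 16L, ppi_nodes = 18L, ppi_edges = 67L)
}

#' Write the worked-example fixture files to a directory
#'
#' Emits the three-pathway GMT, the three centrality tables as TSV, and the
#' stage-count manifest as JSON, so downstream tools (and tests) can consume
#' the worked example through the ordinary readers.
#'
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
emit_reference_fixture <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gmt = file.path(outdir, "reference_pathways.gmt"),
    key_compounds = file.path(outdir, "reference_key_compounds.tsv"),
    pathways = file.path(outdir, "reference_pathway_centralities.tsv"),
    hub_genes = file.path(outdir, "reference_hub_genes.tsv"),
    manifest = file.path(outdir, "reference_counts.json")
  )
  write_gmt(reference_pathway_gene_sets(), paths[["gmt"]])
  write_tsv_plain(reference_key_compounds(), paths[["key_compounds"]])
  write_tsv_plain(reference_pathway_centralities(), paths[["pathways"]])
  write_tsv_plain(reference_hub_genes(), paths[["hub_genes"]])
  write_json_stable(reference_counts(), paths[["manifest"]])
  invisible(paths)
}
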