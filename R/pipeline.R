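#' Build a pipeline configuration
#'
#' One structured object carries every setting of an end-to-end run. Exactly
#' one input mode must be present: `simulate` (a [sim_config()], inputs are
#' generated) or `inputs` (paths to existing tables). Defaults carry the
#' screening settings of the worked example: enrichment alpha 0.05, GO term
#' limits 30/30/25, PPI confidence threshold 0.4, strict above-average
#' screening rules.
#'
#' @param simulate optional [sim_config()].
#' @param inputs optional named list of paths: `compounds` (character vector
#'   of per-herb TSVs), `interactions`, `diseases_gmt`, `pathways_gmt`,
#'   `ppi_edges`, and optionally `symbol_map`.
#' @param enrichment list: `alpha`, `filter_on`, `min_size`, `max_size`,
#'   `limits` (named per-category term caps), `exclude` (set ids dropped from
#'   pathway selection on curator judgment).
#' @param network list: `ppi_threshold`, `normalized`, `screening_role`,
#'   `key_pathway_rule` (`"centrality"` or `"explicit"`), `key_pathway_ids`.
#' @param seed integer seed recorded in the manifest (the simulate seed when
#'   simulating).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            enrichment = list(), network = list(),
                            seed = 1L) {
  if (is.null(simulate) == is.null(inputs)) {
    abort("exactly one of `simulate` or `inputs` must be given")
  }
  if (!is.null(inputs)) {
    required <- c("compounds", "interactions", "diseases_gmt", "pathways_gmt",
                  "ppi_edges")
    missing <- setdiff(required, names(inputs))
    if (length(missing) > 0L) {
      abort(sprintf("inputs is missing: %s", paste(missing, collapse = ", ")))
    }
    paths <- unlist(inputs[c(required, intersect("symbol_map", names(inputs)))])
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0L) {
      abort(sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")))
    }
  }
  enr <- utils::modifyList(
    list(alpha = 0.05, filter_on = "p_adj", min_size = 3L, max_size = 500L,
         limits = c(BP = 30L, CC = 30L, MF = 25L), exclude = character()),
    enrichment
  )
  net <- utils::modifyList(
    list(ppi_threshold = 0.4, normalized = TRUE, screening_role = "compound",
         key_pathway_rule = "centrality", key_pathway_ids = NULL),
    network
  )
  structure(list(simulate = simulate, inputs = inputs, enrichment = enr,
                 network = net, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path a YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulate)) do.call(sim_config, raw$simulate)
  enr <- raw$enrichment %||% list()
  if (!is.null(enr$limits)) enr$limits <- unlist(enr$limits)
  pipeline_config(simulate = sim, inputs = raw$inputs, enrichment = enr,
                  network = raw$network %||% list(), seed = raw$seed %||% 1L)
}

PIPELINE_STAGES <- c("simulate", "ingest", "map", "enrich", "network",
                     "centrality", "screen")

#' Run one pipeline stage on a run directory
#'
#' Each stage reads the public-format intermediates earlier stages wrote
#' under `dir` and writes its own, so a run can be resumed, inspected, or
#' debugged stage by stage. Chaining all stages in order is exactly
#' [run_pipeline()].
#'
#' @param stage one of `r paste0('"', PIPELINE_STAGES, '"', collapse = ", ")`.
#' @param config a `pipeline_config`.
#' @param dir the run directory.
#' @return The run directory, invisibly.
#' @export
run_stage <- function(stage, config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!stage %in% PIPELINE_STAGES) {
    abort(sprintf("unknown stage '%s' (stages: %s)", stage,
                  paste(PIPELINE_STAGES, collapse = ", ")))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(config, dir),
         ingest = stage_ingest(config, dir),
         map = stage_map(config, dir),
         enrich = stage_enrich(config, dir),
         network = stage_network(config, dir),
         centrality = stage_centrality(config, dir),
         screen = stage_screen(config, dir))
  invisible(dir)
}

stage_simulate <- function(config, dir) {
  if (is.null(config$simulate)) return(invisible(dir))  # file mode: no-op
  bundle <- generate_bundle(config$simulate)
  write_bundle(bundle, file.path(dir, "inputs"))
  invisible(dir)
}

# Resolve where the raw input tables live for this run.
input_paths <- function(config, dir) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    inp$compounds <- unlist(inp$compounds)
    return(inp)
  }
  d <- file.path(dir, "inputs")
  list(compounds = list.files(d, pattern = "^compounds_.*\\.tsv$",
                              full.names = TRUE),
       interactions = file.path(d, "interactions.tsv"),
       diseases_gmt = file.path(d, "diseases.gmt"),
       pathways_gmt = file.path(d, "pathways.gmt"),
       ppi_edges = file.path(d, "ppi_edges.tsv"),
       symbol_map = NULL)
}

stage_ingest <- function(config, dir) {
  inp <- input_paths(config, dir)
  smap <- if (!is.null(inp$symbol_map)) read_symbol_map(inp$symbol_map)
  tables <- lapply(inp$compounds, read_compound_table)
  merged <- merge_and_deduplicate(tables)
  write_compound_table(merged, file.path(dir, "merged_compounds.tsv"))
  write_tsv_plain(read_interactions(inp$interactions, smap),
                  file.path(dir, "interactions_normalized.tsv"))
  invisible(dir)
}

stage_map <- function(config, dir) {
  inp <- input_paths(config, dir)
  merged <- read_compound_table(file.path(dir, "merged_compounds.tsv"))
  interactions <- read_interactions(file.path(dir, "interactions_normalized.tsv"))
  diseases <- read_gmt(inp$diseases_gmt, category = "DISEASE")
  compound_targets <- attach_targets(merged, interactions)
  active <- map_to_diseases(compound_targets, diseases, merged)
  write_json_stable(
    list(active_compounds = active$active_compounds,
         potential_targets = active$potential_targets,
         target_to_diseases = active$target_to_diseases,
         per_herb_targets = active$per_herb_targets),
    file.path(dir, "active_set.json")
  )
  triples <- dplyr::bind_rows(lapply(active$active_compounds, function(cid) {
    tg <- intersect(compound_targets[[cid]], active$potential_targets)
    dplyr::bind_rows(lapply(tg, function(t) {
      tibble(compound = cid, target = t, disease = active$target_to_diseases[[t]])
    }))
  }))
  if (nrow(triples) == 0L) {
    triples <- tibble(compound = character(), target = character(),
                      disease = character())
  }
  write_tsv_plain(triples, file.path(dir, "compound_target_disease.tsv"))
  write_tsv_plain(stage_summary(active, merged), file.path(dir, "stage_summary.tsv"))
  invisible(dir)
}

read_active_set <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "active_set.json"),
                             simplifyVector = TRUE)
  structure(
    list(active_compounds = as.character(raw$active_compounds),
         potential_targets = as.character(raw$potential_targets),
         target_to_diseases = lapply(raw$target_to_diseases, as.character),
         per_herb_targets = lapply(raw$per_herb_targets, as.character)),
    class = "active_set"
  )
}

stage_enrich <- function(config, dir) {
  inp <- input_paths(config, dir)
  active <- read_active_set(dir)
  pathways <- read_gmt(inp$pathways_gmt, category = "PATHWAY")
  enr <- config$enrichment
  background <- unique(c(unlist(pathways$members), active$potential_targets))
  res <- run_ora(active$potential_targets, pathways, background = background,
                 alpha = enr$alpha, filter_on = enr$filter_on,
                 min_size = enr$min_size, max_size = enr$max_size)
  res <- top_terms(res, enr$limits)
  flat <- res
  flat$hits <- vapply(res$hits, paste, "", collapse = ";")
  write_tsv_plain(flat, file.path(dir, "enrichment.tsv"))
  selected <- setdiff(res$set_id[res$category == "PATHWAY"], enr$exclude)
  write_json_stable(list(selected_pathways = selected),
                    file.path(dir, "selected_pathways.json"))
  invisible(dir)
}

stage_network <- function(config, dir) {
  inp <- input_paths(config, dir)
  active <- read_active_set(dir)
  merged <- read_compound_table(file.path(dir, "merged_compounds.tsv"))
  interactions <- read_interactions(file.path(dir, "interactions_normalized.tsv"))
  compound_targets <- attach_targets(merged, interactions)
  pathways <- read_gmt(inp$pathways_gmt, category = "PATHWAY")
  selected <- as.character(jsonlite::read_json(
    file.path(dir, "selected_pathways.json"),
    simplifyVector = TRUE)$selected_pathways)
  nets <- list(
    ctd = build_ctd(active, compound_targets),
    tp = build_tp(active$potential_targets, pathways, selected),
    ppi = build_ppi(read_scored_edges(inp$ppi_edges), active$potential_targets,
                    config$network$ppi_threshold)
  )
  for (nm in names(nets)) {
    write_network(nets[[nm]], file.path(dir, paste0(nm, ".graphml")), "graphml")
    write_network(nets[[nm]], file.path(dir, paste0(nm, ".sif")), "sif")
  }
  invisible(dir)
}

stage_centrality <- function(config, dir) {
  for (nm in c("ctd", "tp", "ppi")) {
    net <- read_network(file.path(dir, paste0(nm, ".graphml")), "graphml")
    write_tsv_plain(compute_centralities(net, config$network$normalized),
                    file.path(dir, paste0("centrality_", nm, ".tsv")))
  }
  invisible(dir)
}

read_centrality_table <- function(path) {
  df <- read_tsv_strict(path, c("node_id", "role", "DC", "BC", "CC"),
                        numeric_cols = c("DC", "BC", "CC"))
  df$DC <- as.integer(df$DC)
  df
}

stage_screen <- function(config, dir) {
  cen <- lapply(c(ctd = "ctd", tp = "tp", ppi = "ppi"), function(nm) {
    read_centrality_table(file.path(dir, paste0("centrality_", nm, ".tsv")))
  })
  role <- config$network$screening_role
  has_compounds <- any(cen$ctd$role == role)
  thresholds <- if (has_compounds) role_averages(cen$ctd, role) else
    list(mean_DC = NA_real_, mean_BC = NA_real_, mean_CC = NA_real_)
  key_compounds <- if (has_compounds) {
    screen_key_compounds(cen$ctd, role = role)
  } else cen$ctd[0, ]
  hub_genes <- select_hub_nodes(cen$ppi)
  key_pathways <- if (config$network$key_pathway_rule == "explicit" ||
                      any(cen$tp$role == "pathway")) {
    select_key_pathways(cen$tp, rule = config$network$key_pathway_rule,
                        ids = config$network$key_pathway_ids)
  } else character()
  screening <- list(
    thresholds = thresholds,
    key_compounds = as.list(key_compounds[c("node_id", "DC", "BC", "CC")]),
    hub_genes = as.list(hub_genes[c("node_id", "DC", "BC", "CC")]),
    key_pathways = key_pathways
  )
  write_json_stable(screening, file.path(dir, "screening.json"))
  write_report(config, dir, screening)
  invisible(dir)
}

write_report <- function(config, dir, screening) {
  summary_tbl <- readr::read_tsv(file.path(dir, "stage_summary.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
  counts <- named(as.list(summary_tbl$value), summary_tbl$metric)
  net_counts <- lapply(c(ctd = "ctd", tp = "tp", ppi = "ppi"), function(nm) {
    net <- read_network(file.path(dir, paste0(nm, ".graphml")), "graphml")
    list(nodes = igraph::vcount(net), edges = igraph::ecount(net))
  })
  enrichment_tbl <- readr::read_tsv(file.path(dir, "enrichment.tsv"),
                                    show_col_types = FALSE, progress = FALSE)
  report <- list(
    stage_counts = counts,
    enriched_terms = nrow(enrichment_tbl),
    networks = net_counts,
    n_key_compounds = length(screening$key_compounds$node_id),
    n_hub_genes = length(screening$hub_genes$node_id),
    n_key_pathways = length(screening$key_pathways),
    key_compounds = screening$key_compounds$node_id %||% character(),
    hub_genes = screening$hub_genes$node_id %||% character(),
    key_pathways = screening$key_pathways
  )
  write_json_stable(report, file.path(dir, "report.json"))
  manifest <- list(
    seed = config$seed,
    config = unclass(config)[c("enrichment", "network")],
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    package_version = as.character(utils::packageVersion("herbnetscreen"))
  )
  write_json_stable(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Run the full screening pipeline
#'
#' Executes every stage in order — simulate (when configured), ingest, disease
#' mapping, enrichment, network construction, centrality computation, and
#' screening — writing all intermediates and the final report under `dir`.
#' Every intermediate uses a public format (TSV, GMT, GraphML, SIF, JSON) so
#' each stage is independently inspectable; a fixed configuration and seed
#' reproduce the report byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param dir the run directory (created if needed).
#' @return The parsed report, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  for (stage in PIPELINE_STAGES) run_stage(stage, config, dir)
  invisible(jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE))
}

#' Summarize a completed run directory
#'
#' Re-reads the run outputs, recounts the tables, and returns a condensed
#' summary; a missing stage output is reported by name.
#'
#' @param dir a run directory produced by [run_pipeline()].
#' @return A list with the report, recounted table sizes, and screening lists.
#' @export
render_report <- function(dir) {
  needed <- c("report.json", "screening.json", "stage_summary.tsv",
              "enrichment.tsv", "ctd.graphml", "tp.graphml", "ppi.graphml")
  absent <- needed[!file.exists(file.path(dir, needed))]
  if (length(absent) > 0L) {
    abort(sprintf("incomplete run: missing stage output(s): %s",
                  paste(absent, collapse = ", ")))
  }
  report <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  recounts <- list(
    enrichment_rows = nrow(readr::read_tsv(file.path(dir, "enrichment.tsv"),
                                           show_col_types = FALSE,
                                           progress = FALSE)),
    triples = nrow(readr::read_tsv(file.path(dir, "compound_target_disease.tsv"),
                                   show_col_types = FALSE, progress = FALSE))
  )
  for (nm in c("ctd", "tp", "ppi")) {
    net <- read_network(file.path(dir, paste0(nm, ".graphml")), "graphml")
    recounts[[paste0(nm, "_nodes")]] <- igraph::vcount(net)
    recounts[[paste0(nm, "_edges")]] <- igraph::ecount(net)
  }
  list(report = report, recounts = recounts)
}
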