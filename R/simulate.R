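#' Configure the synthetic database emulator
#'
#' The generator emulates the structure of the database-derived inputs the
#' screening pipeline consumes: two (or more) herb compound lists with a few
#' shared compounds, a many-to-many compound-target bipartite map with a
#' skewed per-compound target count, several partially overlapping disease
#' gene sets, pathway annotation sets enriched for the disease-mapped
#' targets, and a sparse uniformly-scored protein-protein interaction graph.
#' Defaults mirror the rougui-fuzi screening conditions: 65 + 100 compounds
#' with 2 shared, five disease sets, and a 0.4-threshold-exercising uniform
#' score distribution.
#'
#' @param seed integer root seed; each generated table draws from its own
#'   deterministic sub-stream of this seed.
#' @param herbs named integer vector, herb label to compound count.
#' @param n_shared_compounds compounds shared by all herbs.
#' @param target_universe_size size of the gene-symbol universe.
#' @param targets_per_compound list with `mean` and `max`: per-compound target
#'   counts are `1 + Geometric`, truncated at `max` (a heavy-tailed degree
#'   profile).
#' @param n_diseases number of disease gene sets.
#' @param disease_set_size nominal members per disease set.
#' @param overlap_fraction fraction of compound-hit targets placed into
#'   disease sets (ignored when exact planting is requested).
#' @param n_pathways,pathway_size pathway annotation sets and their size.
#' @param ppi_edge_density Erdos-Renyi edge probability of the PPI graph.
#' @param ppi_score_distribution only `"uniform"` (scores on \[0, 1\]).
#' @param n_active_compounds,n_potential_targets optional exact planting: the
#'   generator guarantees the pipeline recovers exactly these counts of
#'   active compounds and potential targets.
#' @param planted_hub optional list with `n` (hub node count) and
#'   `degree_multiplier` (>= 1): hub incident-edge probability is
#'   `min(1, density * multiplier)`.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       herbs = c(fuzi = 65L, rougui = 100L),
                       n_shared_compounds = 2L,
                       target_universe_size = 500L,
                       targets_per_compound = list(mean = 2.5, max = 12L),
                       n_diseases = 5L,
                       disease_set_size = 120L,
                       overlap_fraction = 0.5,
                       n_pathways = 20L,
                       pathway_size = 12L,
                       ppi_edge_density = 0.15,
                       ppi_score_distribution = "uniform",
                       n_active_compounds = NULL,
                       n_potential_targets = NULL,
                       planted_hub = NULL) {
  cfg <- list(seed = as.integer(seed), herbs = herbs,
              n_shared_compounds = as.integer(n_shared_compounds),
              target_universe_size = as.integer(target_universe_size),
              targets_per_compound = targets_per_compound,
              n_diseases = as.integer(n_diseases),
              disease_set_size = as.integer(disease_set_size),
              overlap_fraction = overlap_fraction,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              ppi_edge_density = ppi_edge_density,
              ppi_score_distribution = ppi_score_distribution,
              n_active_compounds = n_active_compounds,
              n_potential_targets = n_potential_targets,
              planted_hub = planted_hub)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$herbs, cfg$n_shared_compounds, cfg$target_universe_size,
              cfg$n_diseases, cfg$disease_set_size, cfg$n_pathways,
              cfg$pathway_size)
  if (any(counts < 0)) abort("all generator counts must be non-negative")
  if (length(cfg$herbs) > 0L && cfg$n_shared_compounds > min(cfg$herbs)) {
    abort("shared compounds cannot exceed the smallest herb's compound count")
  }
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    abort("overlap_fraction must lie in [0, 1]")
  }
  if (cfg$ppi_edge_density < 0 || cfg$ppi_edge_density > 1) {
    abort("ppi_edge_density must lie in [0, 1]")
  }
  if (!identical(cfg$ppi_score_distribution, "uniform")) {
    abort("only the uniform PPI score distribution is implemented")
  }
  n_compounds <- total_compounds(cfg)
  if (!is.null(cfg$n_active_compounds) || !is.null(cfg$n_potential_targets)) {
    if (is.null(cfg$n_active_compounds) || is.null(cfg$n_potential_targets)) {
      abort("exact planting requires both n_active_compounds and n_potential_targets")
    }
    if (cfg$n_active_compounds > n_compounds) {
      abort("planted active compounds exceed the total compound count")
    }
    if (cfg$n_potential_targets > cfg$target_universe_size) {
      abort("planted potential targets exceed the target universe")
    }
    if (cfg$n_active_compounds > 0L && cfg$n_potential_targets == 0L) {
      abort("cannot plant active compounds without potential targets")
    }
    if (cfg$n_active_compounds == 0L && cfg$n_potential_targets > 0L) {
      abort("cannot plant potential targets without active compounds")
    }
    spare <- cfg$target_universe_size - cfg$n_potential_targets
    if (n_compounds > cfg$n_active_compounds &&
        spare < cfg$targets_per_compound$max) {
      abort("not enough non-planted targets for inactive compounds to draw from")
    }
  }
  if (!is.null(cfg$planted_hub)) {
    if (is.null(cfg$planted_hub$n) || is.null(cfg$planted_hub$degree_multiplier) ||
        cfg$planted_hub$n < 0 || cfg$planted_hub$degree_multiplier < 0) {
      abort("planted_hub needs non-negative n and degree_multiplier")
    }
  }
  structure(cfg, class = "sim_config")
}

total_compounds <- function(cfg) {
  if (length(cfg$herbs) == 0L) return(0L)
  as.integer(sum(cfg$herbs) - cfg$n_shared_compounds * (length(cfg$herbs) - 1L))
}

# Truncated-geometric per-compound target count: 1 + Geom(1/mean), capped.
draw_target_counts <- function(n, spec) {
  if (n == 0L) return(integer())
  p <- 1 / max(spec$mean, 1.000001)
  pmin(1L + stats::rgeom(n, p), as.integer(spec$max))
}

#' Generate a synthetic input bundle
#'
#' Draws every input table the pipeline consumes, together with ground-truth
#' bookkeeping (the planted active compounds, potential targets, and hub
#' proteins) recorded by direct set arithmetic at generation time. Identical
#' configurations produce identical bundles; each table is drawn from its own
#' named sub-stream of the root seed, so later stages never perturb earlier
#' ones.
#'
#' @param config a [sim_config()].
#' @return A `sim_bundle`: a list with `config`, `compound_tables` (one per
#'   herb), `interactions`, `disease_sets`, `pathway_sets`, `ppi_edges`, and
#'   `truth`.
#' @export
generate_bundle <- function(config) {
  config <- validate_sim_config(unclass(config))
  n_total <- total_compounds(config)
  n_shared <- if (length(config$herbs) > 1L) config$n_shared_compounds else 0L
  compound_ids <- sprintf("MOL%06d", seq_len(n_total))
  universe <- sprintf("G%04d", seq_len(config$target_universe_size))

  # --- compounds: shared ids first, then each herb's own block ---------------
  compound_tables <- list()
  offset <- n_shared
  for (h in names(config$herbs)) {
    n_h <- config$herbs[[h]]
    own <- if (n_h > n_shared) compound_ids[offset + seq_len(n_h - n_shared)]
           else character()
    offset <- offset + length(own)
    ids <- c(compound_ids[seq_len(n_shared)], own)
    compound_tables[[h]] <- compound_table(
      compound_id = ids,
      name = paste0("compound ", sub("^MOL0*", "", ids)),
      herbs = rep(list(h), length(ids))
    )
  }
  merged <- merge_and_deduplicate(compound_tables)

  # --- compound-target interactions -----------------------------------------
  planted <- !is.null(config$n_active_compounds)
  interactions_raw <- withr::with_seed(sub_seed(config$seed, "interactions"), {
    if (n_total == 0L || config$target_universe_size == 0L) {
      tibble(compound_id = character(), target_symbol = character())
    } else if (planted) {
      draw_planted_interactions(config, compound_ids, universe)
    } else {
      deg <- draw_target_counts(n_total, config$targets_per_compound)
      w <- 1 / seq_along(universe)  # rank-skewed target popularity
      tibble(
        compound_id = rep(compound_ids, deg),
        target_symbol = unlist(lapply(deg, function(d) {
          sample(universe, min(d, length(universe)), prob = w)
        }))
      )
    }
  })
  planted_potential <- attr(interactions_raw, "planted_potential")
  interactions <- normalize_interactions(interactions_raw)
  compound_targets <- attach_targets(merged, interactions)
  hit <- sort(unique(as.character(interactions$target_symbol)))

  # --- disease gene sets -----------------------------------------------------
  potential <- if (planted) {
    planted_potential %||% character()
  } else {
    withr::with_seed(sub_seed(config$seed, "diseases"), {
      if (length(hit) == 0L) character()
      else sort(sample(hit, round(config$overlap_fraction * length(hit))))
    })
  }
  disease_sets <- withr::with_seed(sub_seed(config$seed, "disease_members"), {
    draw_disease_sets(config, universe, hit, potential)
  })

  # --- pathway annotation sets -----------------------------------------------
  pathway_sets <- withr::with_seed(sub_seed(config$seed, "pathways"), {
    draw_pathway_sets(config, universe, potential)
  })

  # --- scored PPI edges ------------------------------------------------------
  hubs <- withr::with_seed(sub_seed(config$seed, "hubs"), {
    if (is.null(config$planted_hub) || config$planted_hub$n == 0L ||
        length(potential) == 0L) character()
    else sort(sample(potential, min(config$planted_hub$n, length(potential))))
  })
  ppi_edges <- withr::with_seed(sub_seed(config$seed, "ppi"), {
    draw_ppi_edges(config, potential, hubs)
  })

  truth <- list(
    active_compounds = sort(as.character(names(compound_targets)[vapply(
      compound_targets, function(tg) length(intersect(tg, potential)) > 0L,
      logical(1))])),
    potential_targets = potential,
    hubs = hubs
  )
  bundle <- structure(
    list(config = config, compound_tables = compound_tables,
         interactions = interactions, disease_sets = disease_sets,
         pathway_sets = pathway_sets, ppi_edges = ppi_edges, truth = truth),
    class = "sim_bundle"
  )
  verify_bundle(bundle)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact planting: every planted active compound hits >= 1 planted potential
# target, every planted potential target is hit, and no inactive compound
# touches the planted set.
draw_planted_interactions <- function(config, compound_ids, universe) {
  n_pot <- config$n_potential_targets
  n_act <- config$n_active_compounds
  potential <- sort(sample(universe, n_pot))
  rest <- setdiff(universe, potential)
  actives <- sort(sample(compound_ids, n_act))
  inactives <- setdiff(compound_ids, actives)
  deg <- named(draw_target_counts(length(compound_ids),
                                  config$targets_per_compound), compound_ids)
  rows <- list()
  if (n_act > 0L) {
    # coverage assignment: cycle potential targets over the active compounds
    forced <- split(rep(potential, length.out = max(n_pot, n_act)),
                    rep(actives, length.out = max(n_pot, n_act)))
    for (cid in actives) {
      f <- unique(forced[[cid]])
      extra <- max(0L, deg[[cid]] - length(f))
      pool <- setdiff(universe, f)
      rows[[cid]] <- tibble(
        compound_id = cid,
        target_symbol = c(f, if (extra > 0L) sample(pool, min(extra, length(pool))))
      )
    }
  }
  for (cid in inactives) {
    rows[[cid]] <- tibble(compound_id = cid,
                          target_symbol = sample(rest, min(deg[[cid]], length(rest))))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "planted_potential") <- potential
  out
}

draw_disease_sets <- function(config, universe, hit, potential) {
  if (config$n_diseases == 0L) {
    return(gene_set_collection(category = character()))
  }
  ids <- sprintf("D%02d", seq_len(config$n_diseases))
  filler_pool <- setdiff(universe, hit)
  members <- rep(list(character()), config$n_diseases)
  if (length(potential) > 0L) {
    # each disease-mapped target sits in 1 + Binom(n-1, 0.3) sets
    n_sets <- 1L + stats::rbinom(length(potential),
                                 max(config$n_diseases - 1L, 0L), 0.3)
    for (j in seq_along(potential)) {
      into <- sample.int(config$n_diseases, n_sets[j])
      for (s in into) members[[s]] <- c(members[[s]], potential[j])
    }
    # guard: a set left empty still gets one target so no set is empty
    for (s in which(lengths(members) == 0L)) {
      members[[s]] <- sample(potential, 1L)
    }
  }
  members <- lapply(members, function(m) {
    need <- config$disease_set_size - length(unique(m))
    filler <- if (need > 0L && length(filler_pool) > 0L) {
      sample(filler_pool, min(need, length(filler_pool)))
    } else character()
    sort(unique(c(m, filler)))
  })
  gene_set_collection(
    set_id = ids,
    description = paste0("synthetic disease gene set ", seq_along(ids)),
    category = rep("DISEASE", length(ids)),
    members = members
  )
}

draw_pathway_sets <- function(config, universe, potential) {
  if (config$n_pathways == 0L || length(universe) == 0L) {
    return(gene_set_collection(category = character()))
  }
  ids <- sprintf("PW%03d", seq_len(config$n_pathways))
  n_signal <- min(ceiling(config$n_pathways / 4), config$n_pathways)
  members <- lapply(seq_len(config$n_pathways), function(i) {
    size <- min(config$pathway_size, length(universe))
    if (i <= n_signal && length(potential) > 0L) {
      n_pot <- min(ceiling(0.7 * size), length(potential))
      pot <- sample(potential, n_pot)
      bg <- sample(setdiff(universe, pot), size - n_pot)
      sort(c(pot, bg))
    } else {
      sort(sample(universe, size))
    }
  })
  gene_set_collection(
    set_id = ids,
    description = paste0("synthetic pathway ", seq_along(ids)),
    category = rep("PATHWAY", length(ids)),
    members = members
  )
}

draw_ppi_edges <- function(config, potential, hubs) {
  empty <- tibble(protein_a = character(), protein_b = character(),
                  combined_score = numeric())
  if (length(potential) < 2L) return(empty)
  pairs <- utils::combn(sort(potential), 2L)
  p <- rep(config$ppi_edge_density, ncol(pairs))
  if (length(hubs) > 0L) {
    touches_hub <- pairs[1L, ] %in% hubs | pairs[2L, ] %in% hubs
    p[touches_hub] <- pmin(1, config$ppi_edge_density *
                             config$planted_hub$degree_multiplier)
  }
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) return(empty)
  scored_edges(tibble(protein_a = pairs[1L, keep], protein_b = pairs[2L, keep],
                      combined_score = stats::runif(sum(keep))))
}

# Generation-time consistency checks: the recorded truth must match the
# emitted tables under direct set arithmetic.
verify_bundle <- function(bundle) {
  merged <- merge_and_deduplicate(bundle$compound_tables)
  tg <- attach_targets(merged, bundle$interactions)
  disease_union <- as.character(unique(unlist(bundle$disease_sets$members)))
  pot <- sort(as.character(intersect(unique(unlist(tg)), disease_union)))
  stopifnot(identical(pot, bundle$truth$potential_targets))
  act <- sort(as.character(names(tg)[vapply(
    tg, function(x) length(intersect(x, pot)) > 0L, logical(1))]))
  stopifnot(identical(act, bundle$truth$active_compounds))
  stopifnot(all(bundle$truth$hubs %in% pot))
  invisible(bundle)
}

#' Write a synthetic bundle to a directory as pipeline-readable files
#'
#' Emits exactly the formats the readers consume: one long-format compound
#' TSV per herb, an interaction TSV, disease and pathway GMTs, a scored-edge
#' TSV, and the ground-truth bookkeeping as JSON.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in names(bundle$compound_tables)) {
    write_compound_table(bundle$compound_tables[[h]],
                         file.path(dir, paste0("compounds_", h, ".tsv")))
  }
  write_tsv_plain(bundle$interactions, file.path(dir, "interactions.tsv"))
  write_gmt(bundle$disease_sets, file.path(dir, "diseases.gmt"))
  write_gmt(bundle$pathway_sets, file.path(dir, "pathways.gmt"))
  write_tsv_plain(bundle$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  write_json_stable(bundle$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir a directory written by [write_bundle()].
#' @return A list with the same table elements as a `sim_bundle` (plus
#'   `truth` when present).
#' @export
read_bundle <- function(dir) {
  files <- list.files(dir, pattern = "^compounds_.*\\.tsv$", full.names = TRUE)
  herbs <- sub("^compounds_(.*)\\.tsv$", "\\1", basename(files))
  tables <- named(lapply(files, read_compound_table), herbs)
  truth_path <- file.path(dir, "truth.json")
  list(
    compound_tables = tables,
    interactions = read_interactions(file.path(dir, "interactions.tsv")),
    disease_sets = read_gmt(file.path(dir, "diseases.gmt"), category = "DISEASE"),
    pathway_sets = read_gmt(file.path(dir, "pathways.gmt"), category = "PATHWAY"),
    ppi_edges = read_scored_edges(file.path(dir, "ppi_edges.tsv")),
    truth = if (file.exists(truth_path)) {
      lapply(jsonlite::read_json(truth_path, simplifyVector = TRUE),
             as.character)
    }
  )
}

#' Planted-hub recovery harness
#'
#' Generates a bundle per seed, runs the full screening pipeline on it
#' (target attachment, disease mapping, thresholded PPI construction,
#' centralities, hub selection), and reports the fraction of planted hub
#' proteins recovered among the selected hubs.
#'
#' @param config a [sim_config()] with `planted_hub` set.
#' @param seeds integer vector of root seeds to run.
#' @param ppi_threshold confidence threshold for the PPI filter (default 0.4).
#' @return A list with `per_seed` (tibble: seed, planted, recovered) and
#'   `sensitivity` (recovered / planted over all seeds; `NaN` when nothing
#'   was planted).
#' @export
plant_and_recover <- function(config, seeds, ppi_threshold = 0.4) {
  config <- validate_sim_config(unclass(config))
  if (is.null(config$planted_hub)) abort("plant_and_recover requires planted_hub")
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    bundle <- generate_bundle(validate_sim_config(unclass(cfg)))
    merged <- merge_and_deduplicate(bundle$compound_tables)
    tg <- attach_targets(merged, bundle$interactions)
    active <- map_to_diseases(tg, bundle$disease_sets, merged)
    net <- build_ppi(bundle$ppi_edges, active$potential_targets, ppi_threshold)
    hubs <- select_hub_nodes(compute_centralities(net))$node_id
    tibble(seed = as.integer(s),
           planted = length(bundle$truth$hubs),
           recovered = length(intersect(bundle$truth$hubs, hubs)))
  })
  per_seed <- dplyr::bind_rows(rows)
  list(per_seed = per_seed,
       sensitivity = sum(per_seed$recovered) / sum(per_seed$planted))
}
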