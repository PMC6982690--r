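empty_active <- function() {
  cmp <- compound_table("c1", "cpd", list("fuzi"))
  tg <- attach_targets(cmp, tibble::tibble(compound_id = character(),
                                           target_symbol = character()))
  dis <- gene_set_collection("d1", "d", "DISEASE", list("T1"))
  map_to_diseases(tg, dis, cmp)
}

test_that("the compound-target-disease network wires compounds to targets to diseases", {
  expect_equal(igraph::vcount(build_ctd(empty_active(), list())), 0L)

  cmp <- compound_table(c("c1", "c2"), c("a", "b"), list("fuzi", "fuzi"))
  tg <- attach_targets(cmp, tibble::tibble(
    compound_id = c("c1", "c1", "c2"),
    target_symbol = c("T1", "T2", "T1")
  ))
  dis <- gene_set_collection(c("d1", "d2"), c("d1", "d2"), rep("DISEASE", 2),
                             list("T1", "T2"))
  act <- map_to_diseases(tg, dis, cmp)
  net <- build_ctd(act, tg)
  expect_equal(igraph::vcount(net), 6L)   # 2 compounds + 2 targets + 2 diseases
  expect_equal(igraph::ecount(net), 5L)   # 3 C-T + 2 T-D
  roles <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_equal(roles[["d1"]], "disease")
  # disease nodes touch targets only
  for (d in c("d1", "d2")) {
    nb <- igraph::neighbors(net, d)$name
    expect_true(all(roles[nb] == "target"))
  }
})

test_that("a planted 84-active / 42-target / 5-disease bundle yields a 131-node network", {
  bundle <- generate_bundle(sim_config(seed = 3, n_active_compounds = 84,
                                       n_potential_targets = 42))
  merged <- merge_and_deduplicate(bundle$compound_tables)
  tg <- attach_targets(merged, bundle$interactions)
  act <- map_to_diseases(tg, bundle$disease_sets, merged)
  expect_equal(length(act$active_compounds), 84L)
  expect_equal(length(act$potential_targets), 42L)
  net <- build_ctd(act, tg)
  expect_equal(igraph::vcount(net), 131L)
  expect_equal(sum(igraph::V(net)$role == "disease"), 5L)
  expect_true(all(igraph::degree(net) > 0))  # no isolated nodes by construction
})

test_that("target-pathway networks carry membership degrees and drop unannotated targets", {
  gs <- reference_pathway_gene_sets()
  expect_equal(igraph::vcount(build_tp(unique(unlist(gs$members)), gs,
                                       character())), 0L)
  expect_error(build_tp("F2", gs, "no-such-pathway"), "unknown pathway")

  targets <- unique(unlist(gs$members))
  tp <- build_tp(c(targets, "UNANNOTATED1"), gs, gs$set_id)
  deg <- igraph::degree(tp)
  expect_equal(deg[["complement and coagulation cascades"]], 7)
  expect_equal(deg[["arachidonic acid metabolism"]], 5)
  expect_equal(deg[["PI3K-Akt signaling pathway"]], 6)
  expect_false("UNANNOTATED1" %in% igraph::V(tp)$name)
  # pathway degree equals set arithmetic by construction
  for (i in seq_len(nrow(gs))) {
    expect_equal(deg[[gs$set_id[i]]], length(intersect(gs$members[[i]], targets)))
  }
})

test_that("a 29-target by 7-pathway annotation yields a 36-node bipartite network", {
  withr::with_seed(9, {
    targets <- sprintf("T%02d", 1:29)
    members <- rep(list(character()), 7)
    for (t in targets) {  # every target annotated somewhere
      for (p in sample.int(7, sample(1:2, 1))) members[[p]] <- c(members[[p]], t)
    }
    gs <- gene_set_collection(sprintf("PW%d", 1:7), sprintf("PW%d", 1:7),
                              rep("PATHWAY", 7), members)
    tp <- build_tp(targets, gs, gs$set_id)
    expect_equal(igraph::vcount(tp), 36L)
    expect_equal(sum(igraph::V(tp)$role == "target"), 29L)
  })
})

test_that("PPI construction keeps strictly above-threshold edges within the subset", {
  edges <- tibble::tibble(protein_a = c("A", "A", "B"),
                          protein_b = c("B", "C", "C"),
                          combined_score = c(0.39, 0.40, 0.41))
  net <- build_ppi(edges, c("A", "B", "C"), 0.4)
  expect_equal(igraph::ecount(net), 1L)  # only 0.41 survives strict >
  expect_equal(igraph::vcount(net), 3L)
  expect_true(igraph::vertex_attr(net, "isolated", "A"))

  expect_equal(igraph::ecount(build_ppi(edges, c("A", "B", "C"), 0.5)), 0L)
  expect_equal(igraph::vcount(build_ppi(edges, character(), 0.4)), 0L)

  # monotone: the edge set shrinks (or holds) as the threshold rises
  withr::with_seed(23, {
    ids <- sprintf("P%02d", 1:15)
    df <- scored_edges(tibble::tibble(protein_a = sample(ids, 60, TRUE),
                                      protein_b = sample(ids, 60, TRUE),
                                      combined_score = stats::runif(60)) |>
                         dplyr::filter(protein_a != protein_b))
    last <- Inf
    for (thr in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
      e <- igraph::ecount(build_ppi(df, ids, thr))
      expect_true(e <= last)
      last <- e
    }
  })
})

test_that("centralities reproduce closed forms on stars, paths, and cliques", {
  star <- hn_network(tibble::tibble(id = c("c", paste0("l", 1:4)), role = "protein"),
                     tibble::tibble(from = "c", to = paste0("l", 1:4)))
  cen <- compute_centralities(star)
  ctr <- cen[cen$node_id == "c", ]
  expect_equal(ctr$DC, 4L)
  expect_equal(ctr$BC, 1)
  expect_equal(ctr$CC, 1)
  leaves <- cen[cen$node_id != "c", ]
  expect_true(all(leaves$BC == 0))
  expect_equal(leaves$CC, rep(4 / 7, 4))

  path <- hn_network(tibble::tibble(id = letters[1:4], role = "protein"),
                     tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d")))
  pc <- compute_centralities(path)
  expect_equal(pc$BC[pc$node_id == "b"], 2 / 3)
  expect_equal(pc$CC[pc$node_id == "a"], 0.5)
  expect_equal(pc$CC[pc$node_id == "b"], 0.75)

  for (n in c(3, 5, 8)) {
    ids <- sprintf("k%d", seq_len(n))
    pairs <- t(utils::combn(ids, 2))
    clique <- hn_network(tibble::tibble(id = ids, role = "protein"),
                         tibble::tibble(from = pairs[, 1], to = pairs[, 2]))
    cc <- compute_centralities(clique)
    expect_true(all(cc$BC == 0))
    expect_true(all(cc$CC == 1))
  }
})

test_that("centralities agree with the exhaustive shortest-path oracle on random graphs", {
  withr::with_seed(29, {
    for (i in 1:25) {
      net <- random_network(20)
      got <- compute_centralities(net)
      want <- oracle_centralities(net)
      ord <- match(want$node_id, got$node_id)
      expect_equal(got$DC[ord], want$DC)
      expect_equal(got$BC[ord], want$BC, tolerance = 1e-9)
      expect_equal(got$CC[ord], want$CC, tolerance = 1e-9)
    }
  })
})

test_that("every generated network obeys the handshake lemma", {
  withr::with_seed(37, {
    for (i in 1:10) {
      net <- random_network(25)
      cen <- compute_centralities(net)
      expect_equal(sum(cen$DC), 2L * igraph::ecount(net))
    }
  })
  bundle <- generate_bundle(sim_config(seed = 4))
  merged <- merge_and_deduplicate(bundle$compound_tables)
  tg <- attach_targets(merged, bundle$interactions)
  act <- map_to_diseases(tg, bundle$disease_sets, merged)
  for (net in list(build_ctd(act, tg),
                   build_tp(act$potential_targets, bundle$pathway_sets,
                            bundle$pathway_sets$set_id),
                   build_ppi(bundle$ppi_edges, act$potential_targets, 0.4))) {
    expect_equal(sum(compute_centralities(net)$DC), 2L * igraph::ecount(net))
  }
})

test_that("role averages reproduce the worked-example pathway means", {
  one <- tibble::tibble(node_id = "x", role = "pathway", DC = 3L,
                        BC = 0.5, CC = 0.25)
  expect_equal(role_averages(one, "pathway"),
               list(mean_DC = 3, mean_BC = 0.5, mean_CC = 0.25))
  expect_error(role_averages(one, "compound"), "no centrality records")

  avg <- role_averages(reference_pathway_centralities(), "pathway")
  expect_equal(round(avg$mean_DC, 4), 5.1429)
  expect_equal(round(avg$mean_BC, 4), 0.3818)
  expect_equal(round(avg$mean_CC, 4), 0.2141)
})

test_that("key-compound screening is strict triple-above-average", {
  flat <- tibble::tibble(node_id = c("a", "b"), role = "compound",
                         DC = 3L, BC = 0.1, CC = 0.2)
  expect_equal(nrow(screen_key_compounds(flat)), 0L)

  thr <- list(mean_DC = 2.7619, mean_BC = 0.0068, mean_CC = 0.3464)
  sel <- screen_key_compounds(reference_key_compounds(), thresholds = thr)
  expect_true("MOL000675" %in% sel$node_id)        # oleic acid
  expect_equal(sel$node_id[1], "MOL000675")        # sorted by DC desc
  # the worked-example table is internally inconsistent with its own stated
  # averages: two of its 21 rows fail the strict rule (CC 0.3040 < 0.3464,
  # BC 0.0067 < 0.0068), so the stated rule recovers 19 of the 21
  expect_equal(nrow(sel), 19L)
  expect_setequal(setdiff(reference_key_compounds()$node_id, sel$node_id),
                  c("MOL002526", "MOL000677"))
})

test_that("screening is invariant to node relabeling and edge order", {
  withr::with_seed(41, {
    net <- random_network(15)
    nodes <- tibble::tibble(id = igraph::V(net)$name, role = "compound")
    el <- igraph::as_edgelist(net, names = TRUE)
    edges <- tibble::tibble(from = el[, 1], to = el[, 2])
    a <- hn_network(nodes, edges)
    b <- hn_network(nodes[sample(nrow(nodes)), ], edges[sample(nrow(edges)), ])
    sa <- screen_key_compounds(compute_centralities(a))
    sb <- screen_key_compounds(compute_centralities(b))
    expect_equal(sa$node_id, sb$node_id)
    expect_equal(select_hub_nodes(compute_centralities(a))$node_id,
                 select_hub_nodes(compute_centralities(b))$node_id)
  })
})

test_that("hub selection is degree strictly above the network mean", {
  # regular graph: nobody exceeds the mean
  ring_ids <- sprintf("r%d", 1:6)
  ring <- hn_network(tibble::tibble(id = ring_ids, role = "protein"),
                     tibble::tibble(from = ring_ids,
                                    to = ring_ids[c(2:6, 1)]))
  expect_equal(nrow(select_hub_nodes(compute_centralities(ring))), 0L)

  star <- hn_network(tibble::tibble(id = c("c", paste0("l", 1:4)), role = "protein"),
                     tibble::tibble(from = "c", to = paste0("l", 1:4)))
  expect_equal(select_hub_nodes(compute_centralities(star))$node_id, "c")

  withr::with_seed(43, {
    for (i in 1:10) {
      cen <- compute_centralities(random_network(20))
      got <- select_hub_nodes(cen)$node_id
      want <- cen$node_id[cen$DC > mean(cen$DC)]
      expect_setequal(got, want)
    }
  })
})

test_that("key-pathway selection supports the centrality rule and an explicit list", {
  one <- tibble::tibble(node_id = "p1", role = "pathway", DC = 5L,
                        BC = 0.3, CC = 0.2)
  expect_equal(length(select_key_pathways(one)), 0L)

  expect_setequal(select_key_pathways(reference_pathway_centralities()),
                  c("complement and coagulation cascades",
                    "PI3K-Akt signaling pathway"))

  trio <- c("complement and coagulation cascades",
            "arachidonic acid metabolism", "PI3K-Akt signaling pathway")
  expect_equal(select_key_pathways(reference_pathway_centralities(),
                                   rule = "explicit", ids = trio), trio)
  expect_error(select_key_pathways(one, rule = "frequency"), "unknown key-pathway rule")
  expect_error(select_key_pathways(one, rule = "explicit"), "id list")
})

test_that("a planted high-degree compound is the unique key compound", {
  # one compound hits every target; the rest hit one each
  cmp <- compound_table(c("hub", sprintf("c%02d", 1:8)),
                        paste0("cpd", 0:8), rep(list("fuzi"), 9))
  targets <- sprintf("T%02d", 1:8)
  inter <- dplyr::bind_rows(
    tibble::tibble(compound_id = "hub", target_symbol = targets),
    tibble::tibble(compound_id = sprintf("c%02d", 1:8), target_symbol = targets)
  )
  dis <- gene_set_collection("d1", "d", "DISEASE", list(targets))
  tg <- attach_targets(cmp, inter)
  act <- map_to_diseases(tg, dis, cmp)
  cen <- compute_centralities(build_ctd(act, tg))
  expect_equal(screen_key_compounds(cen)$node_id, "hub")
})
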