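test_that("compound tables read, merge per compound id, and report format problems", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines("compound_id\tname\therb", path)
  expect_equal(nrow(read_compound_table(path)), 0L)

  writeLines(c("compound_id\tname\therb",
               "M1\toleic acid\trougui",
               "M1\toleic acid\tfuzi"), path)
  tbl <- read_compound_table(path)
  expect_equal(nrow(tbl), 1L)
  expect_setequal(tbl$herbs[[1]], c("rougui", "fuzi"))

  writeLines(c("compound_id\tname",
               "M1\toleic acid"), path)
  expect_error(read_compound_table(path), "herb")

  writeLines(c("compound_id\tname\therb",
               "M1\toleic acid\trougui",
               "M1\toleic acid\trougui"), path)
  expect_warning(tbl <- read_compound_table(path), "duplicate")
  expect_equal(nrow(tbl), 1L)
})

test_that("a 65 + 100 compound inventory with 2 shared ids merges to 163 records", {
  fuzi_path <- withr::local_tempfile(fileext = ".tsv")
  rougui_path <- withr::local_tempfile(fileext = ".tsv")
  shared <- sprintf("MOL%06d", 1:2)
  fuzi_ids <- c(shared, sprintf("MOL%06d", 100 + 1:63))
  rougui_ids <- c(shared, sprintf("MOL%06d", 200 + 1:98))
  writeLines(c("compound_id\tname\therb",
               sprintf("%s\tcpd %s\tfuzi", fuzi_ids, fuzi_ids)), fuzi_path)
  writeLines(c("compound_id\tname\therb",
               sprintf("%s\tcpd %s\trougui", rougui_ids, rougui_ids)), rougui_path)
  merged <- merge_and_deduplicate(list(read_compound_table(fuzi_path),
                                       read_compound_table(rougui_path)))
  expect_equal(nrow(merged), 163L)
  expect_setequal(merged$herbs[[1]], c("fuzi", "rougui"))
})

test_that("GMT files round-trip and malformed lines are located", {
  path <- withr::local_tempfile(fileext = ".gmt")

  writeLines(character(), path)
  expect_equal(nrow(read_gmt(path)), 0L)

  writeLines(c("S1\tdesc\tA\tB", "S2\tshort"), path)
  expect_error(read_gmt(path), "line 2")

  withr::with_seed(42, {
    for (i in 1:5) {
      coll <- random_collection()
      coll$category <- rep("PATHWAY", nrow(coll))  # GMT carries one category
      write_gmt(coll, path)
      back <- read_gmt(path, category = "PATHWAY")
      expect_equal(back$set_id, coll$set_id)
      expect_equal(back$description, coll$description)
      for (j in seq_len(nrow(coll))) {
        expect_setequal(back$members[[j]], toupper(coll$members[[j]]))
      }
    }
  })
})

test_that("the bundled pathway gene lists parse to member counts 7, 5, and 6", {
  dir <- withr::local_tempdir()
  paths <- emit_reference_fixture(dir)
  coll <- read_gmt(paths[["gmt"]], category = "PATHWAY")
  counts <- setNames(lengths(coll$members), coll$set_id)
  expect_equal(counts[["complement and coagulation cascades"]], 7L)
  expect_equal(counts[["arachidonic acid metabolism"]], 5L)
  expect_equal(counts[["PI3K-Akt signaling pathway"]], 6L)
})

test_that("scored edges canonicalize, deduplicate to the max score, and accept both dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines("protein_a\tprotein_b\tcombined_score", path)
  expect_equal(nrow(read_scored_edges(path)), 0L)

  writeLines(c("protein_a\tprotein_b\tcombined_score",
               "B\tA\t0.7", "A\tB\t0.5"), path)
  edges <- read_scored_edges(path)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$protein_a, "A")
  expect_equal(edges$protein_b, "B")
  expect_equal(edges$combined_score, 0.7)

  writeLines(c("protein_a\tprotein_b\tcombined_score", "A\tB\t700"), path)
  expect_message(edges <- read_scored_edges(path), "1000")
  expect_equal(edges$combined_score, 0.7)

  expect_error(scored_edges(tibble::tibble(protein_a = "A", protein_b = "B",
                                           combined_score = 1.5)),
               "\\[0, 1\\]")
})

test_that("canonicalized edge lists never contain both orientations of a pair", {
  withr::with_seed(11, {
    for (i in 1:10) {
      ids <- sprintf("P%02d", 1:12)
      df <- tibble::tibble(protein_a = sample(ids, 40, TRUE),
                           protein_b = sample(ids, 40, TRUE),
                           combined_score = round(stats::runif(40), 3))
      df <- df[df$protein_a != df$protein_b, ]
      canon <- scored_edges(df)
      expect_true(all(canon$protein_a < canon$protein_b))
      expect_false(anyDuplicated(paste(canon$protein_a, canon$protein_b)) > 0)
      # insensitive to row order
      shuffled <- scored_edges(df[sample(nrow(df)), ])
      expect_equal(canon, shuffled)
    }
  })
})

test_that("networks round-trip through GraphML and SIF encodes role-pair relations", {
  dir <- withr::local_tempdir()
  g <- hn_network(tibble::tibble(id = c("a", "b", "c"),
                                 role = c("compound", "target", "disease")),
                  tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  gml <- file.path(dir, "net.graphml")
  write_network(g, gml, "graphml")
  back <- read_network(gml, "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(
    setNames(igraph::V(back)$role, igraph::V(back)$name)[igraph::V(g)$name],
    setNames(igraph::V(g)$role, igraph::V(g)$name)
  )
  expect_equal(igraph::ecount(back), 2)

  sif <- file.path(dir, "net.sif")
  write_network(g, sif, "sif")
  lines <- readLines(sif)
  expect_true("a compound-target b" %in% lines)
  expect_true("b target-disease c" %in% lines)

  # empty network exports an empty SIF body
  empty <- hn_network(tibble::tibble(id = character(), role = character()))
  write_network(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0L)

  expect_error(write_network(g, sif, "dot"), "unknown network format")

  withr::with_seed(5, {
    for (i in 1:5) {
      net <- random_network(12)
      write_network(net, gml, "graphml")
      back <- read_network(gml, "graphml")
      expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
      expect_equal(igraph::ecount(back), igraph::ecount(net))
    }
  })
})

test_that("the worked-example target-pathway subnetwork exports 18 SIF membership lines", {
  gs <- reference_pathway_gene_sets()
  tp <- build_tp(unique(unlist(gs$members)), gs, gs$set_id)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(tp, sif, "sif")
  lines <- readLines(sif)
  expect_equal(sum(grepl(" ", lines, fixed = TRUE)), 18L)
})

test_that("symbol maps must be functions and unmapped names pass through uppercased", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("raw_name\tofficial_symbol", "ptgs-2\tPTGS2", "ptgs-2\tPTGS1"), path)
  expect_error(read_symbol_map(path), "not a function")

  writeLines(c("raw_name\tofficial_symbol", "ptgs-2\tptgs2"), path)
  smap <- read_symbol_map(path)
  expect_equal(smap$official_symbol, "PTGS2")

  df <- tibble::tibble(compound_id = c("M1", "M1"),
                       target_symbol = c("ptgs-2", "il4"))
  expect_warning(norm <- normalize_interactions(df, smap), "uppercased")
  expect_setequal(norm$target_symbol, c("PTGS2", "IL4"))
})
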