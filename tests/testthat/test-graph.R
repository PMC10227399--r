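single_pair_counts <- function() {
  m <- data.frame(doc_id = "d", para_index = 0L,
                  canonical = c("cbd", "analgesic"),
                  etype = c("chemical", "property"), count = c(2L, 3L),
                  stringsAsFactors = FALSE)
  count_cooccurrences(m, n_paragraphs = 1L)
}

test_that("a single scored pair builds a two-node graph with its weight", {
  counts <- single_pair_counts()
  assoc <- decide_edges(counts)
  g <- build_graph(counts, assoc)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 6L)
  expect_equal(igraph::E(g)$relation, "chemical_property")
  expect_equal(nrow(igraph::E(g)$provenance[[1]]), 1L)
})

test_that("permissive and significant-only modes differ on non-significant pairs", {
  counts <- single_pair_counts()  # N = 1: nothing can be significant
  assoc <- decide_edges(counts)
  expect_false(any(assoc$significant))
  g_perm <- build_graph(counts, assoc, mode = "permissive")
  g_sig <- build_graph(counts, assoc, mode = "significant_only")
  expect_equal(igraph::ecount(g_perm), 1L)
  expect_equal(igraph::ecount(g_sig), 0L)

  # isolated mentioned entities appear only on request
  g_iso <- build_graph(counts, assoc[0, ], include_isolated = TRUE)
  expect_equal(igraph::vcount(g_iso), 2L)
  expect_equal(igraph::ecount(g_iso), 0L)
})

test_that("strain edges load from the curated table idempotently", {
  counts <- single_pair_counts()
  g <- build_graph(counts, decide_edges(counts))
  tab <- data.frame(strain = rep("blackberry kush", 3),
                    chemical = c("limonene", "myrcene", "cbd"))
  g2 <- add_strain_edges(g, tab)
  expect_equal(sum(igraph::V(g2)$etype == "strain"), 1L)
  expect_equal(sum(igraph::E(g2)$relation == "strain_chemical"), 3L)
  strain_eids <- which(igraph::E(g2)$relation == "strain_chemical")
  expect_true(all(igraph::E(g2)$weight[strain_eids] == 1L))
  expect_true(all(is.na(igraph::E(g2)$llr[strain_eids])))
  expect_true(all(vapply(igraph::E(g2)$provenance[strain_eids], nrow,
                         integer(1)) == 0L))

  # duplicate rows and re-application change nothing
  g3 <- add_strain_edges(g2, rbind(tab, tab))
  expect_equal(igraph::ecount(g3), igraph::ecount(g2))

  # a nine-strain panel yields nine strain nodes
  nine <- data.frame(strain = sprintf("strain %d", rep(1:9, each = 2)),
                     chemical = rep(c("limonene", "myrcene"), 9))
  g9 <- add_strain_edges(g, nine)
  expect_equal(sum(igraph::V(g9)$etype == "strain"), 9L)
  expect_equal(sum(igraph::E(g9)$relation == "strain_chemical"), 18L)

  expect_error(add_strain_edges(g, data.frame(strain = "", chemical = "x")),
               "malformed")
})

test_that("summary arithmetic: average degree is 2|E|/|V| over typed counts", {
  s <- network_summary(c(chemical = 2L), 1L)
  expect_equal(s$average_degree, 1.0)

  counts <- single_pair_counts()
  g <- build_graph(counts, decide_edges(counts))
  gs <- graph_summary(g)
  expect_equal(gs$node_count, 2L)
  expect_equal(sum(gs$node_count_by_type), gs$node_count)
  expect_equal(gs$average_degree, 1.0)

  empty <- network_summary(setNames(integer(), character()), 0L)
  expect_equal(empty$node_count, 0L)
  expect_equal(empty$average_degree, 0)
})

test_that("built graphs satisfy handshake, admissibility and weight conservation", {
  allowed <- c("chemical|gene", "gene|chemical", "chemical|property",
               "property|chemical", "strain|chemical", "chemical|strain")
  for (seed in c(3, 17, 29)) {
    gen <- generate_corpus(planted_spec(n_docs = 6, paras_per_doc = 40,
                                        seed = seed))
    counts <- count_cooccurrences(gen$corpus, gen$lexicon)
    assoc <- decide_edges(counts)
    g <- build_graph(counts, assoc)
    g <- add_strain_edges(g, data.frame(strain = "testkush",
                                        chemical = "cbd"))
    # handshake identity
    expect_equal(sum(igraph::degree(g)), 2L * igraph::ecount(g))
    # no self edges, no inadmissible type pairs
    el <- igraph::as_edgelist(g)
    expect_true(all(el[, 1] != el[, 2]))
    vt <- setNames(igraph::V(g)$etype, igraph::V(g)$name)
    expect_true(all(paste(vt[el[, 1]], vt[el[, 2]], sep = "|") %in% allowed))
    # weight equals the brute-force per-paragraph product sum
    bf <- brute_force_counts(gen$truth$mentions, gen$truth$n_paragraphs)
    for (e in seq_len(igraph::ecount(g))) {
      if (igraph::E(g)$relation[e] == "strain_chemical") next
      ends <- igraph::ends(g, e)
      pk <- paste(sort(sub("\\|", "/", ends)), collapse = "~")
      expect_equal(igraph::E(g)$weight[e], bf$pair_w[[pk]])
      expect_equal(igraph::E(g)$provenance_count[e],
                   bf$pair_occ[[pk]])
    }
  }
})

test_that("rebuilding from the same counts reproduces the identical export", {
  gen <- generate_corpus(planted_spec(seed = 41))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  build <- function() {
    g <- build_graph(counts, decide_edges(counts))
    dir <- withr::local_tempdir()
    paths <- write_network(g, dir)
    lapply(paths, readLines)
  }
  expect_identical(build(), build())
})

test_that("network exports carry the attribute schema", {
  gen <- generate_corpus(planted_spec(seed = 43))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  g <- build_graph(counts, decide_edges(counts))
  dir <- withr::local_tempdir()
  paths <- write_network(g, dir)
  expect_true(all(file.exists(paths)))
  el <- read.delim(paths[["edges"]])
  expect_true(all(c("from", "to", "relation", "weight", "llr",
                    "significant", "direction", "provenance_count",
                    "provenance") %in% names(el)))
  gml <- readLines(paths[["graphml"]])
  expect_true(any(grepl("graphml", gml)))
  js <- jsonlite::fromJSON(paths[["json"]])
  expect_equal(nrow(js$nodes), igraph::vcount(g))
  expect_equal(nrow(js$edges), igraph::ecount(g))
})
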