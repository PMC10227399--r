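# hand-built graph fixtures via the counts -> assoc -> graph route
fixture_graph <- function(edges) {
  # edges: data.frame(a, ta, g, tg); one co-occurrence paragraph per edge
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    data.frame(doc_id = "d", para_index = i - 1L,
               canonical = c(edges$a[i], edges$g[i]),
               etype = c(edges$ta[i], edges$tg[i]), count = 1L,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  counts <- count_cooccurrences(m, n_paragraphs = nrow(edges))
  build_graph(counts, decide_edges(counts))
}

star_subgraph <- function() {
  # chemical hub with 5 property leaves
  edges <- data.frame(a = "hub", ta = "chemical",
                      g = sprintf("leaf%d", 1:5), tg = "property",
                      stringsAsFactors = FALSE)
  g <- fixture_graph(edges)
  neighbor_subgraph(g, "hub")
}

test_that("neighbor subgraphs are induced on anchors plus neighbors", {
  g <- fixture_graph(data.frame(
    a = c("c1", "c1", "c1", "c2"), ta = "chemical",
    g = c("p1", "p2", "g1", "p1"),
    tg = c("property", "property", "gene", "property"),
    stringsAsFactors = FALSE))
  s <- neighbor_subgraph(g, "c1")
  expect_equal(igraph::vcount(s$graph), 4L)  # c1 + three neighbors
  expect_gte(igraph::ecount(s$graph), 3L)
  expect_equal(s$anchors, "c1|chemical")

  # two anchors sharing a neighbor: the shared node appears once
  s2 <- neighbor_subgraph(g, c("c1", "c2"))
  expect_equal(sum(igraph::V(s2$graph)$canonical == "p1"), 1L)

  # unresolvable names give near-miss suggestions
  expect_error(neighbor_subgraph(g, "c3"), "did you mean.*c1")
})

test_that("induced edges equal a brute-force scan on random graphs", {
  gen <- generate_corpus(planted_spec(n_docs = 8, paras_per_doc = 60,
                                      seed = 19))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  g <- build_graph(counts, decide_edges(counts))
  s <- neighbor_subgraph(g, "cbd")
  keep <- igraph::V(s$graph)$name
  el_all <- igraph::as_edgelist(g)
  want <- el_all[el_all[, 1] %in% keep & el_all[, 2] %in% keep, ,
                 drop = FALSE]
  got <- igraph::as_edgelist(s$graph)
  canon <- function(m) {
    sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  expect_equal(canon(got), canon(want))
  # no subgraph edge has an endpoint outside the subgraph
  expect_true(all(got %in% keep))
})

test_that("degree filtering shows the shrinking-local-degree behavior", {
  s <- star_subgraph()
  expect_equal(unname(local_degree(s)["hub|chemical"]), 5L)

  expect_identical(filter_by_degree(s, 0, protect_anchors = FALSE)$graph[],
                   s$graph[])

  # leaves (degree 1) fall to a min-degree-2 filter; the surviving hub's
  # recomputed local degree is 0
  f <- filter_by_degree(s, 2, protect_anchors = FALSE)
  expect_equal(igraph::V(f$graph)$canonical, "hub")
  expect_equal(unname(local_degree(f)), 0L)

  # iterate mode reaches the k-core fixed point: nothing survives
  f2 <- filter_by_degree(s, 2, protect_anchors = FALSE, iterate = TRUE)
  expect_equal(igraph::vcount(f2$graph), 0L)

  # anchors are protected by default
  f3 <- filter_by_degree(star_subgraph(), 10)
  expect_equal(igraph::V(f3$graph)$canonical, "hub")
})

test_that("progressive filters at rising thresholds monotonically shrink", {
  gen <- generate_corpus(planted_spec(n_docs = 10, paras_per_doc = 80,
                                      seed = 23))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  g <- build_graph(counts, decide_edges(counts))
  s <- neighbor_subgraph(g, c("cbd", "analgesic"))
  sizes <- igraph::vcount(s$graph)
  for (th in c(4, 5, 9)) {
    s <- filter_by_degree(s, th, protect_anchors = FALSE)
    sizes <- c(sizes, igraph::vcount(s$graph))
    # removal-only: survivors are a subset
    expect_true(all(igraph::V(s$graph)$name %in%
                      igraph::V(g)$name))
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("heatmap matrices hold edge weights with zero for absent edges", {
  g <- fixture_graph(data.frame(a = "limonene", ta = "chemical",
                                g = "analgesic", tg = "property",
                                stringsAsFactors = FALSE))
  # re-weight: rebuild with counted mentions 7x1
  m <- data.frame(doc_id = "d", para_index = 0L,
                  canonical = c("limonene", "analgesic"),
                  etype = c("chemical", "property"), count = c(7L, 1L),
                  stringsAsFactors = FALSE)
  counts <- count_cooccurrences(m, n_paragraphs = 1L)
  g <- build_graph(counts, decide_edges(counts))
  s <- neighbor_subgraph(g, "limonene")
  mat <- heatmap_matrix(s, "chemical", "property")
  expect_equal(mat, matrix(7, 1, 1,
                           dimnames = list("limonene", "analgesic")))
  expect_error(heatmap_matrix(s, "chemical", "chemical"), "differ")
  expect_error(heatmap_matrix(s, "chemical", "gene"), "absent")
})

test_that("heatmap row sums equal each chemical's summed edge weights", {
  gen <- generate_corpus(planted_spec(n_docs = 10, paras_per_doc = 60,
                                      seed = 29))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  g <- build_graph(counts, decide_edges(counts))
  s <- neighbor_subgraph(g, c("cbd", "thc"))
  mat <- heatmap_matrix(s, "chemical", "property")
  el <- igraph::as_data_frame(s$graph, what = "edges")
  vtype <- setNames(igraph::V(s$graph)$etype, igraph::V(s$graph)$name)
  vcan <- setNames(igraph::V(s$graph)$canonical, igraph::V(s$graph)$name)
  for (chem in rownames(mat)) {
    hit <- (vcan[el$from] == chem & vtype[el$to] == "property") |
      (vcan[el$to] == chem & vtype[el$from] == "property")
    expect_equal(sum(mat[chem, ]), sum(el$weight[hit]))
  }
  # matrix total equals summed chemical-property edge weight
  cp <- vtype[el$from] == "property" | vtype[el$to] == "property"
  expect_equal(sum(mat), sum(el$weight[cp]))
})

test_that("edge provenance recalls paragraphs that contain both entities", {
  gen <- generate_corpus(planted_spec(n_docs = 8, paras_per_doc = 40,
                                      seed = 37))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  g <- build_graph(counts, decide_edges(counts))
  el <- igraph::as_edgelist(g)
  for (e in seq_len(nrow(el))) {
    a <- sub("\\|.*", "", el[e, 1]); b <- sub("\\|.*", "", el[e, 2])
    prov <- recall_provenance(g, a, b, gen$corpus)
    expect_equal(nrow(prov), igraph::E(g)$provenance_count[e])
    for (txt in prov$text) {
      hits <- match_entities(txt, gen$lexicon)
      expect_true(all(c(a, b) %in% hits$canonical))
    }
    expect_true(all(nzchar(prov$doi)))
  }

  # strain edges have empty provenance but recall cleanly
  g2 <- add_strain_edges(g, data.frame(strain = "kush", chemical = "cbd"))
  prov0 <- recall_provenance(g2, "kush", "cbd", gen$corpus)
  expect_equal(nrow(prov0), 0L)

  expect_error(recall_provenance(g, "cbd", "thc", gen$corpus), "no edge")
})
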