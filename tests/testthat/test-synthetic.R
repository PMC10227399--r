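test_that("degenerate rates and fixed counts are honored exactly", {
  spec <- synthetic_spec(
    entities = data.frame(canonical = "cbd", etype = "chemical",
                          base_rate = 1.0),
    n_docs = 1L, paras_per_doc = 10L,
    mention_model = list(type = "fixed", k = 2L), seed = 4L)
  gen <- generate_corpus(spec)
  expect_equal(nrow(gen$truth$mentions), 10L)
  expect_true(all(gen$truth$mentions$count == 2L))
  # every paragraph's text carries exactly two planted tokens
  for (txt in gen$corpus[[1]]$paragraphs) {
    expect_equal(sum(strsplit(txt, " ")[[1]] == "cbd"), 2L)
  }
})

test_that("spec validation rejects inconsistent structures", {
  ents <- data.frame(canonical = c("g1", "c1"), etype = c("gene", "chemical"),
                     base_rate = 0.1)
  expect_error(synthetic_spec(ents[0, ], n_docs = 1), "entity row")
  expect_error(synthetic_spec(
    data.frame(canonical = "Bad Name", etype = "gene", base_rate = 0.1)),
    "alphanumeric")
  expect_error(synthetic_spec(
    data.frame(canonical = "g1", etype = "protein", base_rate = 0.1)),
    "type")
  expect_error(synthetic_spec(
    data.frame(canonical = "g1", etype = "gene", base_rate = 1.5)),
    "base rate")
  expect_error(synthetic_spec(
    ents, dependent_pairs = data.frame(e1 = "g1", e2 = "zz",
                                       joint_boost = 2)), "unknown entity")
  expect_error(synthetic_spec(
    ents, dependent_pairs = data.frame(e1 = "g1", e2 = "c1",
                                       joint_boost = 0.5)), "joint_boost")
  # inadmissible dependent pair types
  ents2 <- data.frame(canonical = c("g1", "g2"), etype = "gene",
                      base_rate = 0.1)
  expect_error(synthetic_spec(
    ents2, dependent_pairs = data.frame(e1 = "g1", e2 = "g2",
                                        joint_boost = 2)), "admissible")
})

test_that("empirical rates converge to specification rates", {
  spec <- synthetic_spec(
    entities = data.frame(canonical = c("c1", "p1"),
                          etype = c("chemical", "property"),
                          base_rate = 0.1),
    n_docs = 10L, paras_per_doc = 500L, seed = 12L)
  gen <- generate_corpus(spec, text = FALSE)
  N <- gen$truth$n_paragraphs
  m <- gen$truth$mentions
  # marginals within 3 binomial standard errors
  se <- sqrt(0.1 * 0.9 / N)
  for (e in c("c1", "p1")) {
    expect_lt(abs(sum(m$canonical == e) / N - 0.1), 3 * se)
  }
  # independent joint rate near 0.01
  paras <- split(m$canonical, paste(m$doc_id, m$para_index))
  joint <- sum(vapply(paras, function(x) all(c("c1", "p1") %in% x),
                      logical(1)))
  se2 <- sqrt(0.01 * 0.99 / N)
  expect_lt(abs(joint / N - 0.01), 3 * se2)
})

test_that("boosted pairs co-occur at the planted joint probability", {
  spec <- planted_spec(n_docs = 10L, paras_per_doc = 500L, boost = 8,
                       seed = 13L, base_rate = 0.05)
  gen <- generate_corpus(spec, text = FALSE)
  expect_equal(gen$truth$joint_probs$joint, 8 * 0.05 * 0.05)
  m <- gen$truth$mentions
  paras <- split(m$canonical, paste(m$doc_id, m$para_index))
  joint <- sum(vapply(paras, function(x) all(c("cbd", "analgesic") %in% x),
                      logical(1)))
  N <- gen$truth$n_paragraphs
  pj <- gen$truth$joint_probs$joint
  expect_lt(abs(joint / N - pj), 3 * sqrt(pj * (1 - pj) / N))
})

test_that("generation is a pure function of spec and seed", {
  spec <- planted_spec(n_docs = 4L, paras_per_doc = 10L, seed = 6L)
  expect_identical(generate_corpus(spec), generate_corpus(spec))
  expect_false(identical(generate_corpus(spec, seed = 6L),
                         generate_corpus(spec, seed = 7L)))
})

test_that("ground-truth mentions reproduce exactly through the matcher", {
  gen <- generate_corpus(planted_spec(n_docs = 6L, paras_per_doc = 30L,
                                      seed = 21L))
  got <- extract_mentions(gen$corpus, gen$lexicon)
  truth <- gen$truth$mentions
  ord <- function(d) {
    d <- d[order(d$doc_id, d$para_index, d$etype, d$canonical), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got), ord(truth))
})

test_that("the recovery report scores sensitivity, FPR and weight exactness", {
  gen <- generate_corpus(planted_spec(n_docs = 10L, paras_per_doc = 300L,
                                      boost = 8, seed = 44L))
  counts <- count_cooccurrences(gen$corpus, gen$lexicon)
  assoc <- decide_edges(counts)
  rep <- planted_recovery_report(gen$truth, assoc)
  expect_equal(rep$sensitivity, 1.0)
  expect_true(rep$weight_exactness)
  expect_lte(rep$false_positive_rate, 0.4)

  # a null spec yields NA sensitivity and a low FPR
  null_spec <- synthetic_spec(
    entities = planted_spec()$entities, n_docs = 10L, paras_per_doc = 200L,
    seed = 45L)
  gen0 <- generate_corpus(null_spec, text = FALSE)
  counts0 <- count_cooccurrences(gen0$truth$mentions,
                                 n_paragraphs = gen0$truth$n_paragraphs)
  rep0 <- planted_recovery_report(gen0$truth, decide_edges(counts0))
  expect_true(is.na(rep0$sensitivity))
  expect_lte(rep0$false_positive_rate, 0.5)
})
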