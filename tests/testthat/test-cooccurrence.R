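mentions_row <- function(doc, idx, canonical, etype, count) {
  data.frame(doc_id = doc, para_index = idx, canonical = canonical,
             etype = etype, count = count, stringsAsFactors = FALSE)
}

test_that("accumulation applies the mention-count product rule", {
  acc <- cooc_accumulator()
  cooc_accumulate(acc, mentions_row("d", 0L, c("cbdas", "cbda"),
                                    c("gene", "chemical"), c(1L, 2L)))
  counts <- finalize_counts(acc)
  expect_equal(counts$N, 1L)
  expect_equal(counts$pairs$pair_occ, 1L)
  expect_equal(counts$pairs$pair_weight, 2L)  # 1 x 2

  acc2 <- cooc_accumulator()
  cooc_accumulate(acc2, mentions_row("d", 1L, c("cbd", "analgesic"),
                                     c("chemical", "property"), c(2L, 3L)))
  expect_equal(finalize_counts(acc2)$pairs$pair_weight, 6L)  # 2 x 3

  # inadmissible same-type pair: occurrences count, no pair forms
  acc3 <- cooc_accumulator()
  cooc_accumulate(acc3, mentions_row("d", 2L, c("genea", "geneb"),
                                     c("gene", "gene"), c(1L, 1L)))
  c3 <- finalize_counts(acc3)
  expect_equal(c3$N, 1L)
  expect_equal(c3$entities$count, c(1L, 1L))
  expect_equal(nrow(c3$pairs), 0)

  # paragraphs with no mentions still advance N
  cooc_accumulate(acc3,
                  data.frame(doc_id = character(), para_index = integer(),
                             canonical = character(), etype = character(),
                             count = integer()),
                  doc_id = "d", para_index = 3L)
  expect_equal(finalize_counts(acc3)$N, 2L)

  # mixed paragraph keys are rejected
  expect_error(
    cooc_accumulate(acc3, mentions_row(c("a", "b"), 0L, c("x", "y"),
                                       c("gene", "chemical"), 1L)),
    "more than one paragraph")
})

test_that("contingency cells are consistent with the marginals", {
  m <- rbind(mentions_row("d", 0L, c("a1", "g1"), c("chemical", "gene"),
                          c(1L, 1L)))
  counts <- count_cooccurrences(m, n_paragraphs = 100L)
  # a and g each in 1 paragraph of 100, together once
  t1 <- contingency(counts, "a1", "g1")
  expect_equal(unclass(t1)[], c(k11 = 1L, k12 = 0L, k21 = 0L, k22 = 99L),
               ignore_attr = TRUE)

  # forced arithmetic: N=100, c(a)=10, c(g)=10, c(a,g)=1
  rows <- list()
  for (p in 0:9) rows[[p + 1]] <- mentions_row("d", p, "a1", "chemical", 1L)
  for (p in 9:18) {
    rows[[p + 2]] <- mentions_row("d", p, "g1", "gene", 1L)
  }
  m2 <- do.call(rbind, rows)
  counts2 <- count_cooccurrences(m2, n_paragraphs = 100L)
  t2 <- contingency(counts2, "a1", "g1")
  expect_equal(as.integer(t2), c(1L, 9L, 9L, 81L))
  expect_equal(sum(t2), 100L)

  # boundary: both entities in every paragraph
  m3 <- do.call(rbind, lapply(0:4, function(p) {
    mentions_row("d", p, c("a1", "g1"), c("chemical", "gene"), c(1L, 1L))
  }))
  t3 <- contingency(count_cooccurrences(m3, n_paragraphs = 5L), "a1", "g1")
  expect_equal(as.integer(t3), c(5L, 0L, 0L, 0L))

  expect_error(contingency(counts, "nonexistent", "g1"), "not seen")
})

test_that("streaming accumulation is order-independent and matches the vectorized counter", {
  m <- random_mentions(60, seed = 101)
  paras <- unique(m[, c("doc_id", "para_index")])
  n_para <- nrow(paras)

  stream_in <- function(order) {
    acc <- cooc_accumulator()
    for (r in order) {
      rows <- m[m$doc_id == paras$doc_id[r] &
                  m$para_index == paras$para_index[r], , drop = FALSE]
      cooc_accumulate(acc, rows)
    }
    finalize_counts(acc)
  }
  forward <- stream_in(seq_len(n_para))
  set.seed(1)
  shuffled <- stream_in(sample(n_para))
  expect_identical(forward, shuffled)

  vectorized <- count_cooccurrences(m, n_paragraphs = n_para)
  expect_identical(forward, vectorized)
})

test_that("counts equal a brute-force paragraph rescan on 100 random corpora", {
  for (seed in 1:100) {
    m <- random_mentions(20, seed = 1000 + seed)
    if (is.null(m)) next
    n_para <- nrow(unique(m[, c("doc_id", "para_index")]))
    got <- flatten_counts(count_cooccurrences(m, n_paragraphs = n_para))
    want <- brute_force_counts(m, n_para)
    expect_equal(got$N, want$N)
    expect_mapequal(got$occ, want$occ)
    expect_mapequal(got$pair_occ, want$pair_occ)
    expect_mapequal(got$pair_w, want$pair_w)
  }
})

test_that("count invariants hold: cell bounds, weight floor, provenance cardinality", {
  m <- random_mentions(80, seed = 77)
  n_para <- nrow(unique(m[, c("doc_id", "para_index")]))
  counts <- count_cooccurrences(m, n_paragraphs = n_para)
  p <- counts$pairs
  ek <- paste(counts$entities$canonical, counts$entities$etype)
  c1 <- counts$entities$count[match(paste(p$canonical_1, p$etype_1), ek)]
  c2 <- counts$entities$count[match(paste(p$canonical_2, p$etype_2), ek)]
  expect_true(all(p$pair_occ <= pmin(c1, c2)))
  expect_true(all(pmin(c1, c2) <= counts$N))
  expect_true(all(p$pair_weight >= p$pair_occ))
  expect_equal(vapply(counts$provenance, nrow, integer(1)),
               setNames(p$pair_occ, names(counts$provenance)))
  # every queried pair's cells are non-negative and sum to N
  for (i in seq_len(nrow(p))) {
    tt <- contingency(counts, p$canonical_1[i], p$canonical_2[i],
                      p$etype_1[i], p$etype_2[i])
    expect_true(all(tt >= 0))
    expect_equal(sum(tt), counts$N)
  }
})
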