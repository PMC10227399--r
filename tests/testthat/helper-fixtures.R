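# Shared fixtures and independent oracles. Oracles deliberately take a
# different computational route from the implementation they check.

# -- JATS-style XML builder ---------------------------------------------------

jats_xml <- function(title = "T", abstract = c("A"), body = c("P1", "P2"),
                     doi = "10.1000/test", journal = "J Test",
                     year = "2021") {
  paste0(
    "<article><front><journal-meta><journal-title-group>",
    "<journal-title>", journal, "</journal-title></journal-title-group>",
    "</journal-meta><article-meta>",
    "<article-id pub-id-type='doi'>", doi, "</article-id>",
    "<title-group><article-title>", title, "</article-title></title-group>",
    "<contrib-group><contrib contrib-type='author'><name>",
    "<surname>Doe</surname><given-names>Jane</given-names>",
    "</name></contrib></contrib-group>",
    "<pub-date><year>", year, "</year></pub-date>",
    "<abstract>", paste0("<p>", abstract, "</p>", collapse = ""),
    "</abstract></article-meta></front>",
    "<body>", paste0("<p>", body, "</p>", collapse = ""), "</body>",
    "</article>")
}

# -- small hand-built lexicon -------------------------------------------------

toy_lexicon <- function() {
  as_lexicon(data.frame(
    surface = c("cbd", "cannabidiol", "cbda", "cannabidiolic acid",
                "cannabidiolic acid synthase", "cbdas", "limonene",
                "myrcene", "pain", "analgesic", "antiviral",
                "anti-inflammatory"),
    canonical = c("cbd", "cbd", "cannabidiolic acid", "cannabidiolic acid",
                  "cbda synthase", "cbda synthase", "limonene", "myrcene",
                  "pain", "analgesic", "antiviral", "anti inflammatory"),
    etype = c("chemical", "chemical", "chemical", "chemical", "gene",
              "gene", "chemical", "chemical", "property", "property",
              "property", "property"),
    stringsAsFactors = FALSE))
}

# -- independent LLR oracle via stats::dbinom ---------------------------------
# The binomial choose() terms cancel between the constrained and
# unconstrained likelihoods, so differences of dbinom log-masses equal the
# package's explicit x log q + (n-x) log(1-q) formulation.

oracle_llr <- function(k11, k12, k21, k22) {
  n1 <- k11 + k21; n2 <- k12 + k22
  x1 <- k11; x2 <- k12
  p1 <- x1 / n1; p2 <- x2 / n2; p <- (x1 + x2) / (n1 + n2)
  2 * (dbinom(x1, n1, p1, log = TRUE) + dbinom(x2, n2, p2, log = TRUE) -
         dbinom(x1, n1, p, log = TRUE) - dbinom(x2, n2, p, log = TRUE))
}

# -- brute-force paragraph rescan oracle --------------------------------------
# Recomputes presence counts, pair counts and pair weights for a mention
# table by scanning paragraphs one at a time with nested loops; no shared
# code with the accumulator or the vectorized counter.

brute_force_counts <- function(mentions, n_paragraphs) {
  occ <- list(); pair_occ <- list(); pair_w <- list(); pair_paras <- list()
  paras <- unique(mentions[, c("doc_id", "para_index")])
  for (r in seq_len(nrow(paras))) {
    rows <- mentions[mentions$doc_id == paras$doc_id[r] &
                       mentions$para_index == paras$para_index[r], ,
                     drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      k <- paste(rows$canonical[i], rows$etype[i], sep = "/")
      occ[[k]] <- (if (is.null(occ[[k]])) 0 else occ[[k]]) + 1
      if (i < nrow(rows)) {
        for (j in seq.int(i + 1, nrow(rows))) {
          tpair <- sort(c(rows$etype[i], rows$etype[j]))
          if (!(identical(tpair, c("chemical", "gene")) ||
                identical(tpair, c("chemical", "property")))) next
          k2 <- paste(rows$canonical[j], rows$etype[j], sep = "/")
          pk <- paste(sort(c(k, k2)), collapse = "~")
          pair_occ[[pk]] <- (if (is.null(pair_occ[[pk]])) 0
                             else pair_occ[[pk]]) + 1
          pair_w[[pk]] <- (if (is.null(pair_w[[pk]])) 0
                           else pair_w[[pk]]) +
            rows$count[i] * rows$count[j]
          pair_paras[[pk]] <- c(pair_paras[[pk]],
                                paste(paras$doc_id[r], paras$para_index[r]))
        }
      }
    }
  }
  list(N = n_paragraphs, occ = occ, pair_occ = pair_occ, pair_w = pair_w,
       pair_paras = pair_paras)
}

# counts object -> comparable flat lists keyed like the brute-force oracle
flatten_counts <- function(counts) {
  occ <- as.list(setNames(counts$entities$count,
                          paste(counts$entities$canonical,
                                counts$entities$etype, sep = "/")))
  pk <- paste(
    paste(counts$pairs$canonical_1, counts$pairs$etype_1, sep = "/"),
    paste(counts$pairs$canonical_2, counts$pairs$etype_2, sep = "/"),
    sep = "~")
  list(N = counts$N,
       occ = occ,
       pair_occ = as.list(setNames(counts$pairs$pair_occ, pk)),
       pair_w = as.list(setNames(counts$pairs$pair_weight, pk)))
}

# random mention table over a small entity panel, for property tests
random_mentions <- function(n_paragraphs, seed) {
  set.seed(seed)
  ents <- data.frame(
    canonical = c("g1", "g2", "c1", "c2", "c3", "p1", "p2"),
    etype = c("gene", "gene", "chemical", "chemical", "chemical",
              "property", "property"), stringsAsFactors = FALSE)
  rows <- list()
  for (p in seq_len(n_paragraphs)) {
    inc <- which(runif(nrow(ents)) < 0.3)
    if (length(inc) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = sprintf("D%02d", 1L + (p - 1L) %/% 10L),
      para_index = (p - 1L) %% 10L,
      canonical = ents$canonical[inc], etype = ents$etype[inc],
      count = 1L + rpois(length(inc), 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# standard small planted-pair spec used across tests
planted_spec <- function(n_docs = 10L, paras_per_doc = 50L, boost = 8,
                         seed = 11L, base_rate = 0.1) {
  synthetic_spec(
    entities = data.frame(
      canonical = c("cbdas1", "cbd", "thc", "analgesic", "sedative"),
      etype = c("gene", "chemical", "chemical", "property", "property"),
      base_rate = base_rate, stringsAsFactors = FALSE),
    n_docs = n_docs, paras_per_doc = paras_per_doc,
    dependent_pairs = data.frame(e1 = "cbd", e2 = "analgesic",
                                 joint_boost = boost,
                                 stringsAsFactors = FALSE),
    seed = seed)
}
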