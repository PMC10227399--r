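# Synthetic corpora with planted co-occurrence structure. Every pipeline
# stage is testable against exact ground truth: entities are included in
# each paragraph by Bernoulli draws at known base rates, selected pairs are
# given a boosted joint probability, mention counts follow a known model,
# and the filler vocabulary is disjoint from all lexicon surfaces, so the
# dictionary matcher recovers the planted mentions exactly.

#' Specify a synthetic corpus
#'
#' @param entities Data frame with columns `canonical` (single alphanumeric
#'   token), `etype`, `base_rate` (per-paragraph inclusion probability in
#'   (0, 1]).
#' @param n_docs Number of documents.
#' @param paras_per_doc Paragraphs per document: a single count or a
#'   `c(min, max)` range sampled uniformly.
#' @param dependent_pairs Optional data frame `e1`, `e2`, `joint_boost`
#'   (multiplier > 1): the pair's joint inclusion probability becomes
#'   `joint_boost * p1 * p2`, capped at `min(p1, p2)`. Pairs must be
#'   admissible (gene-chemical or chemical-property) and an entity may
#'   appear in at most one dependent pair.
#' @param mention_model `list(type = "geometric", q = 0.5)` (counts on
#'   1, 2, 3, ...) or `list(type = "fixed", k = 2)`.
#' @param filler_vocab_size Number of distinct filler tokens.
#' @param para_len Filler tokens per paragraph.
#' @param seed Default RNG seed for [generate_corpus()].
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(entities, n_docs = 10L, paras_per_doc = 10L,
                           dependent_pairs = NULL,
                           mention_model = list(type = "geometric", q = 0.5),
                           filler_vocab_size = 60L, para_len = 12L,
                           seed = 1L) {
  stopifnot(is.data.frame(entities),
            all(c("canonical", "etype", "base_rate") %in% names(entities)))
  if (nrow(entities) == 0L) {
    stop("synthetic spec needs at least one entity row", call. = FALSE)
  }
  entities$canonical <- as.character(entities$canonical)
  if (any(!grepl("^[a-z0-9]+$", entities$canonical))) {
    stop("synthetic entity canonicals must be single lowercase ",
         "alphanumeric tokens", call. = FALSE)
  }
  if (anyDuplicated(entities$canonical)) {
    stop("duplicate synthetic entity canonicals", call. = FALSE)
  }
  if (!all(entities$etype %in% ENTITY_TYPES)) {
    stop("unknown entity type in synthetic spec", call. = FALSE)
  }
  if (any(entities$base_rate <= 0 | entities$base_rate > 1)) {
    stop("base rates must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(dependent_pairs) && nrow(dependent_pairs) > 0L) {
    stopifnot(all(c("e1", "e2", "joint_boost") %in% names(dependent_pairs)))
    involved <- c(dependent_pairs$e1, dependent_pairs$e2)
    if (!all(involved %in% entities$canonical)) {
      stop("dependent pair references unknown entity", call. = FALSE)
    }
    if (anyDuplicated(involved)) {
      stop("an entity may appear in at most one dependent pair",
           call. = FALSE)
    }
    t1 <- entities$etype[match(dependent_pairs$e1, entities$canonical)]
    t2 <- entities$etype[match(dependent_pairs$e2, entities$canonical)]
    if (!all(admissible_pair(t1, t2))) {
      stop("dependent pairs must be of admissible types ",
           "(gene-chemical or chemical-property)", call. = FALSE)
    }
    if (any(dependent_pairs$joint_boost <= 1)) {
      stop("joint_boost must exceed 1", call. = FALSE)
    }
    p1 <- entities$base_rate[match(dependent_pairs$e1, entities$canonical)]
    p2 <- entities$base_rate[match(dependent_pairs$e2, entities$canonical)]
    joint <- pmin(dependent_pairs$joint_boost * p1 * p2, pmin(p1, p2))
    if (any(joint + (1 - p1 - p2) < 0)) {
      stop("joint_boost yields an invalid joint distribution ",
           "(P(neither) < 0)", call. = FALSE)
    }
    dependent_pairs$joint <- joint
  } else {
    dependent_pairs <- data.frame(e1 = character(), e2 = character(),
                                  joint_boost = numeric(), joint = numeric(),
                                  stringsAsFactors = FALSE)
  }
  stopifnot(mention_model$type %in% c("geometric", "fixed"))
  filler <- sprintf("zqf%03d", seq_len(filler_vocab_size))
  if (any(entities$canonical %in% filler)) {
    stop("entity canonical collides with filler vocabulary", call. = FALSE)
  }
  structure(list(entities = entities, n_docs = as.integer(n_docs),
                 paras_per_doc = as.integer(paras_per_doc),
                 dependent_pairs = dependent_pairs,
                 mention_model = mention_model, filler = filler,
                 para_len = as.integer(para_len), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic corpus with ground truth
#'
#' A pure function of `(spec, seed)`: the same pair always yields the
#' byte-identical corpus. The caller's RNG state is left untouched.
#' Presence and mention-count draws are vectorized over all paragraphs;
#' with `text = FALSE` only the ground-truth mention stream is produced
#' (no paragraph text, no documents), which makes large simulation studies
#' of the counting and testing stages cheap.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @param text Assemble paragraph text and [document()] objects (default
#'   `TRUE`).
#' @return List with `corpus` (list of [document()], `NULL` when
#'   `text = FALSE`), `lexicon` (one entry per planted entity, surface =
#'   canonical), and `truth`: `mentions` (exact per-paragraph mention
#'   counts), `joint_probs` (per dependent pair: `p1`, `p2`, `joint`),
#'   `n_paragraphs`, and the spec.
#' @export
generate_corpus <- function(spec, seed = spec$seed, text = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ents <- spec$entities
  dp <- spec$dependent_pairs
  dep_idx1 <- match(dp$e1, ents$canonical)
  dep_idx2 <- match(dp$e2, ents$canonical)
  indep_idx <- setdiff(seq_len(nrow(ents)), c(dep_idx1, dep_idx2))
  n_entities <- nrow(ents)
  n_para_doc <- if (length(spec$paras_per_doc) == 2L) {
    sample(spec$paras_per_doc[1]:spec$paras_per_doc[2], spec$n_docs,
           replace = TRUE)
  } else rep(spec$paras_per_doc, spec$n_docs)
  P <- sum(n_para_doc)
  doc_ids <- sprintf("SYN%05d", seq_len(spec$n_docs))
  para_doc <- rep(doc_ids, times = n_para_doc)
  para_index <- unlist(lapply(n_para_doc, function(n) seq_len(n) - 1L),
                       use.names = FALSE)
  # presence draws: independent entities as Bernoulli columns, dependent
  # pairs through one uniform per paragraph cut at the 2x2 cell bounds
  present <- matrix(FALSE, P, n_entities)
  for (i in indep_idx) {
    present[, i] <- stats::runif(P) < ents$base_rate[i]
  }
  if (nrow(dp) > 0L) {
    for (j in seq_len(nrow(dp))) {
      p1 <- ents$base_rate[dep_idx1[j]]
      p2 <- ents$base_rate[dep_idx2[j]]
      pj <- dp$joint[j]
      u <- stats::runif(P)
      # cells: both / e1 only / e2 only / neither
      present[, dep_idx1[j]] <- u < p1
      present[, dep_idx2[j]] <- u < pj | (u >= p1 & u < p1 + p2 - pj)
    }
  }
  hit <- which(present, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  n_hit <- nrow(hit)
  counts <- if (spec$mention_model$type == "fixed") {
    rep(as.integer(spec$mention_model$k), n_hit)
  } else {
    1L + stats::rgeom(n_hit, spec$mention_model$q)
  }
  mentions <- data.frame(doc_id = para_doc[hit[, 1L]],
                         para_index = para_index[hit[, 1L]],
                         canonical = ents$canonical[hit[, 2L]],
                         etype = ents$etype[hit[, 2L]],
                         count = as.integer(counts),
                         stringsAsFactors = FALSE)
  corpus <- NULL
  if (text) {
    para_of_hit <- hit[, 1L]
    texts <- character(P)
    from <- 1L
    for (p in seq_len(P)) {
      idx <- integer(0)
      while (from <= n_hit && para_of_hit[from] == p) {
        idx <- c(idx, from)
        from <- from + 1L
      }
      tokens <- c(rep(ents$canonical[hit[idx, 2L]], times = counts[idx]),
                  sample(spec$filler, spec$para_len, replace = TRUE))
      texts[p] <- paste(sample(tokens), collapse = " ")
    }
    corpus <- vector("list", spec$n_docs)
    off <- 0L
    for (d in seq_len(spec$n_docs)) {
      corpus[[d]] <- document(
        doc_ids[d],
        title = paste("The synthetic document", d,
                      "of the generated corpus"),
        abstract = "",
        paragraphs = texts[off + seq_len(n_para_doc[d])],
        meta = list(journal = "Synthetic Corpus",
                    doi = paste0("10.0000/", doc_ids[d])))
      off <- off + n_para_doc[d]
    }
  }
  joint_probs <- if (nrow(dp) > 0L) {
    data.frame(e1 = dp$e1, e2 = dp$e2,
               p1 = ents$base_rate[dep_idx1], p2 = ents$base_rate[dep_idx2],
               joint = dp$joint, stringsAsFactors = FALSE)
  } else {
    data.frame(e1 = character(), e2 = character(), p1 = numeric(),
               p2 = numeric(), joint = numeric(), stringsAsFactors = FALSE)
  }
  lexicon <- as_lexicon(data.frame(surface = ents$canonical,
                                   canonical = ents$canonical,
                                   etype = ents$etype,
                                   stringsAsFactors = FALSE))
  list(corpus = corpus, lexicon = lexicon,
       truth = list(mentions = mentions, joint_probs = joint_probs,
                    n_paragraphs = P, spec = spec, seed = seed))
}

# Ground-truth pair weights: sum over paragraphs of mention-count products.
truth_pair_weights <- function(truth) {
  m <- truth$mentions
  if (nrow(m) == 0L) {
    return(data.frame(e1 = character(), e2 = character(), weight = integer(),
                      occ = integer(), stringsAsFactors = FALSE))
  }
  m$para <- paste(m$doc_id, m$para_index, sep = "\r")
  mm <- merge(m, m, by = "para")
  mm <- mm[mm$canonical.x < mm$canonical.y &
             admissible_pair(mm$etype.x, mm$etype.y), , drop = FALSE]
  if (nrow(mm) == 0L) {
    return(data.frame(e1 = character(), e2 = character(), weight = integer(),
                      occ = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(mm$canonical.x, mm$canonical.y, sep = "\r")
  w <- tapply(mm$count.x * mm$count.y, key, sum)
  occ <- tapply(rep(1L, nrow(mm)), key, sum)
  ks <- sort(names(w))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  data.frame(e1 = vapply(parts, `[`, character(1), 1L),
             e2 = vapply(parts, `[`, character(1), 2L),
             weight = as.integer(w[ks]), occ = as.integer(occ[ks]),
             stringsAsFactors = FALSE)
}

#' Score pipeline output against a generator's ground truth
#'
#' @param truth `truth` component of [generate_corpus()].
#' @param assoc Association results from [decide_edges()] on the generated
#'   corpus.
#' @return List with `sensitivity` (fraction of planted dependent pairs
#'   recovered as significant), `false_positive_rate` (fraction of
#'   independent admissible entity pairs flagged significant; unscored
#'   pairs count as negatives), and `weight_exactness` (`TRUE` iff every
#'   scored pair's weight equals the ground-truth sum of per-paragraph
#'   mention-count products).
#' @export
planted_recovery_report <- function(truth, assoc) {
  ents <- truth$spec$entities
  dp <- truth$spec$dependent_pairs
  upair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sig_pairs <- upair(assoc$entity_a, assoc$entity_g)[assoc$significant]
  # all admissible entity pairs in the spec
  grid <- expand.grid(i = seq_len(nrow(ents)), j = seq_len(nrow(ents)))
  grid <- grid[grid$i < grid$j, , drop = FALSE]
  adm <- admissible_pair(ents$etype[grid$i], ents$etype[grid$j])
  all_pairs <- upair(ents$canonical[grid$i[adm]], ents$canonical[grid$j[adm]])
  planted <- if (nrow(dp) > 0L) upair(dp$e1, dp$e2) else character(0)
  indep <- setdiff(all_pairs, planted)
  sensitivity <- if (length(planted) > 0L) {
    mean(planted %in% sig_pairs)
  } else NA_real_
  fpr <- if (length(indep) > 0L) mean(indep %in% sig_pairs) else NA_real_
  tw <- truth_pair_weights(truth)
  ak <- upair(assoc$entity_a, assoc$entity_g)
  m <- match(ak, upair(tw$e1, tw$e2))
  weight_exactness <- !anyNA(m) && all(assoc$weight == tw$weight[m]) &&
    all(assoc$pair_occ == tw$occ[m])
  list(sensitivity = sensitivity, false_positive_rate = fpr,
       weight_exactness = weight_exactness)
}
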