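# Paragraph-level occurrence and co-occurrence accounting.
#
# Probabilities are defined at paragraph granularity: c(e) counts paragraphs
# containing e at least once, c(e1,e2) counts paragraphs containing both.
# Mention multiplicity enters only the edge weight, as the per-paragraph
# product of the two entities' mention counts, summed over co-occurring
# paragraphs. Only the two mined relation types are admissible:
# gene-chemical and chemical-property.

entity_key <- function(canonical, etype) paste(canonical, etype, sep = "\r")

split_entity_key <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  list(canonical = vapply(parts, `[`, character(1), 1L),
       etype = vapply(parts, `[`, character(1), 2L))
}

#' Is a type pair admissible for a mined co-occurrence edge?
#'
#' @param t1,t2 Entity types.
#' @return Logical; `TRUE` for gene-chemical and chemical-property pairs in
#'   either order, `FALSE` for every other combination (including
#'   same-type pairs and anything involving strains, whose edges are added
#'   manually).
#' @export
admissible_pair <- function(t1, t2) {
  (t1 == "gene" & t2 == "chemical") | (t1 == "chemical" & t2 == "gene") |
    (t1 == "chemical" & t2 == "property") |
    (t1 == "property" & t2 == "chemical")
}

#' Create an empty streaming co-occurrence accumulator
#'
#' @return An object of class `cooc_accumulator`; feed it paragraphs with
#'   [cooc_accumulate()] and finalize with [finalize_counts()].
#' @export
cooc_accumulator <- function() {
  acc <- new.env(parent = emptyenv())
  acc$N <- 0L
  acc$occ <- new.env(parent = emptyenv())
  acc$pairs <- new.env(parent = emptyenv())
  class(acc) <- "cooc_accumulator"
  acc
}

#' Accumulate one paragraph of mentions
#'
#' Increments the paragraph total, the per-entity paragraph presence counts,
#' and, for every admissible pair of distinct entities present, the pair
#' co-occurrence count, the pair weight (product of the two mention counts)
#' and the provenance record.
#'
#' @param acc A [cooc_accumulator()].
#' @param mentions Mention `data.frame` for ONE paragraph (all rows share one
#'   `(doc_id, para_index)`); may have zero rows for an entity-free
#'   paragraph.
#' @param doc_id,para_index Paragraph key, required only when `mentions` has
#'   zero rows.
#' @return `acc`, invisibly (modified in place).
#' @export
cooc_accumulate <- function(acc, mentions, doc_id = NULL, para_index = NULL) {
  stopifnot(inherits(acc, "cooc_accumulator"))
  acc$N <- acc$N + 1L
  if (NROW(mentions) == 0L) return(invisible(acc))
  if (length(unique(mentions$doc_id)) > 1L ||
      length(unique(mentions$para_index)) > 1L) {
    stop("mentions passed to cooc_accumulate span more than one paragraph",
         call. = FALSE)
  }
  if (anyDuplicated(entity_key(mentions$canonical, mentions$etype))) {
    stop("duplicate entity rows in one paragraph's mentions", call. = FALSE)
  }
  keys <- entity_key(mentions$canonical, mentions$etype)
  for (k in keys) acc$occ[[k]] <- (acc$occ[[k]] %||% 0L) + 1L
  m <- nrow(mentions)
  if (m < 2L) return(invisible(acc))
  prov <- c(mentions$doc_id[1], mentions$para_index[1])
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (!admissible_pair(mentions$etype[i], mentions$etype[j])) next
      k1 <- keys[i]; k2 <- keys[j]
      if (k1 > k2) { tmp <- k1; k1 <- k2; k2 <- tmp }
      pk <- paste(k1, k2, sep = "\n")
      rec <- acc$pairs[[pk]]
      if (is.null(rec)) {
        rec <- list(e1 = k1, e2 = k2, occ = 0L, weight = 0L, prov = list())
      }
      rec$occ <- rec$occ + 1L
      rec$weight <- rec$weight + mentions$count[i] * mentions$count[j]
      rec$prov[[length(rec$prov) + 1L]] <- prov
      acc$pairs[[pk]] <- rec
    }
  }
  invisible(acc)
}

#' Finalize an accumulator into a counts object
#'
#' @param acc A [cooc_accumulator()].
#' @return An object of class `cooc_counts`: a list with `N` (paragraphs
#'   scanned), `entities` (`canonical`, `etype`, `count`), `pairs`
#'   (`canonical_1`, `etype_1`, `canonical_2`, `etype_2`, `pair_occ`,
#'   `pair_weight`) and `provenance` (named list of `(doc_id, para_index)`
#'   data frames, one per pair). All components are deterministically
#'   sorted, so any paragraph order yields the identical object.
#' @export
finalize_counts <- function(acc) {
  stopifnot(inherits(acc, "cooc_accumulator"))
  ek <- sort(ls(acc$occ))
  ents <- split_entity_key(ek)
  entities <- data.frame(canonical = ents$canonical, etype = ents$etype,
                         count = vapply(ek, function(k) acc$occ[[k]],
                                        integer(1), USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  pk <- sort(ls(acc$pairs))
  if (length(pk) > 0L) {
    recs <- lapply(pk, function(k) acc$pairs[[k]])
    e1 <- split_entity_key(vapply(recs, `[[`, character(1), "e1"))
    e2 <- split_entity_key(vapply(recs, `[[`, character(1), "e2"))
    pairs <- data.frame(canonical_1 = e1$canonical, etype_1 = e1$etype,
                        canonical_2 = e2$canonical, etype_2 = e2$etype,
                        pair_occ = vapply(recs, `[[`, integer(1), "occ"),
                        pair_weight = vapply(recs, function(r)
                          as.integer(r$weight), integer(1)),
                        stringsAsFactors = FALSE)
    provenance <- lapply(recs, function(r) {
      df <- data.frame(
        doc_id = vapply(r$prov, `[`, character(1), 1L),
        para_index = as.integer(vapply(r$prov, `[`, character(1), 2L)),
        stringsAsFactors = FALSE)
      df <- df[order(df$doc_id, df$para_index), , drop = FALSE]
      rownames(df) <- NULL
      df
    })
    names(provenance) <- pk
  } else {
    pairs <- data.frame(canonical_1 = character(), etype_1 = character(),
                        canonical_2 = character(), etype_2 = character(),
                        pair_occ = integer(), pair_weight = integer(),
                        stringsAsFactors = FALSE)
    provenance <- stats::setNames(list(), character())
  }
  structure(list(N = acc$N, entities = entities, pairs = pairs,
                 provenance = provenance), class = "cooc_counts")
}

#' @export
print.cooc_counts <- function(x, ...) {
  cat("<cooc_counts> ", x$N, " paragraphs, ", nrow(x$entities),
      " entities, ", nrow(x$pairs), " admissible co-occurring pairs\n",
      sep = "")
  invisible(x)
}

#' Count occurrences and co-occurrences over a corpus or mention table
#'
#' Convenience front end to the accumulator. Given a corpus (or paragraph
#' stream) plus a lexicon it tags every paragraph and counts; given an
#' already-extracted mention table it counts directly (vectorized), in which
#' case `n_paragraphs` must state the total number of paragraphs scanned
#' (paragraphs without mentions still contribute to N).
#'
#' @param x Corpus list, paragraph-stream `data.frame`, or mention
#'   `data.frame` (columns `doc_id`, `para_index`, `canonical`, `etype`,
#'   `count`).
#' @param lexicon Lexicon/matcher, required when `x` is a corpus or stream.
#' @param n_paragraphs Total paragraphs scanned, required when `x` is a
#'   mention table.
#' @param include_abstract Passed through to [paragraph_stream()].
#' @return A `cooc_counts` object (see [finalize_counts()]).
#' @export
count_cooccurrences <- function(x, lexicon = NULL, n_paragraphs = NULL,
                                include_abstract = FALSE) {
  if (is.data.frame(x) && all(c("canonical", "etype", "count") %in% names(x))) {
    mentions <- x
    if (is.null(n_paragraphs)) {
      stop("n_paragraphs is required when counting from a mention table",
           call. = FALSE)
    }
  } else {
    if (is.null(lexicon)) stop("lexicon is required", call. = FALSE)
    stream <- if (is.data.frame(x)) x else paragraph_stream(x, include_abstract)
    mentions <- extract_mentions(stream, lexicon)
    n_paragraphs <- nrow(stream)
  }
  counts_from_mentions(mentions, n_paragraphs)
}

# Vectorized counting from a mention table.
counts_from_mentions <- function(mentions, n_paragraphs) {
  if (NROW(mentions) == 0L) {
    acc <- cooc_accumulator()
    acc$N <- as.integer(n_paragraphs)
    return(finalize_counts(acc))
  }
  ekey <- entity_key(mentions$canonical, mentions$etype)
  para <- paste(mentions$doc_id, mentions$para_index, sep = "\r")
  if (anyDuplicated(paste(para, ekey, sep = "\n"))) {
    stop("mention table has duplicate (paragraph, entity) rows", call. = FALSE)
  }
  occ_tab <- table(ekey)
  ek <- sort(names(occ_tab))
  ents <- split_entity_key(ek)
  entities <- data.frame(canonical = ents$canonical, etype = ents$etype,
                         count = as.integer(occ_tab[ek]),
                         stringsAsFactors = FALSE)
  m <- data.frame(para = para, ekey = ekey, etype = mentions$etype,
                  count = mentions$count, doc_id = mentions$doc_id,
                  para_index = mentions$para_index, stringsAsFactors = FALSE)
  mm <- merge(m, m, by = "para")
  mm <- mm[mm$ekey.x < mm$ekey.y &
             admissible_pair(mm$etype.x, mm$etype.y), , drop = FALSE]
  if (nrow(mm) == 0L) {
    pairs <- data.frame(canonical_1 = character(), etype_1 = character(),
                        canonical_2 = character(), etype_2 = character(),
                        pair_occ = integer(), pair_weight = integer(),
                        stringsAsFactors = FALSE)
    provenance <- stats::setNames(list(), character())
  } else {
    pk <- paste(mm$ekey.x, mm$ekey.y, sep = "\n")
    w <- mm$count.x * mm$count.y
    occ_p <- tapply(rep(1L, length(pk)), pk, sum)
    w_p <- tapply(w, pk, sum)
    keys <- sort(names(occ_p))
    halves <- strsplit(keys, "\n", fixed = TRUE)
    e1 <- split_entity_key(vapply(halves, `[`, character(1), 1L))
    e2 <- split_entity_key(vapply(halves, `[`, character(1), 2L))
    pairs <- data.frame(canonical_1 = e1$canonical, etype_1 = e1$etype,
                        canonical_2 = e2$canonical, etype_2 = e2$etype,
                        pair_occ = as.integer(occ_p[keys]),
                        pair_weight = as.integer(w_p[keys]),
                        stringsAsFactors = FALSE)
    prov_df <- data.frame(pk = pk, doc_id = mm$doc_id.x,
                          para_index = mm$para_index.x,
                          stringsAsFactors = FALSE)
    provenance <- lapply(keys, function(k) {
      df <- prov_df[prov_df$pk == k, c("doc_id", "para_index"), drop = FALSE]
      df <- df[order(df$doc_id, df$para_index), , drop = FALSE]
      rownames(df) <- NULL
      df
    })
    names(provenance) <- keys
  }
  structure(list(N = as.integer(n_paragraphs), entities = entities,
                 pairs = pairs, provenance = provenance),
            class = "cooc_counts")
}

#' Paragraph-level 2x2 contingency table for an entity pair
#'
#' Cells over the N scanned paragraphs: both present / only `a` / only `g` /
#' neither. Feeds the log-likelihood-ratio collocation test.
#'
#' @param counts A `cooc_counts` object.
#' @param a,g Canonical entity names.
#' @param a_type,g_type Optional entity types, required when a canonical name
#'   exists under more than one type.
#' @return A [contingency_table()].
#' @export
contingency <- function(counts, a, g, a_type = NULL, g_type = NULL) {
  stopifnot(inherits(counts, "cooc_counts"))
  ra <- resolve_entity(counts, a, a_type)
  rg <- resolve_entity(counts, g, g_type)
  ca <- counts$entities$count[ra]
  cg <- counts$entities$count[rg]
  ka <- entity_key(counts$entities$canonical[ra], counts$entities$etype[ra])
  kg <- entity_key(counts$entities$canonical[rg], counts$entities$etype[rg])
  pk <- paste(sort(c(ka, kg))[1], sort(c(ka, kg))[2], sep = "\n")
  hit <- match(pk, paste(entity_key(counts$pairs$canonical_1,
                                    counts$pairs$etype_1),
                         entity_key(counts$pairs$canonical_2,
                                    counts$pairs$etype_2), sep = "\n"))
  cag <- if (is.na(hit)) 0L else counts$pairs$pair_occ[hit]
  contingency_table(k11 = cag, k12 = ca - cag, k21 = cg - cag,
                    k22 = counts$N - ca - cg + cag)
}

resolve_entity <- function(counts, canonical, etype = NULL) {
  hit <- which(counts$entities$canonical == canonical &
                 (if (is.null(etype)) TRUE else counts$entities$etype == etype))
  if (length(hit) == 0L) {
    stop("entity not seen in counts: ", canonical, call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop("entity name ambiguous across types (give a_type/g_type): ",
         canonical, call. = FALSE)
  }
  hit
}
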