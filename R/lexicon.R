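# Entity lexicons and the dictionary tagger. Four entity types are
# recognized: gene, chemical, property (therapeutic concept) and strain.
# Matching is greedy longest-match, left-to-right, non-overlapping over the
# normalized token sequence; ties at equal length are broken by the fixed
# type priority gene > chemical > property > strain (rarer types win).

ENTITY_TYPES <- c("gene", "chemical", "property", "strain")
.type_priority <- stats::setNames(seq_along(ENTITY_TYPES), ENTITY_TYPES)

#' Normalize a term
#'
#' Lowercases, turns hyphens into spaces, strips leading/trailing
#' punctuation, and collapses whitespace runs to single spaces. Deterministic
#' and idempotent; applied to every lexicon surface and to query terms so
#' that matching is case- and hyphenation-insensitive.
#'
#' @param raw Character vector.
#' @return Normalized character vector of the same length.
#' @export
normalize_term <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", x)
  x
}

# Matching tokenizer: splits on every non-alphanumeric run, so it agrees
# with normalize_term on hyphens and punctuation.
tokenize_text <- function(text) {
  toks <- strsplit(gsub("[^[:alnum:]]+", " ", tolower(text)), " ",
                   fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Build a lexicon from a data frame
#'
#' @param df Data frame with columns `surface`, `canonical`, `etype`.
#' @return Validated, normalized lexicon `data.frame` of class
#'   `litnet_lexicon`; duplicate identical rows are collapsed.
#' @export
as_lexicon <- function(df) {
  stopifnot(all(c("surface", "canonical", "etype") %in% names(df)))
  lex <- data.frame(surface = normalize_term(df$surface),
                    canonical = normalize_term(df$canonical),
                    etype = as.character(df$etype),
                    stringsAsFactors = FALSE)
  bad <- !lex$etype %in% ENTITY_TYPES
  if (any(bad)) {
    stop("unknown entity type(s) at line(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(lex$etype[bad]), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(lex$surface)
  if (any(empty)) {
    stop("empty surface after normalization at line(s) ",
         paste(which(empty), collapse = ", "), call. = FALSE)
  }
  lex <- unique(lex)
  key <- paste(lex$surface, lex$etype, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("conflicting canonicals for the same (surface, etype): ",
         paste(unique(lex$surface[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(lex) <- NULL
  class(lex) <- c("litnet_lexicon", "data.frame")
  lex
}

#' Load an entity lexicon from TSV
#'
#' Columns: surface form, canonical name, entity type (one of gene,
#' chemical, property, strain). Multiple surfaces may map to one canonical
#' (synonyms); a surface may carry different canonicals only under different
#' entity types.
#'
#' @param path TSV file, UTF-8, no header by default.
#' @param header Does the file carry a header row?
#' @return A lexicon (see [as_lexicon()]).
#' @export
load_lexicon <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = header, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("surface", "canonical", "etype"),
                          fill = FALSE, encoding = "UTF-8")
  tryCatch(as_lexicon(df), error = function(e) {
    stop("in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Precompile a lexicon into a matcher index
#'
#' Tokenizes every surface and indexes it by first token; [match_entities()]
#' accepts the result wherever it accepts a lexicon, which avoids rebuilding
#' the index for every paragraph of a large corpus.
#'
#' @param lexicon A lexicon data frame (see [as_lexicon()]).
#' @return An object of class `litnet_matcher`.
#' @export
build_matcher <- function(lexicon) {
  if (inherits(lexicon, "litnet_matcher")) return(lexicon)
  lex <- as_lexicon(lexicon)
  toks <- lapply(lex$surface, tokenize_text)
  len <- lengths(toks)
  keep <- len > 0L
  lex <- lex[keep, , drop = FALSE]; toks <- toks[keep]; len <- len[keep]
  ord <- order(-len, .type_priority[lex$etype])
  lex <- lex[ord, , drop = FALSE]; toks <- toks[ord]; len <- len[ord]
  index <- new.env(parent = emptyenv())
  for (r in seq_along(toks)) {
    ft <- toks[[r]][1]
    index[[ft]] <- c(index[[ft]], r)
  }
  m <- list(lex = lex, toks = toks, len = len, index = index,
            all_single = all(len == 1L))
  if (m$all_single) {
    # fast path: surface -> highest-priority (canonical, etype)
    first <- !duplicated(lex$surface)
    m$fast_surface <- lex$surface[first]
    m$fast_canonical <- lex$canonical[first]
    m$fast_etype <- lex$etype[first]
  }
  structure(m, class = "litnet_matcher")
}

empty_mentions <- function() {
  data.frame(doc_id = character(), para_index = integer(),
             canonical = character(), etype = character(),
             count = integer(), stringsAsFactors = FALSE)
}

#' Tag one paragraph with entity mentions
#'
#' Scans the paragraph's token sequence greedily left-to-right for the
#' longest lexicon surface starting at each position; a token run consumed by
#' one match cannot contribute to another. Counts are aggregated per
#' (canonical, etype).
#'
#' @param text Paragraph text (single string).
#' @param lexicon A lexicon data frame or a prebuilt [build_matcher()] index.
#' @param doc_id,para_index Paragraph key carried into the output.
#' @return `data.frame` with columns `doc_id`, `para_index`, `canonical`,
#'   `etype`, `count` (one row per mentioned entity).
#' @export
match_entities <- function(text, lexicon, doc_id = NA_character_,
                           para_index = NA_integer_) {
  m <- build_matcher(lexicon)
  toks <- tokenize_text(text)
  n <- length(toks)
  if (n == 0L || nrow(m$lex) == 0L) return(empty_mentions())
  if (m$all_single) {
    idx <- match(toks, m$fast_surface)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(empty_mentions())
    tab <- table(idx)
    rows <- as.integer(names(tab))
    return(data.frame(doc_id = doc_id, para_index = para_index,
                      canonical = m$fast_canonical[rows],
                      etype = m$fast_etype[rows],
                      count = as.integer(tab), stringsAsFactors = FALSE))
  }
  hits <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- m$index[[toks[i]]]
    step <- 1L
    if (!is.null(cand)) {
      for (r in cand) {
        L <- m$len[r]
        if (i + L - 1L <= n && all(toks[i:(i + L - 1L)] == m$toks[[r]])) {
          hits <- c(hits, r)
          step <- L
          break
        }
      }
    }
    i <- i + step
  }
  if (length(hits) == 0L) return(empty_mentions())
  key <- paste(m$lex$canonical[hits], m$lex$etype[hits], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(doc_id = doc_id, para_index = para_index,
             canonical = vapply(parts, `[`, character(1), 1L),
             etype = vapply(parts, `[`, character(1), 2L),
             count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Tag a whole corpus
#'
#' @param corpus A list of [document()] objects or a paragraph stream
#'   `data.frame` (see [paragraph_stream()]).
#' @param lexicon Lexicon or matcher.
#' @param include_abstract Passed to [paragraph_stream()] when `corpus` is a
#'   document list.
#' @return Mention `data.frame` over all paragraphs (columns as in
#'   [match_entities()]).
#' @export
extract_mentions <- function(corpus, lexicon, include_abstract = FALSE) {
  stream <- if (is.data.frame(corpus)) corpus
            else paragraph_stream(corpus, include_abstract)
  m <- build_matcher(lexicon)
  out <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    out[[i]] <- match_entities(stream$text[i], m, stream$doc_id[i],
                               stream$index[i])
  }
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (length(out) == 0L) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adapt an external named-entity tagger
#'
#' Wraps any span-producing tagger (e.g. a model-based bioNER system called
#' out-of-process) so that its output flows through the same normalization
#' and canonical lookup as the dictionary matcher, making the two
#' interchangeable. Surfaces unknown to the lexicon become their own
#' canonical.
#'
#' @param tag_fn Function taking paragraph text and returning a `data.frame`
#'   with columns `surface` and `etype`, optionally `start` and `end` token
#'   or character offsets; duplicate spans (identical start/end) are counted
#'   once.
#' @param lexicon Optional lexicon for canonical lookup.
#' @return A tagger `function(text, doc_id, para_index)` returning mentions
#'   in the [match_entities()] format.
#' @export
external_tagger_adapter <- function(tag_fn, lexicon = NULL) {
  lex <- if (!is.null(lexicon)) as_lexicon(lexicon)
  function(text, doc_id = NA_character_, para_index = NA_integer_) {
    spans <- tryCatch(tag_fn(text), error = function(e) {
      stop("external tagger failed on paragraph (", doc_id, ", ", para_index,
           "): ", conditionMessage(e), call. = FALSE)
    })
    if (is.null(spans) || NROW(spans) == 0L) return(empty_mentions())
    spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    stopifnot(all(c("surface", "etype") %in% names(spans)))
    if (!all(spans$etype %in% ENTITY_TYPES)) {
      stop("external tagger returned unknown entity type(s): ",
           paste(setdiff(unique(spans$etype), ENTITY_TYPES), collapse = ", "),
           call. = FALSE)
    }
    if (all(c("start", "end") %in% names(spans))) {
      spans <- spans[!duplicated(spans[, c("start", "end")]), , drop = FALSE]
    }
    surf <- normalize_term(spans$surface)
    canonical <- surf
    if (!is.null(lex)) {
      idx <- match(paste(surf, spans$etype, sep = "\r"),
                   paste(lex$surface, lex$etype, sep = "\r"))
      canonical[!is.na(idx)] <- lex$canonical[idx[!is.na(idx)]]
    }
    key <- paste(canonical, spans$etype, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    data.frame(doc_id = doc_id, para_index = para_index,
               canonical = vapply(parts, `[`, character(1), 1L),
               etype = vapply(parts, `[`, character(1), 2L),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
}
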