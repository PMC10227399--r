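# Skip-gram word embeddings over the corpus, used to expand the manually
# curated therapeutic-property seed list: terms that occur in similar
# contexts acquire nearby vectors, so cosine-similarity neighborhoods of
# the seeds surface candidate synonyms and related concepts for human
# review. Frequent bigrams are merged into single tokens before training so
# multi-word properties (e.g. "anti inflammatory") can embed as units.

#' Train skip-gram embeddings on a corpus
#'
#' Trains skip-gram vectors with negative sampling on the corpus paragraph
#' text. Training is single-threaded with a seeded generator, so identical
#' `(corpus, params, seed)` always yields identical vectors (multi-worker
#' word2vec implementations are not bit-reproducible; this one trades speed
#' for that property). Adjacent token pairs occurring at least
#' `bigram_min_count` times are first merged into single `a_b` tokens.
#'
#' @param x A corpus (list of [document()]), a paragraph-stream
#'   `data.frame`, or a character vector of texts.
#' @param dim Vector dimension, default 100.
#' @param window Context window half-width, default 5.
#' @param min_count Minimum corpus frequency for a vocabulary term,
#'   default 5.
#' @param epochs Training epochs, default 5.
#' @param negative Negative samples per positive pair, default 5.
#' @param learning_rate Initial learning rate (linearly decayed), default
#'   0.025.
#' @param bigram_min_count Frequency threshold for bigram merging, default
#'   20; `Inf` disables phrase merging.
#' @param seed RNG seed, default 1.
#' @return Object of class `skipgram_model`: `vocabulary`, `vectors`
#'   (term-by-dim matrix with terms as rownames), `counts`, `params`.
#' @export
train_skipgram <- function(x, dim = 100L, window = 5L, min_count = 5L,
                           epochs = 5L, negative = 5L,
                           learning_rate = 0.025, bigram_min_count = 20L,
                           seed = 1L) {
  stopifnot(dim >= 2L, window >= 1L, min_count >= 1L, epochs >= 1L)
  texts <- corpus_texts(x)
  sentences <- lapply(texts, tokenize_text)
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) stop("corpus is empty", call. = FALSE)
  if (is.finite(bigram_min_count)) {
    sentences <- merge_bigrams(sentences, bigram_min_count)
  }
  freq <- table(unlist(sentences))
  freq <- freq[freq >= min_count]
  if (length(freq) == 0L) {
    stop("no term reaches min_count = ", min_count,
         "; lower min_count", call. = FALSE)
  }
  vocab <- sort(names(freq))
  counts <- as.numeric(freq[vocab])
  ids <- lapply(sentences, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  ids <- ids[lengths(ids) > 0L]
  vec <- sgns_train_cpp(ids, length(vocab), counts, as.integer(dim),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), learning_rate,
                        as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec,
                 counts = stats::setNames(as.integer(counts), vocab),
                 params = list(dim = as.integer(dim),
                               window = as.integer(window),
                               min_count = as.integer(min_count),
                               epochs = as.integer(epochs),
                               negative = as.integer(negative),
                               learning_rate = learning_rate,
                               bigram_min_count = bigram_min_count,
                               seed = as.integer(seed))),
            class = "skipgram_model")
}

corpus_texts <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) return(x$text)
  paragraph_stream(x)$text
}

# Greedy left-to-right single-pass merge of frequent adjacent pairs.
merge_bigrams <- function(sentences, min_count) {
  big <- unlist(lapply(sentences, function(s) {
    if (length(s) < 2L) return(character(0))
    paste(s[-length(s)], s[-1L], sep = "\r")
  }))
  if (length(big) == 0L) return(sentences)
  keep <- names(which(table(big) >= min_count))
  if (length(keep) == 0L) return(sentences)
  keep_env <- new.env(parent = emptyenv())
  for (k in keep) keep_env[[k]] <- TRUE
  lapply(sentences, function(s) {
    n <- length(s)
    if (n < 2L) return(s)
    out <- character(n)
    o <- 0L; i <- 1L
    while (i <= n) {
      if (i < n && !is.null(keep_env[[paste(s[i], s[i + 1L],
                                            sep = "\r")]])) {
        o <- o + 1L; out[o] <- paste(s[i], s[i + 1L], sep = "_")
        i <- i + 2L
      } else {
        o <- o + 1L; out[o] <- s[i]
        i <- i + 1L
      }
    }
    out[seq_len(o)]
  })
}

#' @export
print.skipgram_model <- function(x, ...) {
  cat("<skipgram_model> ", length(x$vocabulary), " terms, dim ",
      x$params$dim, " (window ", x$params$window, ", min_count ",
      x$params$min_count, ", epochs ", x$params$epochs, ", seed ",
      x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal dimension, each nonzero.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors have different dimensions", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Expand a seed term list by embedding-space neighborhood search
#'
#' For every seed found in the model vocabulary, returns the most similar
#' vocabulary terms above a cosine-similarity threshold. Seeds absent from
#' the vocabulary are reported, never silently dropped. The merged list
#' (seeds plus accepted neighbors, deduplicated after normalization) is an
#' expansion CANDIDATE list intended for human review before entering the
#' lexicon.
#'
#' @param seeds Character vector of seed phrases (normalized; internal
#'   spaces are matched against merged bigram tokens).
#' @param model A [train_skipgram()] model.
#' @param threshold Minimum cosine similarity in (0, 1], default 0.7.
#' @param top_k Maximum neighbors per seed, default 10.
#' @return List with `expansions` (`data.frame` seed, neighbor, similarity,
#'   sorted by seed then descending similarity), `absent` (seeds not in the
#'   vocabulary) and `merged` (seeds plus accepted neighbors).
#' @export
expand_terms <- function(seeds, model, threshold = 0.7, top_k = 10L) {
  stopifnot(inherits(model, "skipgram_model"), top_k >= 1L)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  seeds_norm <- unique(normalize_term(seeds))
  keys <- gsub(" ", "_", seeds_norm, fixed = TRUE)
  vec <- model$vectors
  norms <- sqrt(rowSums(vec^2))
  norms[norms == 0] <- 1
  unit <- vec / norms
  rows <- list()
  absent <- character(0)
  for (i in seq_along(seeds_norm)) {
    k <- keys[i]
    if (!k %in% model$vocabulary) {
      absent <- c(absent, seeds_norm[i])
      next
    }
    sims <- as.numeric(unit %*% unit[k, ])
    names(sims) <- model$vocabulary
    sims <- sims[names(sims) != k]
    sims <- sort(sims[sims >= threshold], decreasing = TRUE)
    if (length(sims) > top_k) sims <- sims[seq_len(top_k)]
    if (length(sims) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seeds_norm[i],
        neighbor = gsub("_", " ", names(sims), fixed = TRUE),
        similarity = as.numeric(sims), stringsAsFactors = FALSE)
    }
  }
  expansions <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(seed = character(), neighbor = character(),
               similarity = numeric(), stringsAsFactors = FALSE)
  rownames(expansions) <- NULL
  list(expansions = expansions, absent = absent,
       merged = unique(c(seeds_norm, expansions$neighbor)))
}

#' Read a seed phrase list
#'
#' @param path Plain-text file, one phrase per line; blank lines and `#`
#'   comments ignored.
#' @return Normalized character vector.
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) stop("seed list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_term(lines))
}

#' Write an expansion report
#'
#' @param expansion Result of [expand_terms()].
#' @param path Output TSV path (columns seed, neighbor, similarity).
#' @return `path`, invisibly.
#' @export
write_expansion_report <- function(expansion, path) {
  utils::write.table(expansion$expansions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Persist embedding vectors as text
#'
#' Format: a header line `n d`, then one line per term: the term followed
#' by `d` floating-point components.
#'
#' @param model A [train_skipgram()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(model$vocabulary), model$params$dim), con)
  for (i in seq_along(model$vocabulary)) {
    writeLines(paste(model$vocabulary[i],
                     paste(sprintf("%.17g", model$vectors[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Load embedding vectors written by [write_embeddings()]
#'
#' @param path Input path.
#' @return A `skipgram_model` carrying the vectors (training parameters
#'   other than the dimension are unknown and set to `NA`).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  vocab <- vapply(parts, `[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec,
                 counts = NULL,
                 params = list(dim = d, window = NA_integer_,
                               min_count = NA_integer_,
                               epochs = NA_integer_, negative = NA_integer_,
                               learning_rate = NA_real_,
                               bigram_min_count = NA, seed = NA_integer_)),
            class = "skipgram_model")
}
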