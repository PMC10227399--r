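# Corpus ingestion: JATS/PMC-style XML parsing, English filtering, JSONL
# round-tripping, and the paragraph stream that feeds co-occurrence counting.

#' Construct a document
#'
#' A document is the unit of ingestion: an identifier, title, abstract, an
#' ordered vector of body paragraphs, and citation metadata. Paragraph text is
#' whitespace-normalized on construction; empty paragraphs are dropped.
#'
#' @param doc_id Non-empty document identifier, unique within a corpus.
#' @param title Article title.
#' @param abstract Abstract text (may be empty).
#' @param paragraphs Character vector of body paragraphs in document order.
#' @param meta List with elements `authors` (character vector), `journal`,
#'   `pub_date` (ISO-8601 or empty) and `doi`; missing elements default to
#'   empty.
#' @return A list of class `litnet_document`.
#' @export
document <- function(doc_id, title, abstract = "", paragraphs = character(),
                     meta = list()) {
  doc_id <- as.character(doc_id)
  if (length(doc_id) != 1L || is.na(doc_id) || !nzchar(doc_id)) {
    stop("doc_id must be a single non-empty string", call. = FALSE)
  }
  paragraphs <- vapply(as.character(paragraphs), squash_ws, character(1),
                       USE.NAMES = FALSE)
  paragraphs <- paragraphs[nzchar(paragraphs)]
  meta_full <- list(authors = character(), journal = "", pub_date = "",
                    doi = "")
  for (k in names(meta)) {
    if (!k %in% names(meta_full)) {
      stop("unknown metadata field: ", k, call. = FALSE)
    }
    meta_full[[k]] <- meta[[k]]
  }
  structure(list(doc_id = doc_id, title = squash_ws(as.character(title)),
                 abstract = squash_ws(as.character(abstract)),
                 paragraphs = paragraphs, meta = meta_full),
            class = "litnet_document")
}

#' @export
print.litnet_document <- function(x, ...) {
  cat("<document ", x$doc_id, "> \"", x$title, "\" (",
      length(x$paragraphs), " paragraphs)\n", sep = "")
  invisible(x)
}

# Collapse all whitespace runs to single spaces and trim.
squash_ws <- function(x) {
  if (length(x) == 0L) return("")
  trimws(gsub("[[:space:]]+", " ", paste(x, collapse = " ")))
}

#' Parse a JATS/PMC-style XML article
#'
#' Accepts the JATS subset used by PubMed Central full text: the title from
#' `article-title`, abstract paragraphs from `abstract//p`, body paragraphs
#' from `body//p`. Inline markup (italics, links, ...) is flattened to text;
#' unknown elements are ignored. Missing metadata fields become empty strings.
#'
#' @param xml_text XML as a single string, or a path to an XML file.
#' @param doc_id Identifier to assign; defaults to the article's DOI or, when
#'   absent, the first `article-id` element; an error if neither exists and no
#'   id is supplied.
#' @return A [document()].
#' @export
parse_pmc_xml <- function(xml_text, doc_id = NULL) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) {
                    stop("malformed XML",
                         if (!is.null(doc_id)) paste0(" in document ", doc_id),
                         ": ", conditionMessage(e), call. = FALSE)
                  })
  title_node <- xml2::xml_find_first(doc, ".//article-title")
  if (inherits(title_node, "xml_missing")) {
    stop("document", if (!is.null(doc_id)) paste0(" ", doc_id),
         " has no article-title element", call. = FALSE)
  }
  title <- xml2::xml_text(title_node)
  abstract <- paste(
    xml2::xml_text(xml2::xml_find_all(doc, ".//abstract//p")),
    collapse = " ")
  paragraphs <- xml2::xml_text(xml2::xml_find_all(doc, ".//body//p"))
  authors <- xml2::xml_find_all(
    doc, ".//contrib[@contrib-type='author']/name")
  author_names <- vapply(authors, function(n) {
    squash_ws(paste(
      xml2::xml_text(xml2::xml_find_first(n, "./given-names")),
      xml2::xml_text(xml2::xml_find_first(n, "./surname"))))
  }, character(1))
  author_names <- gsub("NA ?", "", author_names)
  journal <- first_text(doc, ".//journal-title")
  doi <- first_text(doc, ".//article-id[@pub-id-type='doi']")
  pd <- xml2::xml_find_first(doc, ".//pub-date")
  pub_date <- ""
  if (!inherits(pd, "xml_missing")) {
    y <- first_text(pd, "./year"); m <- first_text(pd, "./month")
    d <- first_text(pd, "./day")
    if (nzchar(y)) {
      pub_date <- y
      if (nzchar(m)) pub_date <- paste0(pub_date, "-", formatC(as.integer(m), width = 2, flag = "0"))
      if (nzchar(m) && nzchar(d)) pub_date <- paste0(pub_date, "-", formatC(as.integer(d), width = 2, flag = "0"))
    }
  }
  if (is.null(doc_id)) {
    doc_id <- if (nzchar(doi)) doi else first_text(doc, ".//article-id")
    if (!nzchar(doc_id)) {
      stop("no doc_id supplied and no article-id/doi in XML", call. = FALSE)
    }
  }
  document(doc_id, title, abstract, paragraphs,
           meta = list(authors = author_names, journal = journal,
                       pub_date = pub_date, doi = doi))
}

first_text <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) "" else squash_ws(xml2::xml_text(n))
}

#' English-language filter
#'
#' Deterministic heuristic standing in for a language-identification model:
#' the fraction of alphabetic tokens of the title plus abstract found in a
#' built-in English stopword list must reach `stopword_ratio_min`. English
#' prose is saturated with function words, so even short titles clear a low
#' threshold, while other languages share essentially none of the list.
#'
#' @param doc A [document()].
#' @param stopword_ratio_min Minimum stopword fraction, default 0.15.
#' @return `TRUE` or `FALSE`. Documents with no alphabetic tokens in title and
#'   abstract are indeterminate and return `FALSE` with a warning.
#' @export
is_english <- function(doc, stopword_ratio_min = 0.15) {
  txt <- tolower(paste(doc$title, doc$abstract))
  tokens <- regmatches(txt, gregexpr("[a-z]+", txt))[[1]]
  if (length(tokens) == 0L) {
    warning("document ", doc$doc_id,
            " has no alphabetic tokens in title/abstract; ",
            "language indeterminate, treating as non-English", call. = FALSE)
    return(FALSE)
  }
  mean(tokens %in% english_stopwords()) >= stopword_ratio_min
}

#' Write a corpus to line-delimited JSON
#'
#' One document per line with fields in fixed order (`doc_id`, `title`,
#' `abstract`, `paragraphs`, `meta`) so that serialized corpora diff
#' reproducibly. Round-trips with [read_corpus()].
#'
#' @param corpus List of [document()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (d in corpus) {
    rec <- list(doc_id = d$doc_id, title = d$title, abstract = d$abstract,
                paragraphs = as.list(d$paragraphs),
                meta = list(authors = as.list(d$meta$authors),
                            journal = d$meta$journal,
                            pub_date = d$meta$pub_date, doi = d$meta$doi))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a corpus
#'
#' @param path A JSONL file (`format = "jsonl"`) or a directory of
#'   per-document XML files (`format = "xml_dir"`, doc_id taken from the file
#'   name without extension).
#' @param format Input format.
#' @return A list of [document()] objects in deterministic order
#'   (lexicographic by `doc_id`). Duplicate document ids are an error.
#' @export
read_corpus <- function(path, format = c("jsonl", "xml_dir")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    if (!file.exists(path)) stop("cannot read corpus: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    corpus <- lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      document(rec$doc_id, rec$title,
               if (is.null(rec$abstract)) "" else rec$abstract,
               unlist(rec$paragraphs),
               meta = list(
                 authors = as.character(unlist(rec$meta$authors)),
                 journal = rec$meta$journal %||% "",
                 pub_date = rec$meta$pub_date %||% "",
                 doi = rec$meta$doi %||% ""))
    })
  } else {
    if (!dir.exists(path)) stop("cannot read corpus dir: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
    corpus <- lapply(files, function(f) {
      parse_pmc_xml(f, doc_id = sub("\\.xml$", "", basename(f)))
    })
  }
  ids <- vapply(corpus, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  corpus[order(ids, method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paragraph stream
#'
#' Flattens a corpus into its ordered paragraph records, the unit over which
#' entities are counted and co-occurrence is defined. Body paragraphs are
#' indexed from 0 in document order; with `include_abstract = TRUE` the
#' abstract is prepended as index 0 and body paragraphs follow from 1.
#'
#' @param corpus List of [document()] objects.
#' @param include_abstract Treat the abstract as a leading paragraph
#'   (default `FALSE`: full-text body paragraphs only).
#' @return `data.frame` with columns `doc_id`, `index`, `text`; one row per
#'   paragraph, `(doc_id, index)` unique.
#' @export
paragraph_stream <- function(corpus, include_abstract = FALSE) {
  rows <- lapply(corpus, function(d) {
    paras <- d$paragraphs
    if (include_abstract && nzchar(d$abstract)) {
      paras <- c(d$abstract, paras)
    }
    if (length(paras) == 0L) return(NULL)
    data.frame(doc_id = d$doc_id, index = seq_along(paras) - 1L,
               text = paras, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(doc_id = character(), index = integer(),
                      text = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
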